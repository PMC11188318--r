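# Stabilized inverse-probability-of-treatment weights: two multinomial
# models for the observed (baseline) class -- a marginal "numerator" model
# on time-fixed covariates and a "denominator" model adding the
# time-varying confounders -- combined as a per-interval probability ratio
# cumulated multiplicatively within patient.

#' Weight model specification
#'
#' Model 1 (cohort 1): numerator `sex + age + calendar period`, denominator
#' adds the three time-varying comorbidity drug flags. Model 2 (cohort 2)
#' additionally puts interval adherence in the denominator. Age enters
#' continuously; calendar time as the three-level period factor.
#' Stabilization is valid because the numerator covariates are a subset of
#' the denominator covariates.
#'
#' @param model 1 or 2.
#' @param truncation_percentiles Optional length-2 probabilities, e.g.
#'   `c(0.01, 0.99)`, for symmetric percentile truncation of the cumulated
#'   weights; `NULL` (default) leaves weights untruncated.
#' @return A list of class `weight_model_spec`.
#' @export
weight_model_spec <- function(model = 1L, truncation_percentiles = NULL) {
  stopifnot(model %in% c(1L, 2L))
  num <- c("sex", "age", "calendar_period")
  den <- c(num, "diabetes_rx", "ra_rx", "asthma_copd_rx")
  if (model == 2L) den <- c(den, "adherence_180")
  if (!is.null(truncation_percentiles))
    stopifnot(length(truncation_percentiles) == 2L,
              truncation_percentiles[1L] < truncation_percentiles[2L])
  structure(list(model = as.integer(model), numerator = num,
                 denominator = den,
                 truncation_percentiles = truncation_percentiles),
            class = "weight_model_spec")
}

exposure_factor <- function(x) {
  lev <- class_levels()
  bad <- setdiff(unique(x), lev)
  if (length(bad)) stop("unknown exposure class: ", paste(bad, collapse = ", "))
  factor(x, levels = lev[lev %in% unique(x)])
}

#' Fit the numerator and denominator propensity models
#'
#' Two multinomial logistic models for the patient's observed exposure
#' class (reference BB), fitted by maximum likelihood.
#'
#' By default the models are fitted on the index-interval (`k == 0`) rows:
#' the class was chosen once, under the covariates of that interval, and
#' fitting on the rows where the choice was made recovers the assignment
#' coefficients without attenuation. `fit_rows = "all"` instead pools
#' every person-period row, as in time-varying-weight estimation; with a
#' baseline-fixed exposure this dilutes the confounder coefficients with
#' post-baseline covariate changes (measured in simulation: the strongest
#' assignment coefficient shrinks by ~40%), so it is not the default.
#' Either way the fitted models predict probabilities for every row.
#'
#' @param pp Person-period table carrying the exposure class and every
#'   covariate named in `spec` (and `k` when `fit_rows = "baseline"`).
#' @param spec A [weight_model_spec()].
#' @param fit_rows `"baseline"` (default) or `"all"`; see above.
#' @return List of class `propensity_models`: `numerator`, `denominator`
#'   (both `nnet::multinom` fits), `spec`, `levels`.
#' @export
fit_propensity_models <- function(pp, spec = weight_model_spec(),
                                  fit_rows = c("baseline", "all")) {
  fit_rows <- match.arg(fit_rows)
  pp <- as.data.table(pp)
  if (fit_rows == "baseline") pp <- pp[k == 0L]
  missing_cov <- setdiff(unique(c(spec$numerator, spec$denominator)),
                         names(pp))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  for (v in unique(c(spec$numerator, spec$denominator)))
    if (anyNA(pp[[v]])) stop("missing values in covariate: ", v)
  y <- exposure_factor(pp$exposure_class)
  if (nlevels(y) < 2L)
    stop("need at least two exposure classes to fit propensity models")
  if (any(table(y) == 0L))
    stop("exposure class with zero rows: ",
         paste(levels(y)[table(y) == 0L], collapse = ", "))
  dat <- copy(pp)[, exposure_class := y]
  fit_one <- function(covs) {
    f <- as.formula(paste("exposure_class ~", paste(covs, collapse = " + ")))
    # collapse identical (class, covariate) rows to frequency weights:
    # same maximum-likelihood solution, far fewer rows
    comp <- dat[, .(.n_rep = .N), by = c("exposure_class", covs)]
    fit <- nnet::multinom(f, data = comp, weights = comp$.n_rep,
                          trace = FALSE, maxit = 300, MaxNWts = 5000)
    if (fit$convergence != 0)
      stop("propensity model did not converge (covariates: ",
           paste(covs, collapse = ", "), ")")
    if (any(!is.finite(coef(fit))))
      stop("non-finite propensity coefficients (separation?)")
    fit
  }
  structure(list(numerator = fit_one(spec$numerator),
                 denominator = fit_one(spec$denominator),
                 spec = spec, levels = levels(y)),
            class = "propensity_models")
}

# Predicted class-probability matrix with columns for every level.
# Computed directly from the coefficient matrix (softmax over the linear
# predictors) -- algebraically identical to predict(fit, type = "probs")
# but without its per-call overhead on large row counts.
prob_matrix <- function(fit, newdata, levels) {
  tt <- delete.response(terms(fit))
  mm <- model.matrix(tt, data = newdata, contrasts.arg = fit$contrasts,
                     xlev = fit$xlevels)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(fit$lev[2L], names(cf)))
  lp <- cbind(0, mm[, colnames(cf), drop = FALSE] %*% t(cf))
  colnames(lp) <- fit$lev
  p <- exp(lp - apply(lp, 1L, max))
  p <- p / rowSums(p)
  p[, levels, drop = FALSE]
}

#' Compute stabilized weights
#'
#' For each person-period row, `p_num` and `p_den` are the predicted
#' probabilities of the patient's own observed class under the numerator
#' and denominator models, and `ratio_k = p_num / p_den` is that
#' interval's stabilized ratio.
#'
#' @details Three aggregations of the ratios are returned, because the
#' exposure class is fixed at the index date and the three behave very
#' differently there. `sw_baseline`, the index-interval ratio carried
#' forward, is the default analysis weight: treatment was chosen once,
#' given the covariates of the first interval, so this is the stabilized
#' inverse probability of that choice. `ratio_k` re-evaluates the ratio at
#' each interval's covariates; it has cross-sectional mean 1 but
#' up-weights patients whose comorbidity streams start *after* the index
#' date, which never influenced the class choice, and therefore
#' over-corrects. `sw_k`, the within-patient cumulative product, is the
#' construction used for genuinely time-varying treatments; with a
#' baseline-fixed exposure the per-patient ratio is nearly constant across
#' intervals, so the product grows geometrically with follow-up and is
#' reported as a diagnostic of covariate-treatment dependence, not as an
#' analysis weight (see the methods vignette). Optional symmetric
#' percentile truncation clamps all three columns.
#'
#' @param pp Person-period table (same schema the models were fitted on).
#' @param models A `propensity_models` object.
#' @return data.table aligned row-wise with `pp`: `patient_id`, `k`,
#'   `p_num`, `p_den`, `ratio_k` (that interval's stabilized ratio), `sw_k`
#'   (within-patient cumulative product) and `sw_baseline` (the index
#'   interval's stabilized ratio carried forward -- the default analysis
#'   weight; see Details).
#' @export
compute_stabilized_weights <- function(pp, models) {
  stopifnot(inherits(models, "propensity_models"))
  pp <- as.data.table(pp)
  pn <- prob_matrix(models$numerator, pp, models$levels)
  pd <- prob_matrix(models$denominator, pp, models$levels)
  j <- match(pp$exposure_class, models$levels)
  p_num <- pn[cbind(seq_len(nrow(pp)), j)]
  p_den <- pd[cbind(seq_len(nrow(pp)), j)]
  if (any(p_den < 1e-12))
    stop("positivity violation: denominator probability below 1e-12 for ",
         sum(p_den < 1e-12), " row(s), e.g. patient ",
         pp$patient_id[which(p_den < 1e-12)[1L]])
  w <- data.table(patient_id = pp$patient_id, k = pp$k,
                  p_num = p_num, p_den = p_den, ratio_k = p_num / p_den,
                  orig = seq_len(nrow(pp)))
  setorder(w, patient_id, k)
  w[, sw_k := cumprod(ratio_k), by = patient_id]
  w[, sw_baseline := ratio_k[1L], by = patient_id]
  tp <- models$spec$truncation_percentiles
  if (!is.null(tp)) {
    for (col in c("ratio_k", "sw_k", "sw_baseline")) {
      b <- quantile(w[[col]], tp)
      w[, (col) := pmin(pmax(get(col), b[1L]), b[2L])]
    }
  }
  setorder(w, orig)
  w[, orig := NULL]
  w[]
}
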