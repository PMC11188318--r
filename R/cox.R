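# Crude and weighted time-varying Cox regression on counting-process
# person-period rows, weighted Kaplan-Meier curves, subgroup and
# interaction analyses, and the sensitivity cohorts.

#' Time-varying Cox regression of the four class contrasts versus BB
#'
#' Partial-likelihood fit (Efron ties) on `(start_day, stop_day]` risk sets
#' from the person-period rows. Unweighted fits give crude hazard ratios
#' with model-based variance; supplying stabilized weights gives the
#' marginal-structural-model fit with patient-clustered robust (sandwich)
#' variance, which the weighting requires.
#'
#' @param pp Person-period table (`patient_id`, `start_day`, `stop_day`,
#'   `event`, `exposure_class`).
#' @param weights Optional numeric vector aligned row-wise with `pp`.
#' @return data.table with one row per non-reference class: `comparison`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`, `weighted`, `n_events`,
#'   `variance_type`. The `coxph` fit is attached as attribute `"fit"`.
#' @export
fit_cox <- function(pp, weights = NULL) {
  pp <- as.data.table(pp)
  if (any(pp$stop_day <= pp$start_day))
    stop("zero- or negative-length person-period row(s)")
  if (sum(pp$event) == 0L) stop("no events in the data")
  dat <- copy(pp)
  dat[, exposure_class := exposure_factor(exposure_class)]
  weighted <- !is.null(weights)
  if (weighted) {
    stopifnot(length(weights) == nrow(dat), all(weights > 0))
    dat[, .w := weights]
    fit <- survival::coxph(
      survival::Surv(start_day, stop_day, event) ~ exposure_class,
      data = dat, weights = .w, cluster = patient_id, ties = "efron")
  } else {
    fit <- survival::coxph(
      survival::Surv(start_day, stop_day, event) ~ exposure_class,
      data = dat, ties = "efron")
  }
  s <- summary(fit)$coefficients
  se <- if (weighted) s[, "robust se"] else s[, "se(coef)"]
  b <- s[, "coef"]
  z <- qnorm(0.975)
  out <- data.table(
    comparison = paste(sub("^exposure_class", "", rownames(s)), "vs BB"),
    hr = exp(b),
    ci_low = exp(b - z * se),
    ci_high = exp(b + z * se),
    p_value = 2 * pnorm(-abs(b / se)),
    weighted = weighted,
    n_events = sum(pp$event),
    variance_type = if (weighted) "robust" else "model"
  )
  setattr(out, "fit", fit)
  out
}

#' (Weighted) Kaplan-Meier curve per exposure class
#'
#' Product-limit estimator over the counting-process rows, optionally
#' weighted by the stabilized weights. Curves start at 1 and are
#' non-increasing.
#'
#' @inheritParams fit_cox
#' @return data.table: `exposure_class`, `day`, `surv`, `n_risk`.
#' @export
estimate_km <- function(pp, weights = NULL) {
  dat <- as.data.table(pp)
  dat[, exposure_class := exposure_factor(exposure_class)]
  if (is.null(weights)) weights <- rep(1, nrow(dat))
  dat[, .w := weights]
  sf <- survival::survfit(
    survival::Surv(start_day, stop_day, event) ~ exposure_class,
    data = dat, weights = .w)
  strata <- if (is.null(sf$strata)) {
    rep(levels(dat$exposure_class)[1L], length(sf$time))
  } else {
    rep(sub("^exposure_class=", "", names(sf$strata)), sf$strata)
  }
  data.table(exposure_class = strata, day = sf$time, surv = sf$surv,
             n_risk = sf$n.risk)
}

#' Subgroup hazard ratios reusing the overall weights
#'
#' Repeats crude and weighted Cox regression within each level of a
#' patient-level subgroup variable. The stabilized weights are *not*
#' refitted per subgroup: the overall weights are reused, as in the
#' original analysis design.
#'
#' @param pp Person-period table including the subgroup column.
#' @param weights Stabilized weights aligned with `pp` (or `NULL` for
#'   crude-only).
#' @param variable Name of the subgroup column in `pp`.
#' @return data.table of [fit_cox()] rows with `subgroup_variable`,
#'   `subgroup_level` prepended.
#' @export
run_subgroups <- function(pp, weights = NULL, variable) {
  pp <- as.data.table(pp)
  stopifnot(variable %in% names(pp))
  levs <- sort(unique(as.character(pp[[variable]])))
  out <- lapply(levs, function(lv) {
    rows <- which(as.character(pp[[variable]]) == lv)
    res <- tryCatch(suppressWarnings({
      crude <- fit_cox(pp[rows], weights = NULL)
      if (!is.null(weights))
        rbind(crude, fit_cox(pp[rows], weights = weights[rows]))
      else crude
    }), error = function(e)
      data.table(comparison = NA_character_, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                 weighted = NA, n_events = NA_integer_,
                 variance_type = NA_character_))
    cbind(data.table(subgroup_variable = variable, subgroup_level = lv), res)
  })
  rbindlist(out)
}

#' Exposure-by-subgroup interaction test
#'
#' Weighted Cox model containing exposure, the subgroup variable, and their
#' product terms; Wald p-value per product term and an overall Wald test of
#' the interaction block, using robust patient-clustered variance.
#'
#' @inheritParams run_subgroups
#' @return List: `terms` (data.table: `term`, `estimate`, `se`, `p_value`)
#'   and `overall` (data.table: `statistic`, `df`, `p_value`).
#' @export
test_interaction <- function(pp, weights = NULL, variable) {
  pp <- as.data.table(pp)
  stopifnot(variable %in% names(pp))
  if (length(unique(pp[[variable]])) < 2L)
    stop("subgroup variable '", variable, "' is constant")
  dat <- copy(pp)
  dat[, exposure_class := exposure_factor(exposure_class)]
  if (is.null(weights)) weights <- rep(1, nrow(dat))
  dat[, .w := weights]
  f <- as.formula(paste(
    "survival::Surv(start_day, stop_day, event) ~ exposure_class *",
    variable))
  fit <- survival::coxph(f, data = dat, weights = .w, cluster = patient_id,
                         ties = "efron")
  b <- coef(fit)
  V <- vcov(fit)                        # robust when cluster is given
  ix <- grep(":", names(b))
  if (!length(ix)) stop("no interaction terms estimated")
  se <- sqrt(diag(V)[ix])
  terms <- data.table(term = names(b)[ix], estimate = b[ix], se = se,
                      p_value = 2 * pnorm(-abs(b[ix] / se)))
  W <- drop(t(b[ix]) %*% solve(V[ix, ix, drop = FALSE]) %*% b[ix])
  list(terms = terms,
       overall = data.table(statistic = W, df = length(ix),
                            p_value = pchisq(W, length(ix),
                                             lower.tail = FALSE)))
}

#' Sensitivity cohorts 3-6
#'
#' Splits each analysis cohort by whether the patient ever switched or
#' received an add-on during follow-up: cohorts 3/4 are the cohort-1/2
#' members with neither, cohorts 5/6 those with either. Within each
#' cohort-1/2 pair the split is a disjoint partition.
#'
#' @param cohort1,cohort2 Member tables from [build_cohorts()].
#' @param summaries Follow-up summaries covering both cohorts.
#' @return Named list of member tables `cohort3` .. `cohort6`.
#' @export
build_sensitivity_cohorts <- function(cohort1, cohort2, summaries) {
  clean <- summaries[switched == FALSE & is.na(addon_day), patient_id]
  list(cohort3 = cohort1[patient_id %in% clean],
       cohort4 = cohort2[patient_id %in% clean],
       cohort5 = cohort1[!patient_id %in% clean],
       cohort6 = cohort2[!patient_id %in% clean])
}

#' Truncate follow-up to a sensitivity horizon
#'
#' Caps each summary at `horizon_days` (1,800 days for the 5-year grid, the
#' default 3,780 for 10 years); events beyond the horizon become
#' administrative censorings. Person-periods are re-derived from the
#' truncated summaries.
#'
#' @param summaries Follow-up summary table.
#' @param horizon_days Horizon in days.
#' @return Truncated copy of `summaries`.
#' @export
truncate_followup <- function(summaries, horizon_days) {
  s <- copy(summaries)
  trunc <- s$followup_days > horizon_days
  s[trunc, `:=`(followup_days = as.integer(horizon_days),
                event = FALSE, event_day = NA_integer_,
                censor_reason = "MAX_FOLLOWUP")]
  s[]
}
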