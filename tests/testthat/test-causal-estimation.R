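sp_cache <- NULL
get_sp <- function() {
  if (is.null(sp_cache))
    sp_cache <<- simulate_person_periods(sim_config(n_patients = 3000L,
                                                    seed = 101L))
  sp_cache
}

test_that("propensity models recover the planted assignment coefficients", {
  sp <- simulate_person_periods(sim_config(n_patients = 20000L, seed = 55L))
  base <- sp$pp[k == 0L]
  fits <- fit_propensity_models(base, weight_model_spec(1L))
  cf <- coef(fits$denominator)
  se <- summary(fits$denominator)$standard.errors
  truth <- sim_config()$class_assignment
  for (cl in rownames(cf)) {
    expect_lt(abs(cf[cl, "diabetes_rxTRUE"] - truth[[cl]]["diabetes"]),
              3 * se[cl, "diabetes_rxTRUE"])
    expect_lt(abs(cf[cl, "sexmale"] - truth[[cl]]["male"]),
              3 * se[cl, "sexmale"])
  }
})

test_that("a null assignment covariate gets a near-zero coefficient", {
  # RA drug use does not influence class choice in this configuration
  flat_ra <- lapply(sim_config()$class_assignment,
                    function(x) { x["ra"] <- 0; x })
  sp <- simulate_person_periods(sim_config(n_patients = 20000L, seed = 56L,
                                           class_assignment = flat_ra))
  fits <- fit_propensity_models(sp$pp[k == 0L], weight_model_spec(1L))
  cf <- coef(fits$denominator)
  se <- summary(fits$denominator)$standard.errors
  for (cl in rownames(cf))
    expect_lt(abs(cf[cl, "ra_rxTRUE"]), 3 * se[cl, "ra_rxTRUE"])
})

test_that("degenerate propensity inputs are rejected", {
  sp <- get_sp()
  single <- sp$pp[exposure_class == "BB"]
  expect_error(fit_propensity_models(single, weight_model_spec(1L)),
               "at least two")
  pp_na <- data.table::copy(sp$pp)
  pp_na$age[1] <- NA   # first row is an index-interval row
  expect_error(fit_propensity_models(pp_na, weight_model_spec(1L)),
               "missing values")
  expect_error(fit_propensity_models(sp$pp[, !"sex"],
                                     weight_model_spec(1L)),
               "missing covariate")
})

test_that("identical numerator and denominator models give unit weights", {
  sp <- get_sp()
  models <- fit_propensity_models(sp$pp, weight_model_spec(1L))
  models$denominator <- models$numerator
  w <- compute_stabilized_weights(sp$pp, models)
  expect_equal(w$sw_baseline, rep(1, nrow(sp$pp)))
  expect_equal(w$sw_k, rep(1, nrow(sp$pp)))
})

test_that("stabilized weights match a hand-computed product on a toy set", {
  sp <- get_sp()
  toy <- sp$pp[patient_id %in% unique(patient_id)[1:2]]
  models <- fit_propensity_models(sp$pp, weight_model_spec(1L))
  w <- compute_stabilized_weights(toy, models)
  # manual computation straight from the two prediction matrices
  pn <- predict(models$numerator, newdata = toy, type = "probs")
  pd <- predict(models$denominator, newdata = toy, type = "probs")
  j <- match(toy$exposure_class, colnames(pn))
  r_manual <- pn[cbind(seq_len(nrow(toy)), j)] /
    pd[cbind(seq_len(nrow(toy)), j)]
  expect_equal(w$sw_baseline, r_manual)
  for (pid in unique(toy$patient_id)) {
    rows <- which(toy$patient_id == pid)
    expect_equal(w$sw_k[rows], cumprod(r_manual[rows]))
  }
  # per-class probabilities sum to one within each model's prediction
  expect_equal(unname(rowSums(pn)), rep(1, nrow(toy)), tolerance = 1e-8)
  expect_equal(unname(rowSums(pd)), rep(1, nrow(toy)), tolerance = 1e-8)
})

test_that("unit weights reproduce the crude Cox fit to 10 significant figures", {
  sp <- get_sp()
  crude <- fit_cox(sp$pp)
  unit <- fit_cox(sp$pp, weights = rep(1, nrow(sp$pp)))
  b1 <- coef(attr(crude, "fit")); b2 <- coef(attr(unit, "fit"))
  expect_equal(b1, b2, tolerance = 1e-10)
  expect_equal(crude$hr, unit$hr, tolerance = 1e-10)
  # variance conventions differ by design
  expect_equal(crude$variance_type, rep("model", 4))
  expect_equal(unit$variance_type, rep("robust", 4))
})

test_that("degenerate survival inputs are rejected", {
  sp <- get_sp()
  no_ev <- data.table::copy(sp$pp)[, event := FALSE]
  expect_error(fit_cox(no_ev), "no events")
  zero_len <- data.table::copy(sp$pp)
  zero_len$stop_day[1] <- zero_len$start_day[1]
  expect_error(fit_cox(zero_len), "zero-")
})

test_that("weighted KM with integer weights equals KM on replicated rows", {
  sp <- get_sp()
  toy <- sp$pp[patient_id %in% unique(patient_id)[1:40]]
  set.seed(9)
  wt_pat <- data.table::data.table(
    patient_id = unique(toy$patient_id),
    w = sample(1:3, length(unique(toy$patient_id)), replace = TRUE))
  toyw <- merge(toy, wt_pat, by = "patient_id", sort = FALSE)
  km_w <- estimate_km(toyw, weights = toyw$w)
  # replicate each patient's rows w times under distinct ids
  rep_rows <- toyw[rep(seq_len(.N), w)]
  rep_rows[, rep_ix := seq_len(.N), by = .(patient_id, k)]
  rep_rows[, patient_id := paste0(patient_id, "_", rep_ix)]
  km_r <- estimate_km(rep_rows)
  expect_equal(km_w[, .(exposure_class, day, surv)],
               km_r[, .(exposure_class, day, surv)], tolerance = 1e-12)
})

test_that("unweighted KM equals the reference product-limit estimator on
           collapsed patient-level data", {
  sp <- get_sp()
  pp <- sp$pp
  km <- estimate_km(pp)
  collapsed <- pp[, .(time = max(stop_day), status = any(event),
                      exposure_class = exposure_class[1]), by = patient_id]
  ref <- survival::survfit(survival::Surv(time, status) ~ exposure_class,
                           data = collapsed)
  ref_dt <- data.table::data.table(
    exposure_class = rep(sub("^exposure_class=", "", names(ref$strata)),
                         ref$strata),
    day = ref$time, surv_ref = ref$surv)
  m <- merge(km, ref_dt, by = c("exposure_class", "day"))
  expect_gt(nrow(m), 100L)
  expect_equal(m$surv, m$surv_ref, tolerance = 1e-12)
  expect_true(all(km[, .(mono = all(diff(surv) <= 1e-12)),
                     by = exposure_class]$mono))
})

test_that("subgroup machinery reuses weights and respects symmetry", {
  sp <- get_sp()
  pp <- data.table::copy(sp$pp)
  models <- fit_propensity_models(pp, weight_model_spec(1L))
  w <- compute_stabilized_weights(pp, models)
  # a constant subgroup reproduces the overall fit
  pp[, whole := "all"]
  sub <- run_subgroups(pp, weights = w$sw_baseline, variable = "whole")
  overall <- rbind(fit_cox(pp), fit_cox(pp, weights = w$sw_baseline))
  expect_equal(sub$hr, overall$hr)
  # two identical half-samples give identical estimates
  ppA <- data.table::copy(pp)[, `:=`(patient_id = paste0(patient_id, "A"),
                                     g = "A")]
  ppB <- data.table::copy(pp)[, `:=`(patient_id = paste0(patient_id, "B"),
                                     g = "B")]
  both <- rbind(ppA, ppB)
  sub2 <- run_subgroups(both, weights = rep(w$sw_baseline, 2), variable = "g")
  expect_equal(sub2[subgroup_level == "A", hr],
               sub2[subgroup_level == "B", hr])
  expect_error(test_interaction(pp, w$sw_baseline, "whole"), "constant")
})

test_that("sensitivity cohorts partition each analysis cohort", {
  sim <- simulate_population(sim_config(n_patients = 800L, seed = 21L))
  ch <- build_cohorts(sim$db)
  sc <- build_sensitivity_cohorts(ch$cohort1, ch$cohort2, ch$summaries)
  expect_equal(sort(c(sc$cohort3$patient_id, sc$cohort5$patient_id)),
               sort(ch$cohort1$patient_id))
  expect_length(intersect(sc$cohort3$patient_id, sc$cohort5$patient_id), 0L)
  expect_equal(sort(c(sc$cohort4$patient_id, sc$cohort6$patient_id)),
               sort(ch$cohort2$patient_id))
  # with switching and add-ons disabled, every member is "clean"
  sim0 <- simulate_population(sim_config(n_patients = 300L, seed = 22L,
                                         switch_probability = 0,
                                         addon_probability = 0))
  ch0 <- build_cohorts(sim0$db)
  sc0 <- build_sensitivity_cohorts(ch0$cohort1, ch0$cohort2, ch0$summaries)
  expect_equal(nrow(sc0$cohort5), 0L)
  expect_equal(sort(sc0$cohort3$patient_id), sort(ch0$cohort1$patient_id))
  # horizon truncation never increases anyone's rows
  pp <- build_person_periods(sim$db, ch$summaries)
  st <- truncate_followup(ch$summaries, 1800L)
  expect_true(all(st$followup_days <= ch$summaries$followup_days))
  expect_true(all(st$followup_days <= 1800L))
})

test_that("baseline table reproduces hand-computed chi-square statistics", {
  bl <- data.table::data.table(
    exposure_class = rep(c("BB", "THIAZIDE"), c(40, 60)),
    sex = c(rep(c("male", "female"), c(10, 30)),
            rep(c("male", "female"), c(30, 30))),
    age = c(rnorm(40, 55, 5), rnorm(60, 60, 5)))
  out <- summarize_baseline(bl, categorical = "sex", continuous = "age")
  ref <- chisq.test(table(bl$sex, bl$exposure_class))
  got <- out$tests[variable == "sex"]
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  ref_w <- oneway.test(age ~ exposure_class, data = bl, var.equal = FALSE)
  expect_equal(out$tests[variable == "age", p_value], ref_w$p.value)
  # column percentages: 10/40 males in BB
  expect_equal(out$table[variable == "sex" & level == "male" &
                           exposure_class == "BB", pct], 25.0)
  expect_message(summarize_baseline(bl[exposure_class == "BB"],
                                    categorical = "sex",
                                    continuous = "age"),
                 "skipped")
})
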