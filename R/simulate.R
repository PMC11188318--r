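# Discrete-time simulator of a community-pharmacy dispensing database with
# known treatment effects. Class choice depends on baseline covariates and
# comorbidity drug use (confounding by indication); events arise from a
# complementary log-log hazard on the 180-day grid so planted coefficients
# are log hazard ratios on the same time resolution the Cox analysis uses.

SIM_CLASS_CODES <- c(BB = "C07AB02", ACEI = "C09AA02", ARB = "C09CA01",
                     CCB = "C08CA01", THIAZIDE = "C03AA03")
SIM_COMORB_CODES <- c(diabetes = "A10BA02", ra = "M01CB01",
                      asthma_copd = "R03AC02")

#' Simulation configuration
#'
#' Defaults emulate the structure of a Dutch community-pharmacy dispensing
#' database: five-class antihypertensive initiation whose class choice
#' depends on sex, age, calendar period and comorbidity drug use; planted
#' hazard ratios versus beta-blockers; adherence gaps, switches and add-ons;
#' co-medication streams that trigger exclusions; and outcome-drug
#' dispensings emitted after events. Default planted hazard ratios mirror
#' the magnitudes the pipeline is designed to detect (ARB 0.79,
#' thiazide 0.80, CCB 1.10, ACEI 1.00, all versus BB).
#'
#' @param n_patients Number of patients.
#' @param seed Integer RNG seed; the whole database is reproducible from it.
#' @param study_start,study_end Administrative window of the database.
#' @param class_assignment Named list (per non-reference class) of named
#'   coefficient vectors over `(intercept, male, age10, period2, period3,
#'   diabetes, ra, asthma_copd)` in a multinomial logit versus BB. `age10`
#'   is (age - 57)/10; `period2`/`period3` indicate index years 2000-2009
#'   and 2010-2020.
#' @param true_log_hr Named log hazard ratios versus BB; BB must be 0.
#' @param baseline_interval_hazard Per-180-day event probability under BB
#'   with no comorbidity drug use.
#' @param confounder_hazard Named log-hazard effects of current diabetes /
#'   RA / asthma-COPD drug use.
#' @param comorbidity_baseline Named baseline prevalence of each comorbidity
#'   drug stream.
#' @param comorbidity_onset Named per-interval onset probability of each
#'   stream (streams never stop once started).
#' @param gap_probability Per-180-day-interval probability of a refill gap.
#' @param gap_min,gap_mean Gap length: `gap_min` plus a geometric tail with
#'   this mean (days); the tail gives some gaps > 180 days, i.e. natural
#'   discontinuation.
#' @param switch_probability,addon_probability Per-interval probabilities of
#'   a treatment switch (stop refills, different class within 180 days) and
#'   of an add-on (second class while refills continue).
#' @param refill_days_covered Days covered per dispensing (Dutch chronic
#'   refill convention: 90).
#' @param lipid_rx_probability,prior_cdt_probability,fixed_combo_probability,chronic_exclusion_probability
#'   Per-patient probabilities of co-medication patterns that trigger the
#'   corresponding exclusions.
#' @param outcome_miss_probability Probability an event emits no qualifying
#'   outcome dispensings (proxy misclassification; default 0 so the proxy
#'   has sensitivity 1 and estimator behavior is isolated from proxy error).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000L,
                       seed = 1L,
                       study_start = as.Date("1996-01-01"),
                       study_end = as.Date("2020-12-31"),
                       class_assignment = list(
                         ACEI = c(intercept = -0.45, male = 0.80,
                                  age10 = 0.05, period2 = 0.10,
                                  period3 = 0.35, diabetes = 2.18,
                                  ra = 0.46, asthma_copd = 0.38),
                         ARB = c(intercept = -1.55, male = 0.50,
                                 age10 = 0.05, period2 = 0.30,
                                 period3 = 0.55, diabetes = 1.40,
                                 ra = 0.46, asthma_copd = 0.49),
                         CCB = c(intercept = -1.60, male = 0.35,
                                 age10 = 0.18, period2 = -0.40,
                                 period3 = 0.80, diabetes = 0.43,
                                 ra = 1.06, asthma_copd = 0.57),
                         THIAZIDE = c(intercept = -0.50, male = -0.05,
                                      age10 = 0.28, period2 = 0.15,
                                      period3 = 0.05, diabetes = 0.63,
                                      ra = 0.13, asthma_copd = 0.50)
                       ),
                       true_log_hr = c(BB = 0, ACEI = 0, ARB = log(0.79),
                                       CCB = log(1.10),
                                       THIAZIDE = log(0.80)),
                       baseline_interval_hazard = 0.008,
                       confounder_hazard = c(diabetes = log(2.5),
                                             ra = log(1.5),
                                             asthma_copd = log(2.0)),
                       comorbidity_baseline = c(diabetes = 0.061, ra = 0.010,
                                                asthma_copd = 0.080),
                       comorbidity_onset = c(diabetes = 0.004, ra = 0.001,
                                             asthma_copd = 0.004),
                       gap_probability = 0.40,
                       gap_min = 15L, gap_mean = 115,
                       switch_probability = 0.030,
                       addon_probability = 0.020,
                       refill_days_covered = 90L,
                       lipid_rx_probability = 0.03,
                       prior_cdt_probability = 0.02,
                       fixed_combo_probability = 0.01,
                       chronic_exclusion_probability = 0.01,
                       outcome_miss_probability = 0) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  probs <- c(cfg$baseline_interval_hazard, cfg$comorbidity_baseline,
             cfg$comorbidity_onset, cfg$gap_probability,
             cfg$switch_probability, cfg$addon_probability,
             cfg$lipid_rx_probability, cfg$prior_cdt_probability,
             cfg$fixed_combo_probability, cfg$chronic_exclusion_probability,
             cfg$outcome_miss_probability)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$study_end > cfg$study_start,
            isTRUE(all.equal(unname(cfg$true_log_hr["BB"]), 0)),
            setequal(names(cfg$class_assignment),
                     setdiff(class_levels(), "BB")))
  cfg
}

cloglog <- function(p) log(-log(1 - p))

# Per-interval event probability under the complementary log-log hazard.
interval_event_prob <- function(h0, log_hr, conf_lp) {
  1 - exp(-exp(cloglog(h0) + log_hr + conf_lp))
}

# Multinomial-logit class assignment on the design columns.
assign_classes <- function(male, age, period2, period3, dia, ra, ast, cfg) {
  n <- length(male)
  X <- cbind(intercept = 1, male = male, age10 = (age - 57) / 10,
             period2 = period2, period3 = period3,
             diabetes = dia, ra = ra, asthma_copd = ast)
  lp <- matrix(0, n, 5L, dimnames = list(NULL, class_levels()))
  for (cl in names(cfg$class_assignment))
    lp[, cl] <- X %*% cfg$class_assignment[[cl]][colnames(X)]
  pr <- exp(lp) / rowSums(exp(lp))
  if (any(apply(pr, 2L, max) > 0.999))
    warning("degenerate class assignment: almost all mass on one class")
  u <- runif(n)
  cum <- t(apply(pr, 1L, cumsum))
  cls <- class_levels()[max.col(u < cum, ties.method = "first")]
  list(class = cls, prob = pr)
}

# Monotone comorbidity-flag trajectories: n x K logical matrices.
comorb_trajectories <- function(n, K, cfg) {
  lapply(setNames(names(cfg$comorbidity_baseline),
                  names(cfg$comorbidity_baseline)), function(nm) {
    base <- rbinom(n, 1L, cfg$comorbidity_baseline[[nm]])
    onset <- matrix(rbinom(n * K, 1L, cfg$comorbidity_onset[[nm]]), n, K)
    onset[, 1L] <- base
    for (j in 2:K) onset[, j] <- onset[, j] | onset[, j - 1L]
    onset > 0
  })
}

# Latent event interval (0-based) and day-within-interval for each patient.
latent_events <- function(cls, flags, K, cfg) {
  n <- length(cls)
  conf_lp <- matrix(0, n, K)
  for (nm in names(flags))
    conf_lp <- conf_lp + cfg$confounder_hazard[[nm]] * flags[[nm]]
  lhr <- cfg$true_log_hr[cls]
  ev_k <- rep(NA_integer_, n)
  for (k in seq_len(K)) {
    p <- interval_event_prob(cfg$baseline_interval_hazard, lhr, conf_lp[, k])
    hit <- is.na(ev_k) & runif(n) < p
    ev_k[hit] <- k - 1L
  }
  list(ev_k = ev_k,
       ev_rel = ifelse(is.na(ev_k), NA_integer_,
                       180L * ev_k + sample.int(180L, n, replace = TRUE) - 1L))
}

#' Simulate a prescription database with planted effects
#'
#' Generates patients, assigns a monotherapy class by multinomial logit on
#' baseline covariates (confounding by indication), emits two or more years
#' of pre-index background dispensings plus class refills with gaps,
#' switches and add-ons, evolves comorbidity drug streams per 180-day
#' interval, draws events from the complementary log-log hazard, and emits
#' qualifying outcome-drug dispensings after each event. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `db` (an `rx_db`) and `truth` (a `sim_truth`: planted
#'   hazard ratios, per-patient assigned class, latent event day and
#'   confounder history).
#' @export
simulate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_patients
  K <- 21L
  start_day <- day_of(config$study_start)
  end_day <- day_of(config$study_end)

  sexes <- ifelse(runif(n) < 0.45, "male", "female")
  age <- pmin(95, pmax(16, round(rnorm(n, 57, 13.5))))
  index_day <- start_day + 730L +
    sample.int(end_day - start_day - 930L, n, replace = TRUE)
  birth_day <- index_day - round(age * 365.25) -
    sample.int(365L, n, replace = TRUE) + 1L
  year <- as.integer(format(as.Date(index_day, origin = "1970-01-01"), "%Y"))
  p2 <- as.numeric(year >= 2000 & year <= 2009)
  p3 <- as.numeric(year >= 2010)

  flags <- comorb_trajectories(n, K, config)
  dia0 <- flags$diabetes[, 1L]; ra0 <- flags$ra[, 1L]
  ast0 <- flags$asthma_copd[, 1L]
  asg <- assign_classes(as.numeric(sexes == "male"), age, p2, p3,
                        as.numeric(dia0), as.numeric(ra0), as.numeric(ast0),
                        config)
  cls <- asg$class
  lat <- latent_events(cls, flags, K, config)

  # per-patient protocol processes (1-based interval of first occurrence)
  switch_k <- if (config$switch_probability > 0)
    rgeom(n, config$switch_probability) + 1L else rep(NA_integer_, n)
  switch_k[switch_k > K] <- NA_integer_
  addon_k <- if (config$addon_probability > 0)
    rgeom(n, config$addon_probability) + 1L else rep(NA_integer_, n)
  addon_k[addon_k > K] <- NA_integer_

  excl_lipid <- runif(n) < config$lipid_rx_probability
  excl_prior <- runif(n) < config$prior_cdt_probability
  excl_combo <- runif(n) < config$fixed_combo_probability
  excl_chronic <- runif(n) < config$chronic_exclusion_probability
  miss_event <- runif(n) < config$outcome_miss_probability

  p_gap_refill <- 1 - (1 - config$gap_probability)^
    (config$refill_days_covered / 180)
  ids <- sprintf("P%06d", seq_len(n))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- index_day[i]
    rec_end <- min(end_day, idx + 3780L + 90L)
    entry <- idx - 730L - sample.int(120L, 1L)
    day <- seq(entry, rec_end, by = 120L)
    code <- rep("N02BE01", length(day))
    cov <- rep(30L, length(day))

    refill_end <- if (!is.na(switch_k[i]))
      idx + 180L * switch_k[i] + sample.int(60L, 1L) else rec_end
    t <- idx; sched <- integer(0)
    while (t < refill_end) {
      sched <- c(sched, t)
      t <- t + config$refill_days_covered
      if (runif(1) < p_gap_refill)
        t <- t + config$gap_min + rgeom(1L, 1 / config$gap_mean)
    }
    day <- c(day, sched)
    code <- c(code, rep(SIM_CLASS_CODES[[cls[i]]], length(sched)))
    cov <- c(cov, rep(config$refill_days_covered, length(sched)))

    if (!is.na(switch_k[i]) && length(sched)) {
      new_cls <- sample(setdiff(class_levels(), cls[i]), 1L)
      sw_start <- max(sched) + config$refill_days_covered +
        sample(30:150, 1L)
      if (sw_start < rec_end) {
        sw_days <- seq(sw_start, rec_end, by = config$refill_days_covered)
        day <- c(day, sw_days)
        code <- c(code, rep(SIM_CLASS_CODES[[new_cls]], length(sw_days)))
        cov <- c(cov, rep(config$refill_days_covered, length(sw_days)))
      }
    }
    if (!is.na(addon_k[i])) {
      a_day <- idx + 180L * addon_k[i] + sample.int(180L, 1L) - 1L
      if (a_day < refill_end && a_day < rec_end) {
        add_cls <- sample(setdiff(class_levels(), cls[i]), 1L)
        a_days <- seq(a_day, min(a_day + 360L, rec_end),
                      by = config$refill_days_covered)
        day <- c(day, a_days)
        code <- c(code, rep(SIM_CLASS_CODES[[add_cls]], length(a_days)))
        cov <- c(cov, rep(config$refill_days_covered, length(a_days)))
      }
    }
    for (nm in names(flags)) {
      traj <- flags[[nm]][i, ]
      if (!any(traj)) next
      st <- if (traj[1L]) idx - sample(180:720, 1L)
            else idx + 180L * (which(traj)[1L] - 1L) + sample.int(90L, 1L)
      if (st > rec_end) next
      c_days <- seq(st, rec_end, by = 90L)
      day <- c(day, c_days)
      code <- c(code, rep(SIM_COMORB_CODES[[nm]], length(c_days)))
      cov <- c(cov, rep(90L, length(c_days)))
    }
    if (!is.na(lat$ev_rel[i]) && !miss_event[i]) {
      e1 <- idx + lat$ev_rel[i]
      e2 <- e1 + sample(10:60, 1L)
      keep <- c(e1, e2)[c(e1, e2) <= rec_end]
      day <- c(day, keep)
      code <- c(code, rep("B01AC06", length(keep)))
      cov <- c(cov, rep(30L, length(keep)))
    }
    if (excl_prior[i]) {
      pd <- idx - sample(100:700, 1L)
      day <- c(day, pd, pd + 30L)
      code <- c(code, "B01AC06", "B01AC06"); cov <- c(cov, 30L, 30L)
    }
    if (excl_lipid[i]) {
      day <- c(day, idx + sample.int(365L, 1L))
      code <- c(code, "C10AA01"); cov <- c(cov, 90L)
    }
    if (excl_combo[i]) {
      day <- c(day, idx + 60L, idx + 150L)
      code <- c(code, "C09BA02", "C09BA02"); cov <- c(cov, 90L, 90L)
    }
    if (excl_chronic[i]) {
      ch_code <- sample(c("C01AA05", "N02CC01", "H03AA01"), 1L)
      day <- c(day, idx - 300L, idx - 150L)
      code <- c(code, ch_code, ch_code); cov <- c(cov, 90L, 90L)
    }
    recs[[i]] <- data.table(patient_id = ids[i], disp_day = as.integer(day),
                            atc_code = code, days_covered = as.integer(cov))
  }
  records <- rbindlist(recs)
  records[, dispense_date := as.Date(disp_day, origin = "1970-01-01")]
  patients <- data.table(patient_id = ids, sex = sexes,
                         birth_date = as.Date(birth_day,
                                              origin = "1970-01-01"))
  db <- rx_db(patients,
              records[, .(patient_id, dispense_date, atc_code, days_covered)])
  truth <- structure(list(
    true_hr = exp(config$true_log_hr),
    true_log_hr = config$true_log_hr,
    patients = data.table(
      patient_id = ids, exposure_class = cls, sex = sexes, age = age,
      index_day = index_day, diabetes0 = dia0, ra0 = ra0,
      asthma_copd0 = ast0, latent_event_rel = lat$ev_rel,
      switch_k = switch_k, addon_k = addon_k),
    config = config), class = "sim_truth")
  list(db = db, truth = truth)
}

#' Simulate person-period data directly (reduced form)
#'
#' Shares the class-assignment and complementary log-log hazard mechanism
#' with [simulate_population()] but emits analysis-ready person-period rows
#' directly, with non-informative administrative and protocol censoring.
#' Used for estimator calibration at large replicate counts, where emitting
#' and re-parsing dispensing records adds nothing to what is being tested.
#'
#' @param config A [sim_config()] (`n_patients`, `seed`, assignment, hazard
#'   and confounder fields are honored).
#' @param protocol_censor_probability Per-interval probability follow-up
#'   ends for protocol reasons (discontinuation/add-on), independent of
#'   everything else.
#' @return List: `pp` (person-period data.table with covariate columns
#'   `sex`, `age`, `calendar_period` attached) and `truth`.
#' @export
simulate_person_periods <- function(config = sim_config(),
                                    protocol_censor_probability = 0.10) {
  set.seed(config$seed)
  n <- config$n_patients
  K <- 21L
  sexes <- ifelse(runif(n) < 0.45, "male", "female")
  age <- pmin(95, pmax(18, round(rnorm(n, 57, 13.5))))
  period <- sample(c("1996-2000", "2000-2010", "2010-2020"), n,
                   replace = TRUE, prob = c(0.07, 0.41, 0.52))
  flags <- comorb_trajectories(n, K, config)
  asg <- assign_classes(as.numeric(sexes == "male"), age,
                        as.numeric(period == "2000-2010"),
                        as.numeric(period == "2010-2020"),
                        as.numeric(flags$diabetes[, 1L]),
                        as.numeric(flags$ra[, 1L]),
                        as.numeric(flags$asthma_copd[, 1L]), config)
  cls <- asg$class
  lat <- latent_events(cls, flags, K, config)
  avail_k <- sample(6:21, n, replace = TRUE)            # admin horizon
  prot_k <- if (protocol_censor_probability > 0)
    rgeom(n, protocol_censor_probability) + 1L else rep(K + 1L, n)
  cens_k <- pmin(avail_k, prot_k, K)                    # rows available
  ev_k <- lat$ev_k
  has_event <- !is.na(ev_k) & ev_k < cens_k
  last_k <- ifelse(has_event, ev_k, cens_k - 1L)        # 0-based last row
  nrow_i <- last_k + 1L
  id <- rep(seq_len(n), nrow_i)
  k <- sequence(nrow_i) - 1L
  last <- k == rep(last_k, nrow_i)
  event_day_in <- 180L * ev_k +
    sample.int(180L, n, replace = TRUE)                 # stop of event row
  stop_day <- 180L * (k + 1L)
  ev_rows <- which(last & rep(has_event, nrow_i))
  stop_day[ev_rows] <- event_day_in[id[ev_rows]]
  flag_at <- function(m) m[cbind(id, k + 1L)]
  pp <- data.table(
    patient_id = sprintf("P%06d", id),
    k = k, start_day = 180L * k, stop_day = stop_day,
    exposure_class = cls[id],
    adherence_180 = round(rbeta(length(id), 9, 1), 4),
    diabetes_rx = flag_at(flags$diabetes),
    ra_rx = flag_at(flags$ra),
    asthma_copd_rx = flag_at(flags$asthma_copd),
    event = last & rep(has_event, nrow_i),
    sex = sexes[id], age = age[id], calendar_period = period[id]
  )
  truth <- structure(list(
    true_hr = exp(config$true_log_hr),
    true_log_hr = config$true_log_hr,
    patients = data.table(patient_id = sprintf("P%06d", seq_len(n)),
                          exposure_class = cls, sex = sexes, age = age,
                          diabetes0 = flags$diabetes[, 1L],
                          ra0 = flags$ra[, 1L],
                          asthma_copd0 = flags$asthma_copd[, 1L],
                          latent_event_rel = lat$ev_rel),
    config = config), class = "sim_truth")
  list(pp = pp, truth = truth)
}
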