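# Patient-level baseline covariates and the baseline-characteristics table
# with Pearson chi-square / Welch ANOVA tests across exposure classes.

#' Assign calendar period
#'
#' The three-level period factor used throughout: 1996-2000, 2000-2010,
#' 2010-2020. Boundary years go to the later period (2000 is in 2000-2010).
#'
#' @param year Integer calendar years.
#' @return Factor with the three period levels.
#' @export
calendar_period_of <- function(year) {
  factor(ifelse(year <= 1999, "1996-2000",
                ifelse(year <= 2009, "2000-2010", "2010-2020")),
         levels = c("1996-2000", "2000-2010", "2010-2020"))
}

#' Patient-level baseline covariates for a cohort
#'
#' Sex, age at index (continuous and 18-39 / 40-69 / 70+ categories),
#' calendar period of the index year, initial comorbidity drug flags (the
#' flags of the first 180-day interval), total adherence and its category.
#'
#' @param members Cohort member table.
#' @param db The `rx_db` (for sex and birth date).
#' @param pp Person-period table covering the members.
#' @param summaries Follow-up summaries covering the members.
#' @return data.table, one row per member.
#' @export
baseline_covariates <- function(members, db, pp, summaries) {
  bl <- copy(members)
  bl[db$patients, `:=`(sex = i.sex, birth_day = i.birth_day),
     on = "patient_id"]
  bl[, age := floor((index_day - birth_day) / 365.25)]
  bl[, age_cat := cut(age, breaks = c(-Inf, 39, 69, Inf),
                      labels = c("18-39", "40-69", "70+"))]
  bl[, calendar_period := calendar_period_of(
    as.integer(format(index_date, "%Y")))]
  first <- pp[k == 0L, .(patient_id, diabetes0 = diabetes_rx, ra0 = ra_rx,
                         asthma_copd0 = asthma_copd_rx)]
  bl <- merge(bl, first, by = "patient_id", all.x = TRUE)
  bl <- merge(bl, summaries[, .(patient_id, adherence_total, followup_days)],
              by = "patient_id", all.x = TRUE)
  bl[, adherence_cat := cut(adherence_total, breaks = c(-Inf, 0.8, 0.9, Inf),
                            labels = c("<0.80", "0.80-0.90", ">=0.90"),
                            right = FALSE)]
  bl[, birth_day := NULL]
  bl[]
}

#' Attach baseline covariates to person-period rows
#'
#' The weight models need `sex`, `age` and `calendar_period` on every
#' person-period row; this joins them in from the baseline table.
#'
#' @param pp Person-period table.
#' @param baseline Output of [baseline_covariates()].
#' @return Copy of `pp` with the covariate columns added.
#' @export
attach_baseline_covariates <- function(pp, baseline) {
  out <- copy(as.data.table(pp))
  out[baseline, `:=`(sex = i.sex, age = i.age,
                     calendar_period = i.calendar_period),
      on = "patient_id"]
  out[]
}

#' Baseline characteristics table with class-difference tests
#'
#' Counts and column percentages per exposure class for each categorical
#' covariate with a Pearson chi-square test, and mean +/- SD with a Welch
#' ANOVA (unequal-variance `oneway.test`) for continuous covariates.
#' Tests are skipped with a notice when fewer than two classes are present.
#'
#' @param baseline Output of [baseline_covariates()].
#' @param categorical,continuous Covariate column names.
#' @return List: `table` (long data.table: `variable`, `level`,
#'   `exposure_class`, `n`, `pct`) and `tests` (data.table: `variable`,
#'   `test`, `statistic`, `p_value`).
#' @export
summarize_baseline <- function(baseline,
                               categorical = c("sex", "age_cat",
                                               "diabetes0", "ra0",
                                               "asthma_copd0",
                                               "calendar_period"),
                               continuous = "age") {
  bl <- as.data.table(baseline)
  cls <- exposure_factor(bl$exposure_class)
  single <- nlevels(droplevels(cls)) < 2L
  if (single) message("single exposure class: between-class tests skipped")
  tabs <- list(); tests <- list()
  for (v in categorical) {
    x <- factor(bl[[v]])
    ct <- table(x, cls)
    n_cls <- colSums(ct)
    long <- as.data.table(ct)
    setnames(long, c("level", "exposure_class", "n"))
    long[, `:=`(variable = v, pct = percent1(n, n_cls[exposure_class]))]
    tabs[[v]] <- long[, .(variable, level, exposure_class, n, pct)]
    if (!single) {
      ht <- suppressWarnings(chisq.test(ct))
      tests[[v]] <- data.table(variable = v, test = "pearson_chisq",
                               statistic = unname(ht$statistic),
                               p_value = ht$p.value)
    }
  }
  for (v in continuous) {
    m <- bl[, .(n = .N, mean = mean(get(v)), sd = sd(get(v))), by = .(cls)]
    long <- data.table(variable = v, level = "mean_sd",
                       exposure_class = as.character(m$cls), n = m$n,
                       pct = NA_real_, mean = m$mean, sd = m$sd)
    tabs[[paste0(v, "_cont")]] <- long
    if (!single) {
      ht <- oneway.test(bl[[v]] ~ cls, var.equal = FALSE)
      tests[[paste0(v, "_cont")]] <-
        data.table(variable = v, test = "welch_anova",
                   statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  }
  list(table = rbindlist(tabs, fill = TRUE),
       tests = if (length(tests)) rbindlist(tests) else
         data.table(variable = character(), test = character(),
                    statistic = numeric(), p_value = numeric()))
}
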