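# Inception-cohort construction: index dates, the inclusion/exclusion
# ledger, and the two analysis cohorts (cohort 1 = adherent with > 1 year
# follow-up; cohort 2 = all eligible initiators regardless of adherence).

REASON_CODES <- function(catalog) c(
  "AGE", "PRE_HISTORY", "POST_HISTORY", "MIN_PRESCRIPTIONS", "LIPID_CO_RX",
  "MULTI_CLASS", "FIXED_COMBO", "PRIOR_CDT", "EARLY_CDT",
  paste0("CHRONIC_EXCLUSION:", names(catalog$exclusion_therapy))
)

#' Eligibility rule thresholds
#'
#' Every inclusion/exclusion threshold as an explicit named parameter.
#'
#' @param age_min Minimum age (years) at index.
#' @param pre_history_days Required span of records before index (any drug).
#' @param post_history_days Required span of records after index.
#' @param min_rx Minimum same-class dispensings in the first post-index year.
#' @param first_year_days Length of the "first year" window.
#' @param lipid_window_days Post-index window in which any lipid-lowering
#'   dispensing excludes the patient.
#' @param multi_class_threshold Exclude when at least this many distinct
#'   monotherapy classes qualify in the first year ("more than two").
#' @param multi_class_min_rx Dispensings a class needs to qualify.
#' @param fixed_combo_min Fixed-dose-combination dispensings in the first
#'   year that trigger exclusion.
#' @param lookback_cdt_days Outcome-drug lookback before index.
#' @param blanking_cdt_days Post-index blanking window for outcome drugs.
#' @param chronic_min_rx Dispensings of a chronic-exclusion therapy (within
#'   `[index - lookback_cdt_days, index + blanking_cdt_days]`) that exclude.
#' @param adherence_min Total-adherence floor for cohort 1.
#' @param min_followup_days Follow-up must strictly exceed this for cohort 1.
#' @return A list of class `eligibility_rules`.
#' @export
eligibility_rules <- function(age_min = 18L,
                              pre_history_days = 730L,
                              post_history_days = 365L,
                              min_rx = 3L,
                              first_year_days = 365L,
                              lipid_window_days = 365L,
                              multi_class_threshold = 3L,
                              multi_class_min_rx = 3L,
                              fixed_combo_min = 2L,
                              lookback_cdt_days = 730L,
                              blanking_cdt_days = 90L,
                              chronic_min_rx = 2L,
                              adherence_min = 0.80,
                              min_followup_days = 365L) {
  structure(as.list(environment()), class = "eligibility_rules")
}

#' Find each patient's index date
#'
#' The index date is the earliest dispensing mapping to one of the five
#' antihypertensive monotherapy classes; the exposure class is that
#' dispensing's class. Patients with no such dispensing are absent from the
#' result. Same-day ties break by ATC code order (deterministic).
#'
#' @param db An `rx_db`.
#' @return data.table: `patient_id`, `index_day`, `index_date`,
#'   `exposure_class`.
#' @export
find_index_date <- function(db) {
  rec <- classified_records(db)
  exp_rec <- rec[startsWith(role, "exposure:")]
  if (nrow(exp_rec) == 0L)
    return(data.table(patient_id = character(), index_day = integer(),
                      index_date = as.Date(character()),
                      exposure_class = character()))
  setorder(exp_rec, patient_id, disp_day, atc_code)
  idx <- exp_rec[, .SD[1L], by = patient_id]
  idx[, .(patient_id, index_day = disp_day,
          index_date = as.Date(disp_day, origin = "1970-01-01"),
          exposure_class = role_exposure_class(role))]
}

#' Evaluate all eligibility rules
#'
#' Every rule is evaluated for every patient with an index date (no
#' short-circuiting), so `reason_codes` is complete and attrition counts are
#' derivable in any rule order. Rule windows are closed day intervals
#' relative to index. Cohort-1 status additionally requires the adherence
#' and follow-up conditions and is filled in by [build_cohorts()].
#'
#' @param db An `rx_db`.
#' @param rules An [eligibility_rules()].
#' @return data.table: one row per indexed patient with `index_date`,
#'   `exposure_class`, one logical column per rule, `reason_codes`
#'   (comma-separated, rule order), and `eligible_cohort2`.
#' @export
check_eligibility <- function(db, rules = eligibility_rules()) {
  idx <- find_index_date(db)
  rec <- classified_records(db)
  rec <- rec[idx, on = "patient_id"][, rel := disp_day - index_day]
  pat <- db$patients[idx, on = "patient_id"]
  dec <- copy(idx)

  dec[pat, age := floor((index_day - birth_day) / 365.25), on = "patient_id"]
  dec[, AGE := age < rules$age_min]

  span <- rec[, .(first_rel = min(rel), last_rel = max(rel)), by = patient_id]
  dec[span, `:=`(PRE_HISTORY = first_rel > -rules$pre_history_days,
                 POST_HISTORY = last_rel < rules$post_history_days),
      on = "patient_id"]

  fy <- rules$first_year_days
  same_fy <- rec[role == paste0("exposure:", exposure_class) &
                   rel >= 0L & rel <= fy, .N, by = patient_id]
  dec[, MIN_PRESCRIPTIONS := TRUE]
  dec[same_fy, MIN_PRESCRIPTIONS := N < rules$min_rx, on = "patient_id"]

  lip <- rec[role == "antihyperlipidemic" & rel >= 0L &
               rel <= rules$lipid_window_days, unique(patient_id)]
  dec[, LIPID_CO_RX := patient_id %in% lip]

  mc <- rec[startsWith(role, "exposure:") & rel >= 0L & rel <= fy,
            .N, by = .(patient_id, role)][N >= rules$multi_class_min_rx,
                                          .(n_classes = .N), by = patient_id]
  dec[, MULTI_CLASS := FALSE]
  dec[mc, MULTI_CLASS := n_classes >= rules$multi_class_threshold,
      on = "patient_id"]

  fc <- rec[role == "fixed_combination" & rel >= 0L & rel <= fy,
            .N, by = patient_id]
  dec[, FIXED_COMBO := FALSE]
  dec[fc, FIXED_COMBO := N >= rules$fixed_combo_min, on = "patient_id"]

  prior <- rec[role == "outcome" & rel >= -rules$lookback_cdt_days & rel < 0L,
               unique(patient_id)]
  dec[, PRIOR_CDT := patient_id %in% prior]
  early <- rec[role == "outcome" & rel >= 0L &
                 rel <= rules$blanking_cdt_days, unique(patient_id)]
  dec[, EARLY_CDT := patient_id %in% early]

  for (nm in names(db$catalog$exclusion_therapy)) {
    col <- paste0("CHRONIC_EXCLUSION:", nm)
    ch <- rec[role == paste0("exclusion_therapy:", nm) &
                rel >= -rules$lookback_cdt_days &
                rel <= rules$blanking_cdt_days, .N, by = patient_id]
    dec[, (col) := FALSE]
    dec[ch, (col) := N >= rules$chronic_min_rx, on = "patient_id"]
  }

  codes <- REASON_CODES(db$catalog)
  flag_mat <- as.matrix(dec[, codes, with = FALSE])
  dec[, reason_codes := apply(flag_mat, 1L, function(f)
    paste(codes[f], collapse = ","))]
  dec[, eligible_cohort2 := reason_codes == ""]
  setorder(dec, patient_id)
  dec[]
}

#' Build analysis cohorts 1 and 2 with the attrition flow
#'
#' Cohort 2 = all eligible initiators independent of adherence; cohort 1 =
#' the subset with total adherence at or above `adherence_min` and follow-up
#' strictly longer than `min_followup_days` (both computed by the episode
#' engine). The attrition table attributes each excluded patient to the
#' first failed rule in rule order.
#'
#' @param db An `rx_db`.
#' @param rules An [eligibility_rules()].
#' @param opts An [episode_options()].
#' @return List: `decisions`, `cohort1`, `cohort2` (member tables with
#'   `patient_id`, `index_day`, `index_date`, `exposure_class`),
#'   `summaries` (follow-up summaries for cohort-2 members), `attrition`.
#' @export
build_cohorts <- function(db, rules = eligibility_rules(),
                          opts = episode_options()) {
  dec <- check_eligibility(db, rules)
  member_cols <- c("patient_id", "index_day", "index_date", "exposure_class")
  cohort2 <- dec[eligible_cohort2 == TRUE, ..member_cols]
  if (nrow(cohort2) == 0L) {
    warning("no eligible patients; cohorts are empty")
    empty <- dec[0L, ..member_cols]
    return(list(decisions = dec, cohort1 = empty, cohort2 = empty,
                summaries = data.table(), attrition = attrition_table(dec, db)))
  }
  summ <- followup_summaries(db, cohort2, opts)
  keep1 <- summ[adherence_total >= rules$adherence_min &
                  followup_days > rules$min_followup_days, patient_id]
  cohort1 <- cohort2[patient_id %in% keep1]
  # annotate cohort-1 failures on the decision ledger
  dec[, eligible_cohort1 := eligible_cohort2 & patient_id %in% keep1]
  low <- summ[adherence_total < rules$adherence_min, patient_id]
  short <- summ[followup_days <= rules$min_followup_days, patient_id]
  dec[eligible_cohort2 == TRUE & patient_id %in% low,
      reason_codes := trimws(paste(reason_codes, "LOW_ADHERENCE", sep = ","),
                             whitespace = ",")]
  dec[eligible_cohort2 == TRUE & patient_id %in% short,
      reason_codes := trimws(paste(reason_codes, "SHORT_FOLLOWUP", sep = ","),
                             whitespace = ",")]
  list(decisions = dec, cohort1 = cohort1, cohort2 = cohort2,
       summaries = summ, attrition = attrition_table(dec, db))
}

# Sequential attrition: each excluded patient counted under the first rule
# (in rule order) that failed.
attrition_table <- function(dec, db) {
  codes <- REASON_CODES(db$catalog)
  first_reason <- vapply(strsplit(dec$reason_codes, ","), function(r)
    if (length(r) == 0L || r[1L] == "") "ELIGIBLE" else {
      r <- intersect(codes, r)          # rule order
      if (length(r)) r[1L] else "ELIGIBLE"
    }, character(1))
  tab <- data.table(reason = factor(first_reason,
                                    levels = c(codes, "ELIGIBLE")))[
    , .(n = .N), by = reason]
  merge(data.table(reason = factor(c(codes, "ELIGIBLE"),
                                   levels = c(codes, "ELIGIBLE"))),
        tab, by = "reason", all.x = TRUE)[is.na(n), n := 0L][]
}

#' One-decimal percentage
#'
#' `100 * num / den` rounded to one decimal, the convention used in the
#' reported cohort tables.
#'
#' @param num,den Numerator and denominator counts.
#' @return Numeric.
#' @export
percent1 <- function(num, den) round(100 * num / den, 1)

#' Event counts and follow-up summary for a cohort
#'
#' @param members Cohort member table.
#' @param summaries Follow-up summaries covering the members.
#' @return One-row data.table: `n`, `n_events`, `event_pct` (one decimal),
#'   `mean_followup_years`, `sd_followup_years` (365.25-day years).
#' @export
summarize_events <- function(members, summaries) {
  s <- summaries[patient_id %in% members$patient_id]
  data.table(
    n = nrow(s),
    n_events = sum(s$event),
    event_pct = percent1(sum(s$event), nrow(s)),
    mean_followup_years = mean(s$followup_days / 365.25),
    sd_followup_years = sd(s$followup_days / 365.25)
  )
}
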