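# Episode engine: turns each cohort member's dispensing stream into 180-day
# person-periods with adherence, time-varying comorbidity drug flags, outcome
# ascertainment and per-protocol censoring. All day arithmetic is on integer
# offsets relative to the index date; coverage intervals are half-open
# [dispense_day, dispense_day + days_covered).

#' Episode-engine options
#'
#' Thresholds and interpretation switches for follow-up construction.
#'
#' @param interval_days Length of a person-period (days).
#' @param gap_days Supply gap beyond which the index therapy counts as
#'   discontinued.
#' @param max_followup_days Administrative cap on follow-up (10 years in the
#'   180-day grid: 3,780 days).
#' @param outcome_min_rx Minimum number of outcome-proxy dispensings within
#'   one outcome window for an event.
#' @param outcome_window_days Width of the outcome window.
#' @param outcome_anchor `"rolling"`: the window is anchored at each outcome
#'   dispensing (two dispensings within 180 days of each other);
#'   `"grid"`: both must fall in the same fixed 180-day person-period.
#' @param gap_from `"coverage_end"`: the discontinuation gap is measured from
#'   the end of covered supply (does not penalize long refills);
#'   `"dispense_date"`: from the dispensing date itself.
#' @param terminal_denominator `"actual"`: the terminal partial interval's
#'   adherence denominator is its true length; `"fixed"`: always
#'   `interval_days`.
#' @param admin_end Administrative end of data collection (Date or
#'   anything `as.Date` accepts).
#' @return A list of class `episode_options`.
#' @export
episode_options <- function(interval_days = 180L,
                            gap_days = 180L,
                            max_followup_days = 3780L,
                            outcome_min_rx = 2L,
                            outcome_window_days = 180L,
                            outcome_anchor = c("rolling", "grid"),
                            gap_from = c("coverage_end", "dispense_date"),
                            terminal_denominator = c("actual", "fixed"),
                            admin_end = as.Date("2020-12-31")) {
  structure(list(
    interval_days = as.integer(interval_days),
    gap_days = as.integer(gap_days),
    max_followup_days = as.integer(max_followup_days),
    outcome_min_rx = as.integer(outcome_min_rx),
    outcome_window_days = as.integer(outcome_window_days),
    outcome_anchor = match.arg(outcome_anchor),
    gap_from = match.arg(gap_from),
    terminal_denominator = match.arg(terminal_denominator),
    admin_end_day = day_of(admin_end)
  ), class = "episode_options")
}

#' Covered days within a window
#'
#' Size of the union of per-dispensing coverage intervals
#' `[day, day + days_covered)` intersected with the half-open window
#' `[window[1], window[2])`. Overlapping supply counts once (no
#' stockpiling carry-forward).
#'
#' @param disp_day Integer dispensing days.
#' @param days_covered Integer coverage lengths (>= 1).
#' @param window Length-2 integer vector, half-open window.
#' @return Integer count of covered days.
#' @export
coverage_union <- function(disp_day, days_covered, window) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  if (length(disp_day) == 0L) return(0L)
  s <- pmax(as.numeric(disp_day), window[1L])
  e <- pmin(as.numeric(disp_day) + as.numeric(days_covered), window[2L])
  keep <- e > s
  if (!any(keep)) return(0L)
  o <- order(s[keep])
  s <- s[keep][o]; e <- e[keep][o]
  # merge sorted intervals
  tot <- 0; cs <- s[1L]; ce <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  as.integer(tot + (ce - cs))
}

#' Total adherence over follow-up
#'
#' Proportion of follow-up days covered by index-class supply:
#' covered-day union over `[0, followup_days)` divided by `followup_days`.
#'
#' @param disp_day,days_covered Index-class dispensing stream (days relative
#'   to index).
#' @param followup_days Total follow-up length in days (>= 1).
#' @return Proportion in `[0, 1]`.
#' @export
compute_adherence_total <- function(disp_day, days_covered, followup_days) {
  if (followup_days <= 0) stop("followup_days must be >= 1")
  coverage_union(disp_day, days_covered, c(0L, as.integer(followup_days))) /
    followup_days
}

#' Interval adherence
#'
#' Proportion of one person-period's days covered by index-class supply.
#' For the terminal partial interval the denominator is the actual interval
#' length by default (see [episode_options()]).
#'
#' @inheritParams compute_adherence_total
#' @param start_day,stop_day Half-open interval bounds relative to index.
#' @param opts [episode_options()].
#' @return Proportion in `[0, 1]`.
#' @export
compute_adherence_180 <- function(disp_day, days_covered, start_day, stop_day,
                                  opts = episode_options()) {
  stopifnot(stop_day > start_day)
  denom <- if (opts$terminal_denominator == "fixed") opts$interval_days
           else stop_day - start_day
  min(1, coverage_union(disp_day, days_covered, c(start_day, stop_day)) / denom)
}

#' Detect discontinuation of the index therapy
#'
#' Scans same-class dispensings for the first supply gap exceeding
#' `gap_days`. The gap is measured from the running coverage end (or the
#' dispensing date, per `opts$gap_from`) to the next same-class dispensing;
#' after the final dispensing, a gap to `admin_end` beyond the threshold also
#' counts. The discontinuation day is the coverage end of the last dispensing
#' before the gap.
#'
#' @param disp_day,days_covered Sorted same-class dispensing stream (relative
#'   days).
#' @param admin_end_rel Administrative end, relative days.
#' @param opts [episode_options()].
#' @return Integer discontinuation day, or `NA_integer_` if none.
#' @export
detect_discontinuation <- function(disp_day, days_covered, admin_end_rel,
                                   opts = episode_options()) {
  n <- length(disp_day)
  if (n == 0L) return(NA_integer_)
  cov_end <- cummax(disp_day + days_covered)
  ref <- if (opts$gap_from == "coverage_end") cov_end else cummax(disp_day)
  if (n > 1L) {
    gaps <- disp_day[-1L] - ref[-n]
    i <- which(gaps > opts$gap_days)
    if (length(i)) return(as.integer(cov_end[i[1L]]))
  }
  if (admin_end_rel - ref[n] > opts$gap_days) return(as.integer(cov_end[n]))
  NA_integer_
}

#' Detect a treatment switch after discontinuation
#'
#' A switch is a dispensing of a different antihypertensive class or of a
#' fixed-dose combination within `gap window` days after discontinuation.
#' Switching never alters censoring (follow-up already ended at
#' discontinuation); it only labels the patient for the sensitivity cohorts.
#'
#' @param disp_day Relative dispensing days (all records).
#' @param role Role tags from [classify_atc()] aligned with `disp_day`.
#' @param index_class The patient's exposure class.
#' @param disc_day Discontinuation day or `NA`.
#' @param opts [episode_options()].
#' @return List with `switched` (logical) and `new_class` (character or NA).
#' @export
detect_switch <- function(disp_day, role, index_class, disc_day,
                          opts = episode_options()) {
  if (is.na(disc_day)) return(list(switched = FALSE, new_class = NA_character_))
  cls <- role_exposure_class(role)
  cand <- (( !is.na(cls) & cls != index_class) | role == "fixed_combination") &
    disp_day > disc_day & disp_day <= disc_day + opts$gap_days
  if (!any(cand)) return(list(switched = FALSE, new_class = NA_character_))
  first <- which(cand)[which.min(disp_day[cand])]
  list(switched = TRUE,
       new_class = if (is.na(cls[first])) "FIXED_COMBO" else cls[first])
}

#' Detect a drug add-on
#'
#' Earliest dispensing of a different antihypertensive class strictly after
#' index and strictly before discontinuation (or before the end of candidate
#' follow-up when there is no discontinuation). Add-ons censor follow-up.
#'
#' @inheritParams detect_switch
#' @param limit_day Discontinuation day, or candidate follow-up end when
#'   no discontinuation occurred.
#' @return Integer add-on day or `NA_integer_`.
#' @export
detect_addon <- function(disp_day, role, index_class, limit_day) {
  cls <- role_exposure_class(role)
  cand <- !is.na(cls) & cls != index_class & disp_day > 0L &
    disp_day < limit_day
  if (!any(cand)) return(NA_integer_)
  as.integer(min(disp_day[cand]))
}

#' Ascertain the acute-CDT outcome
#'
#' Scans outcome-proxy dispensings after index in date order; the event fires
#' at the first dispensing that has at least `outcome_min_rx - 1` further
#' outcome dispensings within `outcome_window_days` of it (rolling window),
#' or within the same fixed 180-day person-period (`outcome_anchor =
#' "grid"`). The event day is the first of the qualifying dispensings.
#'
#' @param outcome_day Sorted relative days of outcome-role dispensings
#'   (> 0, i.e. after index).
#' @param opts [episode_options()].
#' @return Integer event day or `NA_integer_`.
#' @export
ascertain_outcome <- function(outcome_day, opts = episode_options()) {
  m <- opts$outcome_min_rx
  n <- length(outcome_day)
  if (n < m) return(NA_integer_)
  if (opts$outcome_anchor == "rolling") {
    for (i in seq_len(n - m + 1L)) {
      if (outcome_day[i + m - 1L] - outcome_day[i] <= opts$outcome_window_days)
        return(as.integer(outcome_day[i]))
    }
  } else {
    g <- outcome_day %/% opts$interval_days
    tab <- table(g)
    ok <- as.integer(names(tab))[tab >= m]
    if (length(ok))
      return(as.integer(min(outcome_day[g == min(ok)])))
  }
  NA_integer_
}

# Censoring reasons in tie-break priority order.
CENSOR_PRIORITY <- c("CDT_EVENT", "ADDON", "DISCONTINUATION",
                     "MAX_FOLLOWUP", "ADMIN_END")

#' Determine end of follow-up for one member
#'
#' Follow-up ends at the earliest of: event day, add-on day, discontinuation
#' day, the 10-year cap, and the administrative end; ties break by priority
#' event > add-on > discontinuation > cap/administrative end. Returns the
#' follow-up summary row including total adherence.
#'
#' @param records data.table of the patient's records with columns
#'   `disp_day`, `days_covered`, `role` (absolute days).
#' @param index_day Absolute index day.
#' @param index_class Exposure class at index.
#' @param opts [episode_options()].
#' @return One-row data.table (`followup_days`, `adherence_total`, `event`,
#'   `event_day`, `censor_reason`, `disc_day`, `switched`, `addon_day`), all
#'   days relative to index; zero-row table if follow-up is empty.
#' @export
determine_followup_end <- function(records, index_day, index_class,
                                   opts = episode_options()) {
  d <- records$disp_day - index_day
  if (is.unsorted(d)) stop("records must be sorted by dispense date")
  role <- records$role
  cov <- records$days_covered
  admin_rel <- opts$admin_end_day - index_day
  same <- role == paste0("exposure:", index_class) & d >= 0L
  disc <- detect_discontinuation(d[same], cov[same], admin_rel, opts)
  ev <- ascertain_outcome(sort(d[role == "outcome" & d > 0L]), opts)
  cand_end <- min(disc, ev, opts$max_followup_days, admin_rel, na.rm = TRUE)
  addon <- detect_addon(d, role, index_class,
                        limit_day = if (is.na(disc)) cand_end else disc)
  ends <- c(CDT_EVENT = ev, ADDON = addon, DISCONTINUATION = disc,
            MAX_FOLLOWUP = opts$max_followup_days, ADMIN_END = admin_rel)
  fu <- min(ends, na.rm = TRUE)
  reason <- CENSOR_PRIORITY[which(!is.na(ends) & ends == fu)][1L]
  if (fu <= 0L) return(data.table())
  sw <- detect_switch(d, role, index_class, disc, opts)
  data.table(
    followup_days = as.integer(fu),
    adherence_total = compute_adherence_total(d[same], cov[same], fu),
    event = reason == "CDT_EVENT",
    event_day = if (reason == "CDT_EVENT") as.integer(ev) else NA_integer_,
    censor_reason = reason,
    disc_day = disc,
    switched = sw$switched,
    addon_day = addon
  )
}

#' Follow-up summaries for a set of cohort members
#'
#' Applies [determine_followup_end()] to every member. Members whose
#' follow-up is empty (<= 0 days) are dropped with a warning.
#'
#' @param db An `rx_db` (roles are classified internally).
#' @param members data.table with `patient_id`, `index_day`,
#'   `exposure_class`.
#' @param opts [episode_options()].
#' @return data.table keyed by `patient_id` with the follow-up summary
#'   columns of [determine_followup_end()].
#' @export
followup_summaries <- function(db, members, opts = episode_options()) {
  rec <- classified_records(db)
  rec <- rec[patient_id %in% members$patient_id]
  out <- rec[members, on = "patient_id"][
    , determine_followup_end(.SD, index_day[1L], exposure_class[1L], opts),
    by = .(patient_id, index_day, exposure_class)]
  dropped <- setdiff(members$patient_id, out$patient_id)
  if (length(dropped))
    warning(length(dropped), " member(s) dropped: empty follow-up")
  out
}

classified_records <- function(db) {
  rec <- copy(db$records)
  rec[, role := classify_atc(atc_code, db$catalog)]
  rec
}

#' Build 180-day person-periods
#'
#' Tiles each member's follow-up `[0, followup_days)` with half-open 180-day
#' intervals (terminal interval clipped), computing interval adherence
#' (index-class coverage), comorbidity drug flags (any dispensing of the
#' named comorbidity set within the interval), and the event indicator on
#' the final row.
#'
#' @param db An `rx_db`.
#' @param summaries Output of [followup_summaries()].
#' @param opts [episode_options()].
#' @return data.table with one row per (patient, interval): `patient_id`,
#'   `k`, `start_day`, `stop_day`, `exposure_class`, `adherence_180`,
#'   `diabetes_rx`, `ra_rx`, `asthma_copd_rx`, `event`, `censor_reason`.
#' @export
build_person_periods <- function(db, summaries, opts = episode_options()) {
  rec <- classified_records(db)
  rec <- rec[patient_id %in% summaries$patient_id]
  L <- opts$interval_days
  pp <- summaries[, {
    nk <- as.integer(ceiling(followup_days / L))
    kk <- seq_len(nk) - 1L
    .(k = kk, start_day = kk * L,
      stop_day = pmin((kk + 1L) * L, as.integer(followup_days)))
  }, by = .(patient_id, index_day, exposure_class, followup_days,
            event, censor_reason)]
  streams <- rec[unique(pp[, .(patient_id, index_day, exposure_class)]),
                 on = "patient_id"]
  streams[, rel := disp_day - index_day]

  grid <- pp[, .(patient_id, k, gs = start_day, ge = stop_day - 1L)]
  setkey(grid, patient_id, gs, ge)

  # interval adherence: overlap-join index-class coverage onto the grid,
  # then union segment lengths within each (patient, interval)
  cls <- streams[role == paste0("exposure:", exposure_class) & rel >= 0L,
                 .(patient_id, s = rel, e = rel + days_covered - 1L,
                   s0 = rel, e0 = rel + days_covered)]
  cov <- if (nrow(cls)) {
    fo <- foverlaps(cls, grid, by.x = c("patient_id", "s", "e"),
                    type = "any", nomatch = NULL)
    fo[, `:=`(seg_s = pmax(s0, gs), seg_e = pmin(e0, ge + 1L))]
    fo[, .(covered_days = union_length(seg_s, seg_e)), by = .(patient_id, k)]
  } else data.table(patient_id = character(), k = integer(),
                    covered_days = integer())
  pp <- merge(pp, cov, by = c("patient_id", "k"), all.x = TRUE)
  pp[is.na(covered_days), covered_days := 0L]
  denom <- if (opts$terminal_denominator == "fixed")
    rep(L, nrow(pp)) else pp$stop_day - pp$start_day
  pp[, adherence_180 := pmin(1, covered_days / denom)]

  # comorbidity drug flags: any dispensing of the set within the interval
  flag_cols <- c(diabetes = "diabetes_rx", ra = "ra_rx",
                 asthma_copd = "asthma_copd_rx")
  for (nm in names(db$catalog$comorbidity)) {
    col <- if (nm %in% names(flag_cols)) flag_cols[[nm]]
           else paste0(nm, "_rx")
    dd <- streams[role == paste0("comorbidity:", nm),
                  .(patient_id, s = rel, e = rel)]
    pp[, (col) := FALSE]
    if (nrow(dd)) {
      hit <- unique(foverlaps(dd, grid, by.x = c("patient_id", "s", "e"),
                              type = "any",
                              nomatch = NULL)[, .(patient_id, k)])
      pp[hit, (col) := TRUE, on = c("patient_id", "k")]
    }
  }

  pp[, event := event & k == max(k), by = patient_id]
  setorder(pp, patient_id, k)
  pp[, covered_days := NULL]
  pp[]
}

# Union length of half-open integer intervals [s, e).
union_length <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  lagmax <- shift(cummax(e), 1L, fill = min(s))
  as.integer(sum(pmax(0L, e - pmax(s, lagmax))))
}
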