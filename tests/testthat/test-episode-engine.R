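test_that("coverage union counts overlapping supply once", {
  expect_equal(coverage_union(10L, 90L, c(0L, 180L)), 90L)
  expect_equal(coverage_union(c(0L, 15L), c(30L, 30L), c(0L, 180L)), 45L)
  expect_equal(coverage_union(integer(0), integer(0), c(0L, 180L)), 0L)
  expect_equal(coverage_union(170L, 90L, c(0L, 180L)), 10L)  # clipped
})

test_that("coverage and adherence match the day-by-day boolean oracle", {
  set.seed(42)
  for (i in 1:200) {
    st <- random_stream()
    a <- sample(0:300, 1); b <- a + sample(c(60, 180, 365), 1)
    expect_equal(coverage_union(st$day, st$cov, c(a, b)),
                 oracle_coverage(st$day, st$cov, a, b))
    fu <- sample(100:900, 1)
    expect_equal(compute_adherence_total(st$day, st$cov, fu),
                 oracle_coverage(st$day, st$cov, 0, fu) / fu)
  }
})

test_that("total adherence hits the stated 80% boundary exactly", {
  # 292 covered days of 365 follow-up days = 0.8
  expect_equal(compute_adherence_total(0L, 292L, 365L), 0.8)
  expect_equal(compute_adherence_total(seq(0L, 630L, 90L),
                                       rep(90L, 8L), 720L), 1.0)
  expect_error(compute_adherence_total(0L, 90L, 0L), "followup_days")
})

test_that("interval adherence uses the actual length of a partial interval", {
  expect_equal(compute_adherence_180(0L, 90L, 0L, 180L), 0.5)
  expect_equal(compute_adherence_180(360L, 100L, 360L, 460L), 1.0)
  opts_fixed <- episode_options(terminal_denominator = "fixed")
  expect_equal(compute_adherence_180(360L, 100L, 360L, 460L, opts_fixed),
               100 / 180)
  set.seed(7)
  for (i in 1:50) {
    st <- random_stream()
    a <- 180L * sample(0:3, 1); b <- a + sample(30:180, 1)
    expect_equal(compute_adherence_180(st$day, st$cov, a, b),
                 min(1, oracle_coverage(st$day, st$cov, a, b) / (b - a)))
  }
})

test_that("discontinuation fires on the first >180-day supply gap", {
  opts <- episode_options()
  # steady refills into the administrative end: no discontinuation
  expect_true(is.na(detect_discontinuation(seq(0L, 900L, 90L),
                                           rep(90L, 11L), 1000L, opts)))
  # coverage to day 400, next dispensing day 620: gap 220 > 180
  expect_equal(detect_discontinuation(c(0L, 90L, 180L, 310L, 620L),
                                      rep(90L, 5L), 3000L, opts), 400L)
  # single dispensing with a long data tail after it
  expect_equal(detect_discontinuation(0L, 90L, 3000L, opts), 90L)
  # dispense-date reading penalizes the 310-day dispensing gap immediately
  opts_dd <- episode_options(gap_from = "dispense_date")
  expect_equal(detect_discontinuation(c(0L, 310L, 620L), rep(90L, 3L),
                                      3000L, opts_dd), 90L)
  expect_true(is.na(detect_discontinuation(c(0L, 170L), c(90L, 90L),
                                           350L, opts)))
})

test_that("switch requires a new class within 180 days of discontinuation", {
  role <- c("exposure:BB", "exposure:CCB")
  expect_true(detect_switch(c(0L, 370L), role, "BB", 270L)$switched)
  expect_false(detect_switch(c(0L, 480L), role, "BB", 270L)$switched)
  expect_false(detect_switch(c(0L, 370L), role, "BB", NA_integer_)$switched)
  # fixed-dose combination also counts as a switch target
  expect_true(detect_switch(c(0L, 300L), c("exposure:BB", "fixed_combination"),
                            "BB", 270L)$switched)
})

test_that("add-on is the earliest other-class dispensing before discontinuation", {
  role <- c("exposure:BB", "exposure:THIAZIDE", "exposure:ACEI")
  expect_equal(detect_addon(c(0L, 300L, 500L), role, "BB", 720L), 300L)
  # other-class dispensing only after discontinuation: a switch, not add-on
  expect_true(is.na(detect_addon(c(0L, 400L), role[1:2], "BB", 270L)))
  expect_true(is.na(detect_addon(c(0L, 90L), rep("exposure:BB", 2), "BB",
                                 720L)))
})

test_that("outcome needs two proxy dispensings within a 180-day window", {
  opts <- episode_options()
  expect_equal(ascertain_outcome(c(400L, 450L), opts), 400L)
  expect_true(is.na(ascertain_outcome(500L, opts)))
  expect_true(is.na(ascertain_outcome(c(400L, 600L), opts)))
  set.seed(11)
  for (i in 1:100) {
    days <- sort(sample.int(2000L, sample.int(6L, 1)))
    expect_equal(ascertain_outcome(days, opts), oracle_outcome(days),
                 info = paste(days, collapse = ","))
  }
  # grid anchoring: both dispensings must share a fixed 180-day interval
  opts_grid <- episode_options(outcome_anchor = "grid")
  expect_true(is.na(ascertain_outcome(c(170L, 190L), opts_grid)))
  expect_equal(ascertain_outcome(c(190L, 350L), opts_grid), 190L)
})

make_member_records <- function(rel, code, cov = 90L) {
  data.table::data.table(disp_day = rel, days_covered = as.integer(cov),
                         role = classify_atc(code))
}

test_that("follow-up ends at the earliest terminating event with priority ties", {
  opts <- episode_options(admin_end = as.Date("2020-12-31"))
  idx <- as.integer(as.Date("2010-01-06"))
  # event day 700 beats discontinuation at 900
  rec <- rbind(
    make_member_records(idx + seq(0L, 810L, 90L), rep("C07AB02", 10)),
    make_member_records(idx + c(700L, 720L), c("B01AC06", "B01AC06"), 30L))
  data.table::setorder(rec, disp_day)
  s <- determine_followup_end(rec, idx, "BB", opts)
  expect_equal(s$followup_days, 700L)
  expect_equal(s$censor_reason, "CDT_EVENT")
  expect_true(s$event)
  # event and add-on on the same day: event wins
  rec <- rbind(
    make_member_records(idx + seq(0L, 810L, 90L), rep("C07AB02", 10)),
    make_member_records(idx + 300L, "C09AA02"),
    make_member_records(idx + c(300L, 330L), c("B01AC06", "B01AC06"), 30L))
  data.table::setorder(rec, disp_day)
  s <- determine_followup_end(rec, idx, "BB", opts)
  expect_equal(s$censor_reason, "CDT_EVENT")
  expect_equal(s$followup_days, 300L)
  # add-on strictly before discontinuation censors at the add-on day
  rec <- rbind(make_member_records(idx + c(0L, 90L), rep("C07AB02", 2)),
               make_member_records(idx + 150L, "C03AA03"))
  data.table::setorder(rec, disp_day)
  s <- determine_followup_end(rec, idx, "BB", opts)
  expect_equal(s$censor_reason, "ADDON")
  expect_equal(s$followup_days, 150L)
  expect_true(s$addon_day == 150L)
  # nothing happens near the administrative end
  idx_late <- as.integer(as.Date("2019-06-01"))
  rec <- make_member_records(idx_late + seq(0L, 540L, 90L), rep("C07AB02", 7))
  s <- determine_followup_end(rec, idx_late, "BB", opts)
  expect_equal(s$censor_reason, "ADMIN_END")
  expect_equal(s$followup_days,
               as.integer(as.Date("2020-12-31")) - idx_late)
})

test_that("person-periods tile follow-up and carry interval-local flags", {
  db <- toy_db()
  members <- find_index_date(db)
  summ <- followup_summaries(db, members)
  pp <- build_person_periods(db, summ)
  # exact tiling, no gaps or overlaps
  tile <- pp[, .(len = sum(stop_day - start_day),
                 first = min(start_day), holes = anyDuplicated(k)),
             by = patient_id]
  chk <- merge(tile, summ[, .(patient_id, followup_days)], by = "patient_id")
  expect_equal(chk$len, chk$followup_days)
  expect_true(all(chk$first == 0L))
  expect_true(all(chk$holes == 0L))
  # patient B: diabetes dispensings on days 200 and 290 flag k = 1 only
  expect_equal(pp[patient_id == "B" & diabetes_rx == TRUE, k], 1L)
  # follow-up of 720 days -> 4 full intervals
  expect_equal(pp[patient_id == "A", .N], 4L)
  # interval adherence consistent with total adherence (Eq.1 vs Eq.2)
  cov_k <- pp[, .(tot = sum(adherence_180 * (stop_day - start_day))),
              by = patient_id]
  chk <- merge(cov_k, summ[, .(patient_id, adherence_total, followup_days)],
               by = "patient_id")
  expect_equal(chk$tot / chk$followup_days, chk$adherence_total,
               tolerance = 1e-12)
})

test_that("censoring is idempotent on truncated streams", {
  db <- toy_db()
  members <- find_index_date(db)
  summ <- followup_summaries(db, members)
  # drop all records beyond each patient's follow-up end and recompute
  rec2 <- merge(db$records,
                summ[, .(patient_id, end_abs = index_day + followup_days)],
                by = "patient_id")
  rec2 <- rec2[disp_day <= end_abs]
  db2 <- rx_db(db$patients, rec2[, .(patient_id, dispense_date, atc_code,
                                     days_covered)])
  summ2 <- followup_summaries(db2, members)
  expect_equal(summ2[, .(patient_id, followup_days, event, censor_reason)],
               summ[, .(patient_id, followup_days, event, censor_reason)])
})

test_that("with an infinite gap threshold everyone reaches the horizon", {
  db <- toy_db()
  members <- find_index_date(db)
  opts <- episode_options(gap_days = 10000000L)
  summ <- followup_summaries(db, members, opts)
  admin <- as.integer(as.Date("2020-12-31"))
  expect_equal(summ$followup_days,
               pmin(3780L, admin - members$index_day))
})
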