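test_that("index date is the earliest antihypertensive dispensing", {
  d0 <- as.integer(as.Date("2000-01-01"))
  pats <- data.table::data.table(patient_id = c("x", "y", "z"),
                                 sex = "male",
                                 birth_date = as.Date("1950-01-01"))
  recs <- data.table::data.table(
    patient_id = c("x", "x", "y", "z", "z"),
    dispense_date = as.Date(d0 + c(800L, 900L, 100L, 600L, 500L),
                            origin = "1970-01-01"),
    atc_code = c("C09AA02", "C07AB02", "N02BE01", "C03AA03", "C07AB02"),
    days_covered = 90L)
  db <- rx_db(pats, recs)
  idx <- find_index_date(db)
  expect_equal(idx[patient_id == "x", exposure_class], "ACEI")
  expect_equal(idx[patient_id == "x", index_day], d0 + 800L)
  expect_false("y" %in% idx$patient_id)          # no antihypertensive ever
  # earliest over all dispensings, regardless of class precedence
  oracle <- recs[classify_atc(atc_code) %in%
                   paste0("exposure:", class_levels())][
    , .SD[which.min(dispense_date)], by = patient_id]
  expect_equal(idx[patient_id == "z", exposure_class], "BB")
  expect_equal(idx[patient_id == "z", index_day],
               as.integer(oracle[patient_id == "z", dispense_date]))
})

test_that("every fixture patient receives its expected decision", {
  fx <- make_eligibility_fixture()
  ch <- build_cohorts(fx$db)
  got <- ch$decisions[, .(patient_id, exposure_class, eligible_cohort2,
                          eligible_cohort1, reason_codes)]
  want <- fx$expected[, .(patient_id, exposure_class, eligible_cohort2,
                          eligible_cohort1, reason_codes)]
  data.table::setorder(got, patient_id)
  data.table::setorder(want, patient_id)
  expect_equal(got, want)
  # follow-up, adherence and events of the eligible members match the
  # hand-enumerated values
  s <- merge(ch$summaries, fx$expected[!is.na(followup_days)],
             by = "patient_id")
  expect_equal(s$followup_days.x, s$followup_days.y)
  expect_equal(s$adherence_total.x, s$adherence_total.y)
  expect_equal(s$event.x, s$event.y)
  expect_equal(nrow(ch$cohort2), sum(fx$expected$eligible_cohort2))
  expect_equal(nrow(ch$cohort1), sum(fx$expected$eligible_cohort1))
})

test_that("vacuous rules admit every patient with an index date", {
  fx <- make_eligibility_fixture()
  rules <- eligibility_rules(age_min = 0L, pre_history_days = 0L,
                             post_history_days = 0L, min_rx = 1L,
                             lipid_window_days = -1L,
                             multi_class_threshold = 99L,
                             fixed_combo_min = 99L,
                             lookback_cdt_days = 0L,
                             blanking_cdt_days = -1L,
                             chronic_min_rx = 99L)
  dec <- check_eligibility(fx$db, rules)
  idx <- find_index_date(fx$db)
  expect_equal(sum(dec$eligible_cohort2), nrow(idx))
})

test_that("relaxing a single threshold never shrinks cohort 2", {
  fx <- make_eligibility_fixture()
  base <- check_eligibility(fx$db)
  n0 <- sum(base$eligible_cohort2)
  relaxed <- list(
    eligibility_rules(age_min = 0L),
    eligibility_rules(pre_history_days = 100L),
    eligibility_rules(min_rx = 1L),
    eligibility_rules(lookback_cdt_days = 10L),
    eligibility_rules(multi_class_threshold = 99L),
    eligibility_rules(chronic_min_rx = 99L))
  for (r in relaxed)
    expect_gte(sum(check_eligibility(fx$db, r)$eligible_cohort2), n0)
})

test_that("cohort construction is complete and order-invariant", {
  fx <- make_eligibility_fixture()
  ch <- build_cohorts(fx$db)
  expect_true(all(ch$cohort1$patient_id %in% ch$cohort2$patient_id))
  # every indexed patient lands in the attrition table exactly once
  expect_equal(sum(ch$attrition$n), nrow(find_index_date(fx$db)))
  # shuffling input rows changes nothing
  set.seed(1)
  rec <- fx$db$records[sample(.N)]
  db2 <- rx_db(fx$db$patients[sample(.N)],
               rec[, .(patient_id, dispense_date, atc_code, days_covered)])
  ch2 <- build_cohorts(db2)
  expect_equal(ch2$decisions[order(patient_id), reason_codes],
               ch$decisions[order(patient_id), reason_codes])
  expect_equal(sort(ch2$cohort1$patient_id), sort(ch$cohort1$patient_id))
})

test_that("printed-percentage helper rounds to one decimal", {
  expect_equal(percent1(1, 3), 33.3)
  expect_equal(percent1(0, 10), 0)
})
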