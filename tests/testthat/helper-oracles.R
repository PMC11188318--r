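# Independent brute-force oracles used across tests.

# Day-by-day boolean-array union of coverage intervals within [a, b).
oracle_coverage <- function(disp_day, days_covered, a, b) {
  days <- rep(FALSE, b - a)
  for (i in seq_along(disp_day)) {
    lo <- max(disp_day[i], a)
    hi <- min(disp_day[i] + days_covered[i], b)
    if (hi > lo) days[(lo - a + 1):(hi - a)] <- TRUE
  }
  sum(days)
}

# Random dispensing stream (relative days).
random_stream <- function(max_day = 900, max_n = 12) {
  n <- sample.int(max_n, 1)
  list(day = sort(sample.int(max_day, n, replace = TRUE)) - 1L,
       cov = sample(c(10L, 30L, 90L), n, replace = TRUE))
}

# All-pairs oracle for outcome ascertainment: first day with another
# outcome dispensing within `win` days.
oracle_outcome <- function(days, win = 180L) {
  days <- sort(days)
  n <- length(days)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && days[j] >= days[i] && days[j] - days[i] <= win)
        return(days[i])
    }
  }
  NA_integer_
}

# Small in-memory database: one clean initiator per class plus assorted
# streams, used where the full simulator would be overkill.
toy_db <- function() {
  d0 <- as.integer(as.Date("2005-06-01"))
  rx <- function(pid, rel, code, cov = 90L)
    data.table::data.table(
      patient_id = pid,
      dispense_date = as.Date(d0 + rel, origin = "1970-01-01"),
      atc_code = code, days_covered = as.integer(cov))
  pats <- data.table::data.table(
    patient_id = c("A", "B", "C"),
    sex = c("male", "female", "male"),
    birth_date = as.Date(c("1950-01-01", "1960-05-05", "1945-12-31")))
  recs <- rbind(
    rx("A", c(-800L, 400L), "N02BE01", 30L),
    rx("A", seq(0L, 630L, 90L), "C07AB02"),
    rx("B", c(-900L, 500L), "N02BE01", 30L),
    rx("B", seq(0L, 630L, 90L), "C09AA02"),
    rx("B", c(200L, 290L), "A10BA02"),
    rx("C", c(-750L, 450L), "N02BE01", 30L),
    rx("C", seq(0L, 540L, 90L), "C03AA03"))
  rxmsm::rx_db(pats, recs)
}
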