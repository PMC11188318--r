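# Readers/writers for the prescription database (two CSVs: patients and
# dispensing records) and for derived tables. Dates are carried internally
# as integer day offsets (days since 1970-01-01) so all interval arithmetic
# is exact; calendar dates appear only at I/O.

day_of <- function(x) as.integer(as.Date(x))

parse_dates_or_die <- function(x, what, file) {
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  bad <- which(is.na(d) | format(d, "%Y-%m-%d") != x)
  if (length(bad))
    stop(sprintf("%s: malformed %s at row %s (ISO-8601 required)",
                 file, what, paste(head(bad, 5L), collapse = ", ")))
  d
}

#' Read a prescription database
#'
#' Reads the two-file database: a patients CSV (`patient_id`, `sex`,
#' `birth_date`) and a records CSV (`patient_id`, `dispense_date`,
#' `atc_code`, `days_covered`). All invariants are validated on read:
#' ISO dates, valid ATC syntax, `days_covered >= 1`, unique patient ids,
#' no record for an unknown patient, and birth strictly before every
#' dispensing. Records are returned sorted by `(patient_id, dispense_date)`
#' with an integer day-offset column `disp_day`.
#'
#' @param patients_path,records_path CSV file paths.
#' @param catalog An [atc_catalog()] (kept with the database).
#' @return A list of class `rx_db` with elements `patients` (data.table:
#'   `patient_id`, `sex`, `birth_date`, `birth_day`) and `records`
#'   (data.table: `patient_id`, `dispense_date`, `disp_day`, `atc_code`,
#'   `days_covered`), plus the `catalog`.
#' @export
read_rx_db <- function(patients_path, records_path, catalog = atc_catalog()) {
  pat <- fread(patients_path, colClasses = list(character = "patient_id"))
  req <- c("patient_id", "sex", "birth_date")
  if (!all(req %in% names(pat)))
    stop(patients_path, ": missing column(s) ",
         paste(setdiff(req, names(pat)), collapse = ", "))
  if (anyDuplicated(pat$patient_id))
    stop(patients_path, ": duplicate patient_id")
  if (!all(pat$sex %in% c("male", "female")))
    stop(patients_path, ": sex must be 'male' or 'female', row ",
         which(!pat$sex %in% c("male", "female"))[1L])
  bd <- parse_dates_or_die(as.character(pat$birth_date), "birth_date",
                           patients_path)
  pat <- data.table(patient_id = pat$patient_id, sex = pat$sex,
                    birth_date = bd, birth_day = as.integer(bd))

  rec <- fread(records_path, colClasses = list(character = "patient_id"))
  req <- c("patient_id", "dispense_date", "atc_code", "days_covered")
  if (!all(req %in% names(rec)))
    stop(records_path, ": missing column(s) ",
         paste(setdiff(req, names(rec)), collapse = ", "))
  dd <- parse_dates_or_die(as.character(rec$dispense_date), "dispense_date",
                           records_path)
  bad <- which(!is_valid_atc(rec$atc_code))
  if (length(bad))
    stop(records_path, ": invalid ATC code '", rec$atc_code[bad[1L]],
         "' at row ", bad[1L])
  if (!is.numeric(rec$days_covered) || any(rec$days_covered < 1) ||
      any(rec$days_covered != as.integer(rec$days_covered)))
    stop(records_path, ": days_covered must be integer >= 1, row ",
         which(rec$days_covered < 1 |
                 rec$days_covered != as.integer(rec$days_covered))[1L])
  unknown <- which(!rec$patient_id %in% pat$patient_id)
  if (length(unknown))
    stop(records_path, ": unknown patient_id '", rec$patient_id[unknown[1L]],
         "' at row ", unknown[1L])
  rec <- data.table(patient_id = rec$patient_id, dispense_date = dd,
                    disp_day = as.integer(dd), atc_code = rec$atc_code,
                    days_covered = as.integer(rec$days_covered))
  setorder(rec, patient_id, disp_day, atc_code)
  first_disp <- rec[, .(first_day = min(disp_day)), by = patient_id]
  chk <- merge(first_disp, pat[, .(patient_id, birth_day)], by = "patient_id")
  if (any(chk$first_day <= chk$birth_day))
    stop(records_path, ": dispensing on or before birth_date for patient ",
         chk$patient_id[which(chk$first_day <= chk$birth_day)[1L]])
  structure(list(patients = pat, records = rec, catalog = catalog),
            class = "rx_db")
}

#' Assemble an in-memory prescription database
#'
#' Same validation as [read_rx_db()] but from in-memory tables (used by the
#' simulator and by tests).
#'
#' @param patients data.frame with `patient_id`, `sex`, `birth_date`.
#' @param records data.frame with `patient_id`, `dispense_date`, `atc_code`,
#'   `days_covered`.
#' @inheritParams read_rx_db
#' @return An `rx_db` list.
#' @export
rx_db <- function(patients, records, catalog = atc_catalog()) {
  pat <- as.data.table(patients)
  rec <- as.data.table(records)
  pat[, birth_date := as.Date(birth_date)]
  pat[, birth_day := as.integer(birth_date)]
  rec[, dispense_date := as.Date(dispense_date)]
  rec[, disp_day := as.integer(dispense_date)]
  rec[, days_covered := as.integer(days_covered)]
  stopifnot(!anyDuplicated(pat$patient_id),
            all(rec$patient_id %in% pat$patient_id),
            all(rec$days_covered >= 1L),
            all(is_valid_atc(rec$atc_code)),
            all(pat$sex %in% c("male", "female")))
  setorder(rec, patient_id, disp_day, atc_code)
  structure(list(patients = pat, records = rec, catalog = catalog),
            class = "rx_db")
}

#' @export
print.rx_db <- function(x, ...) {
  cat(sprintf("<rx_db> %d patients, %d dispensing records (%s to %s)\n",
              nrow(x$patients), nrow(x$records),
              min(x$records$dispense_date), max(x$records$dispense_date)))
  invisible(x)
}

#' Write a prescription database to a directory
#'
#' Emits `patients.csv` and `records.csv` in the schema read by
#' [read_rx_db()].
#'
#' @param db An `rx_db`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_rx_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(db$patients[, .(patient_id, sex,
                         birth_date = format(birth_date, "%Y-%m-%d"))],
         file.path(dir, "patients.csv"))
  fwrite(db$records[, .(patient_id,
                        dispense_date = format(dispense_date, "%Y-%m-%d"),
                        atc_code, days_covered)],
         file.path(dir, "records.csv"))
  invisible(dir)
}

#' Write / read a derived analysis table
#'
#' Deterministic CSV writer for derived tables (person-periods, eligibility
#' decisions, weights, hazard tables, ...). Missing values are written as
#' the sentinel `NA` and recovered on read; the column order of the input
#' is preserved, so a write/read cycle reproduces the table exactly.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @param allow_empty Write a header-only file when `x` has zero rows.
#' @return `write_table` returns `path` invisibly; `read_table` a data.table.
#' @export
write_table <- function(x, path, allow_empty = FALSE) {
  if (nrow(x) == 0L && !allow_empty)
    stop("refusing to write empty table to ", path,
         " (set allow_empty = TRUE)")
  fwrite(x, path, na = "NA", quote = "auto")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  fread(path, na.strings = "NA",
        colClasses = if ("patient_id" %in% names(fread(path, nrows = 0L)))
          list(character = "patient_id") else NULL)
}
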