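# Hand-constructed eligibility fixture: ~24 patients, one per
# inclusion/exclusion rule plus clean initiators, add-on/switch/event
# cases, with the expected decision for each. Serves as the oracle for the
# cohort builder and for end-to-end event counting.

#' Eligibility fixture database with expected decisions
#'
#' Builds a tiny prescription database in which each patient exercises one
#' rule: under-18 at index; short pre-index history; no records after one
#' year; fewer than three first-year prescriptions; lipid-lowering co-use;
#' three qualifying monotherapy classes in year one; fixed-dose
#' combinations; outcome drugs in the lookback or the 90-day blanking
#' window; each chronic-exclusion therapy; one clean includable initiator
#' per class; and low-adherence, short-follow-up, event, add-on and switch
#' cases. Expected decisions (reason codes, cohort membership, follow-up,
#' adherence, events) are enumerated by hand alongside.
#'
#' @return List: `db` (an `rx_db`) and `expected` (data.table of expected
#'   decisions; `followup_days`/`adherence_total`/`event` are `NA` for
#'   patients excluded before follow-up is defined).
#' @export
make_eligibility_fixture <- function() {
  index_date <- as.Date("2010-01-06")
  d0 <- as.integer(index_date)
  rx <- function(pid, rel, code, cov = 90L)
    data.table(patient_id = pid,
               dispense_date = as.Date(d0 + rel, origin = "1970-01-01"),
               atc_code = code, days_covered = as.integer(cov))
  bg <- function(pid, rels = c(-800L, 400L))
    rx(pid, rels, "N02BE01", 30L)
  refills <- function(pid, code) rx(pid, seq(0L, 630L, 90L), code)

  pats <- list(); recs <- list(); exp <- list()
  add <- function(pid, sex, birth, rec, class, c2, c1, reasons,
                  fu = NA_integer_, adh = NA_real_, ev = NA) {
    pats[[pid]] <<- data.table(patient_id = pid, sex = sex,
                               birth_date = as.Date(birth))
    recs[[pid]] <<- rec
    exp[[pid]] <<- data.table(patient_id = pid, exposure_class = class,
                              eligible_cohort2 = c2, eligible_cohort1 = c1,
                              reason_codes = reasons,
                              followup_days = as.integer(fu),
                              adherence_total = adh, event = ev)
  }

  add("P01_AGE", "male", "1997-06-15",
      rbind(bg("P01_AGE"), refills("P01_AGE", "C07AB02")),
      "BB", FALSE, FALSE, "AGE")
  add("P02_PREHIST", "female", "1955-03-20",
      rbind(bg("P02_PREHIST", c(-300L, 400L)),
            refills("P02_PREHIST", "C07AB02")),
      "BB", FALSE, FALSE, "PRE_HISTORY")
  add("P03_POSTHIST", "male", "1955-03-20",
      rbind(bg("P03_POSTHIST", -800L),
            rx("P03_POSTHIST", c(0L, 90L, 180L), "C07AB02")),
      "BB", FALSE, FALSE, "POST_HISTORY")
  add("P04_MINRX", "female", "1955-03-20",
      rbind(bg("P04_MINRX"), rx("P04_MINRX", c(0L, 90L), "C03AA03")),
      "THIAZIDE", FALSE, FALSE, "MIN_PRESCRIPTIONS")
  add("P05_LIPID", "male", "1955-03-20",
      rbind(bg("P05_LIPID"), refills("P05_LIPID", "C07AB02"),
            rx("P05_LIPID", 200L, "C10AA01")),
      "BB", FALSE, FALSE, "LIPID_CO_RX")
  add("P06_MULTI", "female", "1955-03-20",
      rbind(bg("P06_MULTI"),
            rx("P06_MULTI", c(0L, 30L, 60L), "C07AB02"),
            rx("P06_MULTI", c(10L, 40L, 70L), "C09AA02"),
            rx("P06_MULTI", c(20L, 50L, 80L), "C08CA01")),
      "BB", FALSE, FALSE, "MULTI_CLASS")
  add("P07_COMBO", "male", "1955-03-20",
      rbind(bg("P07_COMBO"), refills("P07_COMBO", "C07AB02"),
            rx("P07_COMBO", c(100L, 200L), "C09BA02")),
      "BB", FALSE, FALSE, "FIXED_COMBO")
  add("P08_PRIORCDT", "female", "1955-03-20",
      rbind(bg("P08_PRIORCDT"), refills("P08_PRIORCDT", "C07AB02"),
            rx("P08_PRIORCDT", -400L, "B01AA03", 30L)),
      "BB", FALSE, FALSE, "PRIOR_CDT")
  add("P09_EARLYCDT", "male", "1955-03-20",
      rbind(bg("P09_EARLYCDT"), refills("P09_EARLYCDT", "C07AB02"),
            rx("P09_EARLYCDT", 50L, "B01AC06", 30L)),
      "BB", FALSE, FALSE, "EARLY_CDT")
  chronic <- c(P10_HF = "C01AA05", P11_MIG = "N02CC01", P12_ADR = "H02AA02",
               P13_PARA = "H05BA01", P14_THY = "H03AA01")
  chronic_name <- c(P10_HF = "heart_failure", P11_MIG = "migraine",
                    P12_ADR = "adrenal_disease",
                    P13_PARA = "hyperparathyroidism", P14_THY = "thyroid")
  for (pid in names(chronic))
    add(pid, "female", "1955-03-20",
        rbind(bg(pid), refills(pid, "C07AB02"),
              rx(pid, c(-300L, -200L), chronic[[pid]])),
        "BB", FALSE, FALSE,
        paste0("CHRONIC_EXCLUSION:", chronic_name[[pid]]))
  clean <- c(P15_BB = "C07AB02", P16_ACEI = "C09AA02", P17_ARB = "C09CA01",
             P18_CCB = "C08CA01", P19_THIA = "C03AA03")
  clean_class <- c(P15_BB = "BB", P16_ACEI = "ACEI", P17_ARB = "ARB",
                   P18_CCB = "CCB", P19_THIA = "THIAZIDE")
  for (pid in names(clean))
    add(pid, "male", "1955-03-20",
        rbind(bg(pid), refills(pid, clean[[pid]])),
        clean_class[[pid]], TRUE, TRUE, "", fu = 720L, adh = 1.0, ev = FALSE)
  # coverage [0,90)+[170,260)+[340,430)+[510,600): 360 of 600 days = 0.6
  add("P20_LOWADH", "female", "1955-03-20",
      rbind(bg("P20_LOWADH"),
            rx("P20_LOWADH", c(0L, 170L, 340L, 510L), "C03AA03")),
      "THIAZIDE", TRUE, FALSE, "LOW_ADHERENCE",
      fu = 600L, adh = 0.6, ev = FALSE)
  add("P21_SHORTFU", "male", "1955-03-20",
      rbind(bg("P21_SHORTFU"),
            rx("P21_SHORTFU", c(0L, 90L, 180L, 270L), "C07AB02")),
      "BB", TRUE, FALSE, "SHORT_FOLLOWUP", fu = 360L, adh = 1.0, ev = FALSE)
  add("P22_EVENT", "female", "1955-03-20",
      rbind(bg("P22_EVENT"), refills("P22_EVENT", "C07AB02"),
            rx("P22_EVENT", c(400L, 430L), "B01AC06", 30L)),
      "BB", TRUE, TRUE, "", fu = 400L, adh = 1.0, ev = TRUE)
  add("P23_ADDON", "male", "1955-03-20",
      rbind(bg("P23_ADDON"), refills("P23_ADDON", "C07AB02"),
            rx("P23_ADDON", 300L, "C09AA02")),
      "BB", TRUE, FALSE, "SHORT_FOLLOWUP", fu = 300L, adh = 1.0, ev = FALSE)
  add("P24_SWITCH", "female", "1955-03-20",
      rbind(bg("P24_SWITCH"),
            rx("P24_SWITCH", c(0L, 90L, 180L), "C07AB02"),
            rx("P24_SWITCH", c(350L, 440L, 530L), "C08CA01")),
      "BB", TRUE, FALSE, "SHORT_FOLLOWUP", fu = 270L, adh = 1.0, ev = FALSE)

  db <- rx_db(rbindlist(pats), rbindlist(recs))
  list(db = db, expected = rbindlist(exp))
}
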