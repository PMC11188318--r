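# ATC code catalog: prefix sets that assign every dispensing a role in the
# analysis (exposure class, outcome proxy, exclusion trigger, comorbidity
# marker, or none).

#' Antihypertensive exposure classes
#'
#' The five monotherapy classes compared by the pipeline, with their WHO ATC
#' prefixes: thiazides (C03AA), calcium channel blockers (C08C/C08D/C08E),
#' ACE inhibitors (C09A), angiotensin-II receptor blockers (C09C) and
#' beta-blockers (C07A). Beta-blockers are the reference class everywhere.
#'
#' @return Named list mapping class label to character vector of ATC prefixes.
#' @export
exposure_classes <- function() {
  list(
    BB       = "C07A",
    ACEI     = "C09A",
    ARB      = "C09C",
    CCB      = c("C08C", "C08D", "C08E"),
    THIAZIDE = "C03AA"
  )
}

#' Ordered exposure class labels (reference first)
#' @return Character vector of the five class labels, `BB` first.
#' @export
class_levels <- function() names(exposure_classes())

#' Build an ATC code catalog
#'
#' A catalog groups ATC prefixes by analytic role. Roles beyond the five
#' exposure classes: `outcome` (acute cardiac drug therapy proxy:
#' platelet-aggregation inhibitors B01AC, organic nitrates C01DA, vitamin-K
#' antagonists B01AA, other acute vasodilators C01DX), `antihyperlipidemic`
#' (statins etc., C10A), `fixed_combination` (fixed-dose antihypertensive or
#' lipid combination products), named `exclusion_therapy` sets (chronic
#' therapies whose users are excluded), and named `comorbidity` sets
#' (drug proxies for diabetes, rheumatoid arthritis, asthma/COPD used as
#' time-varying confounders). All sets are overridable; the exclusion-therapy
#' defaults are drawn from the standard ATC chapters for each condition.
#'
#' @param exposure Named list of exposure-class prefix vectors.
#' @param outcome Character vector of outcome-proxy prefixes.
#' @param antihyperlipidemic Character vector of lipid-lowering prefixes.
#' @param fixed_combination Character vector of fixed-dose combination prefixes.
#' @param exclusion_therapy Named list of chronic-exclusion prefix vectors.
#' @param comorbidity Named list of comorbidity drug prefix vectors.
#' @return An object of class `atc_catalog`.
#' @export
atc_catalog <- function(exposure = exposure_classes(),
                        outcome = c("B01AC", "C01DA", "B01AA", "C01DX"),
                        antihyperlipidemic = "C10A",
                        fixed_combination = c("C03AB", "C03EA", "C07B", "C07C",
                                              "C07D", "C07F", "C08G", "C09B",
                                              "C09D", "C10B"),
                        exclusion_therapy = list(
                          heart_failure      = "C01AA",
                          migraine           = "N02CC",
                          adrenal_disease    = "H02AA",
                          hyperparathyroidism = "H05B",
                          thyroid            = c("H03A", "H03B")
                        ),
                        comorbidity = list(
                          diabetes    = "A10",
                          ra          = c("M01C", "L04AB", "L04AX"),
                          asthma_copd = "R03"
                        )) {
  cat <- structure(
    list(exposure = exposure, outcome = outcome,
         antihyperlipidemic = antihyperlipidemic,
         fixed_combination = fixed_combination,
         exclusion_therapy = exclusion_therapy,
         comorbidity = comorbidity),
    class = "atc_catalog"
  )
  validate_catalog(cat)
  cat
}

# Flatten a catalog to a prefix -> role lookup table.
catalog_prefix_table <- function(catalog) {
  rows <- list(
    data.table(prefix = unlist(catalog$exposure, use.names = FALSE),
               role = rep(paste0("exposure:", names(catalog$exposure)),
                          lengths(catalog$exposure))),
    data.table(prefix = catalog$outcome, role = "outcome"),
    data.table(prefix = catalog$antihyperlipidemic, role = "antihyperlipidemic"),
    data.table(prefix = catalog$fixed_combination, role = "fixed_combination"),
    data.table(prefix = unlist(catalog$exclusion_therapy, use.names = FALSE),
               role = rep(paste0("exclusion_therapy:",
                                 names(catalog$exclusion_therapy)),
                          lengths(catalog$exclusion_therapy))),
    data.table(prefix = unlist(catalog$comorbidity, use.names = FALSE),
               role = rep(paste0("comorbidity:", names(catalog$comorbidity)),
                          lengths(catalog$comorbidity)))
  )
  rbindlist(rows)
}

validate_catalog <- function(catalog) {
  tab <- catalog_prefix_table(catalog)
  bad <- tab$prefix[!is_valid_atc_prefix(tab$prefix)]
  if (length(bad))
    stop("invalid ATC prefix in catalog: ", paste(bad, collapse = ", "))
  # Nested prefixes mapping to different roles would make one code match two
  # roles; reject at load time, not at query time.
  tab <- unique(tab)
  if (anyDuplicated(tab$prefix))
    stop("catalog assigns one prefix to multiple roles: ",
         paste(unique(tab$prefix[duplicated(tab$prefix)]), collapse = ", "))
  n <- nrow(tab)
  for (i in seq_len(n)) {
    nested <- startsWith(tab$prefix, tab$prefix[i]) & tab$role != tab$role[i]
    if (any(nested))
      stop("catalog prefixes overlap across roles: ", tab$prefix[i], " vs ",
           paste(tab$prefix[nested], collapse = ", "))
  }
  invisible(TRUE)
}

#' Validate ATC code syntax
#'
#' An ATC code is 1 letter, 2 digits, then optionally 1 letter, 1 letter,
#' and 2 digits (levels 1-5); prefixes may stop at any level boundary.
#'
#' @param code Character vector.
#' @return Logical vector.
#' @export
is_valid_atc <- function(code) {
  grepl("^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$", code)
}

is_valid_atc_prefix <- is_valid_atc

#' Classify ATC codes against a catalog
#'
#' Longest-prefix match of each code against the catalog's prefix sets.
#' Exactly one role is returned per code; codes matching no prefix get
#' `"other"`. Role strings are `"exposure:<CLASS>"`, `"outcome"`,
#' `"antihyperlipidemic"`, `"fixed_combination"`,
#' `"exclusion_therapy:<name>"`, `"comorbidity:<name>"`, `"other"`.
#'
#' @param code Character vector of valid ATC codes.
#' @param catalog An [atc_catalog()].
#' @return Character vector of role tags, same length as `code`.
#' @export
classify_atc <- function(code, catalog = atc_catalog()) {
  stopifnot(inherits(catalog, "atc_catalog"))
  if (any(!is_valid_atc(code)))
    stop("invalid ATC code: ",
         paste(unique(code[!is_valid_atc(code)]), collapse = ", "))
  tab <- catalog_prefix_table(catalog)
  setorder(tab, -prefix)          # longer (more specific) prefixes win
  out <- rep("other", length(code))
  matched <- rep(FALSE, length(code))
  # iterate prefixes longest-first; first match per code is the longest
  tab <- tab[order(-nchar(prefix))]
  for (i in seq_len(nrow(tab))) {
    hit <- !matched & startsWith(code, tab$prefix[i])
    out[hit] <- tab$role[i]
    matched <- matched | hit
  }
  out
}

prefix <- NULL # silence R CMD check for data.table column

# Extract the exposure class label from role tags; NA for non-exposure roles.
role_exposure_class <- function(role) {
  cls <- rep(NA_character_, length(role))
  is_exp <- startsWith(role, "exposure:")
  cls[is_exp] <- sub("^exposure:", "", role[is_exp])
  cls
}

#' Read / write a catalog as YAML
#'
#' The catalog (and any run configuration embedding it) serializes to a YAML
#' file and reads back identically.
#'
#' @param catalog An [atc_catalog()].
#' @param path File path.
#' @return `read_catalog` returns an `atc_catalog`; `write_catalog` its path,
#'   invisibly.
#' @export
write_catalog <- function(catalog, path) {
  yaml::write_yaml(unclass(catalog), path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(atc_catalog, lapply(raw, function(x)
    if (is.list(x)) lapply(x, as.character) else as.character(x)))
}
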