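## screening: five-rule annotation screen and MSI confidence levels.

## Fixed order in which a failing record is attributed to a rule.
SCREEN_RULES <- c("db", "ppm", "rt", "area", "ms2")

#' Screening configuration
#'
#' Parameters of the five annotation-screening rules: database confirmation,
#' mass accuracy (ppm), retention-time window, minimum peak area, and MS2
#' availability.
#'
#' The default mass tolerance is +/- 3 ppm and the default elution window is
#' 5-50 min, extensible to 0-120 min via `rt_extended`. The default area
#' floor is 1.0e5 counts; the threshold is fully configurable because
#' instrument-count scales differ between acquisitions.
#'
#' @param ppm_tol mass tolerance, ppm (> 0).
#' @param rt_min,rt_max retention-time window, minutes.
#' @param rt_extended optional length-2 numeric; when set it replaces the
#'   standard window (e.g. `c(0, 120)`).
#' @param area_min minimum maximum-peak-area, instrument counts.
#' @param require_db_hit require at least one reference-database match.
#' @param require_ms2 require an MS2 spectrum.
#' @param standards_list compound names confirmed with authentic standards
#'   (drives MSI level 1 assignment).
#' @return a `screening_config`.
#' @export
screening_config <- function(ppm_tol = 3, rt_min = 5, rt_max = 50,
                             rt_extended = NULL, area_min = 1e5,
                             require_db_hit = TRUE, require_ms2 = TRUE,
                             standards_list = character()) {
  stopifnot(ppm_tol > 0, rt_min < rt_max, area_min >= 0)
  if (!is.null(rt_extended)) {
    stopifnot(length(rt_extended) == 2, rt_extended[1] < rt_extended[2])
  }
  structure(list(ppm_tol = ppm_tol, rt_min = rt_min, rt_max = rt_max,
                 rt_extended = rt_extended, area_min = area_min,
                 require_db_hit = require_db_hit, require_ms2 = require_ms2,
                 standards_list = standards_list),
            class = "screening_config")
}

#' Signed mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed_mz observed m/z, Da.
#' @param theoretical_mz theoretical m/z, Da (> 0).
#' @return signed ppm error, vectorized.
#' @export
#' @examples
#' ppm_error(100.0001, 100) # 1 ppm
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0))
    had_stop("theoretical m/z must be positive", "hadmet_domain_error")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Theoretical m/z of a neutral mass under protonation/deprotonation
#'
#' Assumes `[M+H]+` in positive mode and `[M-H]-` in negative mode
#' (proton mass 1.007276 Da); other adducts are out of scope.
#'
#' @param calc_mw neutral monoisotopic mass, Da.
#' @param ion_mode `"positive"` or `"negative"`.
#' @return theoretical m/z, Da.
#' @export
theoretical_mz <- function(calc_mw, ion_mode) {
  calc_mw + ifelse(ion_mode == "positive", PROTON_MASS, -PROTON_MASS)
}

## Per-rule pure predicates over a feature table; NA fields needed by an
## active rule yield NA (caught by apply_screening as record errors).
screen_predicates <- function(tbl, config) {
  db <- if (config$require_db_hit) nzchar(tbl$db_hits) else rep(TRUE, nrow(tbl))
  err <- ppm_error(tbl$precursor_mz, theoretical_mz(tbl$calc_mw, tbl$ion_mode))
  ppm <- abs(err) <= config$ppm_tol
  win <- config$rt_extended %||% c(config$rt_min, config$rt_max)
  rt <- tbl$rt >= win[1] & tbl$rt <= win[2]
  area <- tbl$peak_area >= config$area_min
  ms2 <- if (config$require_ms2) tbl$has_ms2 else rep(TRUE, nrow(tbl))
  cbind(db = db, ppm = ppm, rt = rt, area = area, ms2 = ms2)
}

#' Apply the five-rule metabolite screen
#'
#' A record passes iff it has at least one database hit (when required), its
#' precursor m/z is within `ppm_tol` of the theoretical protonated /
#' deprotonated mass, its retention time falls in the configured window, its
#' maximum peak area reaches the floor, and it carries an MS2 spectrum (when
#' required). Each rule is a pure predicate, so the passed set is the same
#' for any rule order; a failing record is attributed to the *first* failing
#' rule in the fixed order db, ppm, rt, area, ms2.
#'
#' Records with missing fields needed by an active rule are excluded and
#' collected in `record_errors`.
#'
#' @param tbl a [feature_table()].
#' @param config a [screening_config()].
#' @return a `screening_report`: list with `n_input`, `n_pass`,
#'   `n_fail_per_rule` (named integer over the five rules), `passed`
#'   (feature_table), `fail_rule` (per input row: `"pass"`, a rule name, or
#'   `"error"`), and `record_errors` (integer row indices).
#' @export
apply_screening <- function(tbl, config = screening_config()) {
  validate_feature_table(tbl)
  n <- nrow(tbl)
  if (n == 0) {
    return(structure(list(
      n_input = 0L, n_pass = 0L,
      n_fail_per_rule = stats::setNames(integer(length(SCREEN_RULES)), SCREEN_RULES),
      passed = feature_table(), fail_rule = character(0),
      record_errors = integer(0)), class = "screening_report"))
  }
  p <- screen_predicates(tbl, config)
  has_na <- apply(p, 1, anyNA)
  fail_rule <- rep("pass", n)
  fail_rule[has_na] <- "error"
  for (i in which(!has_na)) {
    failed <- SCREEN_RULES[!p[i, SCREEN_RULES]]
    if (length(failed)) fail_rule[i] <- failed[1]
  }
  nf <- stats::setNames(vapply(SCREEN_RULES, function(r) sum(fail_rule == r),
                               integer(1)), SCREEN_RULES)
  passed <- tbl[fail_rule == "pass", , drop = FALSE]
  class(passed) <- c("feature_table", "data.frame")
  structure(list(n_input = n, n_pass = sum(fail_rule == "pass"),
                 n_fail_per_rule = nf, passed = passed,
                 fail_rule = fail_rule,
                 record_errors = which(has_na)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Metabolite screening report\n")
  cat(sprintf("  input records : %d\n", x$n_input))
  cat(sprintf("  passed        : %d\n", x$n_pass))
  for (r in names(x$n_fail_per_rule))
    cat(sprintf("  failed %-6s : %d\n", r, x$n_fail_per_rule[[r]]))
  if (length(x$record_errors))
    cat(sprintf("  record errors : %d\n", length(x$record_errors)))
  invisible(x)
}

#' Assign MSI confidence levels
#'
#' Metabolomics Standards Initiative levels: 1 for compounds confirmed with
#' an authentic standard plus matching MS/MS; 2 for accurate-mass plus
#' MS/MS database annotation; 3 for a database hit without MS2; 4 for
#' unannotated features.
#'
#' @param tbl a [feature_table()] (vectorized over rows).
#' @param standards_list compound names confirmed with authentic standards.
#' @return integer vector of MSI levels in 1..4.
#' @export
assign_msi_level <- function(tbl, standards_list = character()) {
  has_db <- nzchar(tbl$db_hits)
  ms2 <- !is.na(tbl$has_ms2) & tbl$has_ms2
  std <- !is.na(tbl$compound_name) &
    normalize_name(tbl$compound_name) %in% normalize_name(standards_list)
  ifelse(std & ms2, 1L, ifelse(ms2 & has_db, 2L, ifelse(has_db, 3L, 4L)))
}
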