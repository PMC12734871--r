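#' @keywords internal
"_PACKAGE"

## Reference databases queried by Compound Discoverer; db_hits must be a
## subset of these.
DB_SOURCES <- c("mzCloud", "mzVault", "Metabolika", "ChemSpider", "MassList")

## Monoisotopic masses (Da) of the elements seen in annotated natural
## products; sufficient for the CHNOPS + halogen formulas handled here.
MONOISOTOPIC_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, F = 18.9984032, Cl = 34.96885271,
  Br = 78.9183376, I = 126.904473
)

PROTON_MASS <- 1.007276

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a compound name for identity matching
#'
#' Lower-cases, trims, collapses internal whitespace and strips punctuation
#' so that cosmetic spelling variants of the same annotation ("Aloin A",
#' "aloin-A ") compare equal. Used as the compound identity key throughout
#' the comparative module; molecular formulas are never used as keys because
#' isomers (e.g. Aloin A/B) share a formula.
#'
#' @param x character vector of compound names.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_name(c(" Aloin A", "aloin-a"))
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Monoisotopic mass of a molecular formula
#'
#' Parses a Hill-notation formula such as `"C15H10O5"` and returns the
#' neutral monoisotopic mass in Da.
#'
#' @param formula character vector of formulas.
#' @return numeric vector of masses (Da); `NA` for `NA` input.
#' @export
#' @examples
#' formula_mass("C15H10O5") # emodin, 270.0528
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(f))
      stop("malformed molecular formula: ", f, call. = FALSE)
    total <- 0
    for (tok in toks) {
      el <- gsub("[0-9]+", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(MONOISOTOPIC_MASS))
        stop("element not in mass table: ", el, " (formula ", f, ")",
             call. = FALSE)
      total <- total + MONOISOTOPIC_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

## stop() with a consistent error class so callers/tests can distinguish
## configuration errors from data errors.
had_stop <- function(msg, class) {
  stop(structure(class = c(class, "hadmet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
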