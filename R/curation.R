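## curation: expert-concordance scoring of superclass assignments.

#' Concordance between model assignments and expert labels
#'
#' A compound is confirmed when its predicted superclass equals the expert
#' superclass after whitespace/case normalization (exact label match; the
#' superclass vocabulary is closed, so no synonym resolution). Compounds
#' absent from the expert map are listed as `unassigned`; by default they
#' stay in the denominator and count as unconfirmed, with
#' `include_unassigned = FALSE` they are excluded from the denominator.
#' Raw counts are always reported alongside the percentage.
#'
#' @param predicted data.frame with columns `compound` and `superclass`
#'   (e.g. a `class_prediction`).
#' @param expert named character vector (compound -> expert superclass) or
#'   a data.frame with columns `compound`, `superclass`.
#' @param species optional species tag carried into the report.
#' @param include_unassigned keep expert-unlabelled compounds in the
#'   denominator (default `TRUE`).
#' @return a `concordance_report`: `species`, `n_total`, `n_confirmed`,
#'   `concordance_pct` (1 decimal), `discordant` (compound, predicted,
#'   expert), `unassigned` (compound names).
#' @export
#' @examples
#' pred <- data.frame(compound = c("a", "b", "c"),
#'                    superclass = c("Flavonoids", "Flavonoids", "Coumarins"))
#' concordance(pred, c(a = "Flavonoids", b = "Stilbenoids", c = "Coumarins"))
concordance <- function(predicted, expert, species = NA_character_,
                        include_unassigned = TRUE) {
  if (nrow(predicted) == 0)
    had_stop("no predictions to score", "hadmet_domain_error")
  if (is.data.frame(expert)) {
    stopifnot(all(c("compound", "superclass") %in% names(expert)))
    expert <- stats::setNames(as.character(expert$superclass),
                              as.character(expert$compound))
  }
  key <- normalize_name(names(expert))
  lab <- normalize_label(expert)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- tapply(lab, key, function(x) length(unique(x)) > 1)
    if (any(conflict))
      had_stop(paste("conflicting expert labels for:",
                     paste(names(conflict)[conflict], collapse = ", ")),
               "hadmet_validation_error")
    keep <- !dup
    key <- key[keep]; lab <- lab[keep]; expert <- expert[keep]
  }
  emap <- stats::setNames(lab, key)
  eraw <- stats::setNames(as.character(expert), key)

  pkey <- normalize_name(predicted$compound)
  plab <- normalize_label(predicted$superclass)
  known <- pkey %in% names(emap)
  confirmed <- known & plab == unname(emap[pkey])
  n_total <- if (include_unassigned) nrow(predicted) else sum(known)
  n_confirmed <- sum(confirmed)
  discordant <- data.frame(
    compound = predicted$compound[known & !confirmed],
    predicted = predicted$superclass[known & !confirmed],
    expert = unname(eraw[pkey[known & !confirmed]]),
    stringsAsFactors = FALSE)
  structure(list(species = species, n_total = n_total,
                 n_confirmed = n_confirmed,
                 concordance_pct = round(100 * n_confirmed / n_total, 1),
                 discordant = discordant,
                 unassigned = predicted$compound[!known],
                 include_unassigned = include_unassigned),
            class = "concordance_report")
}

## label normalization for matching: case + whitespace folding only
normalize_label <- function(x) gsub("[[:space:]]+", " ",
                                    trimws(tolower(as.character(x))))

#' @export
print.concordance_report <- function(x, ...) {
  sp <- if (is.na(x$species)) "" else paste0(" [", x$species, "]")
  cat(sprintf("Expert concordance%s: %d/%d confirmed (%.1f%%)\n", sp,
              x$n_confirmed, x$n_total, x$concordance_pct))
  if (nrow(x$discordant)) {
    cat("  discordant:\n")
    for (i in seq_len(nrow(x$discordant)))
      cat(sprintf("    %s: predicted '%s', expert '%s'\n",
                  x$discordant$compound[i], x$discordant$predicted[i],
                  x$discordant$expert[i]))
  }
  if (length(x$unassigned))
    cat(sprintf("  unassigned (no expert label): %d\n", length(x$unassigned)))
  invisible(x)
}

#' Write a concordance report as CSV
#' @param report a `concordance_report`.
#' @param path output CSV path (summary row; discordant cases appended with
#'   a `role` column).
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  summary <- data.frame(role = "summary", compound = NA, predicted = NA,
                        expert = NA, species = report$species,
                        n_total = report$n_total,
                        n_confirmed = report$n_confirmed,
                        concordance_pct = report$concordance_pct)
  rows <- summary
  if (nrow(report$discordant)) {
    d <- report$discordant
    rows <- rbind(rows, data.frame(role = "discordant", compound = d$compound,
                                   predicted = d$predicted, expert = d$expert,
                                   species = report$species, n_total = NA,
                                   n_confirmed = NA, concordance_pct = NA))
  }
  if (length(report$unassigned))
    rows <- rbind(rows, data.frame(role = "unassigned",
                                   compound = report$unassigned,
                                   predicted = NA, expert = NA,
                                   species = report$species, n_total = NA,
                                   n_confirmed = NA, concordance_pct = NA))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
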