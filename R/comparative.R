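## comparative: cross-species statistics — Venn membership regions,
## superclass distribution tables, PCA, HCA, heatmap matrices.

#' Construct a species profile
#'
#' The screened, deduplicated compound list of one botanical sample with
#' per-replicate peak areas.
#'
#' @param species species name.
#' @param compounds data.frame with at least `name`; optional `formula`,
#'   `superclass`, `msi_level`. Names must be unique after normalization.
#' @param areas numeric matrix, compounds x replicates (>= 1 column),
#'   nonnegative; column names are replicate ids.
#' @return a `species_profile`.
#' @export
species_profile <- function(species, compounds, areas) {
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  stopifnot("name" %in% names(compounds))
  compounds$norm_name <- normalize_name(compounds$name)
  if (anyDuplicated(compounds$norm_name))
    had_stop(paste("duplicate compound names in profile for", species),
             "hadmet_validation_error")
  areas <- as.matrix(areas)
  stopifnot(nrow(areas) == nrow(compounds), ncol(areas) >= 1)
  if (any(areas < 0, na.rm = TRUE))
    had_stop("peak areas must be nonnegative", "hadmet_validation_error")
  if (is.null(colnames(areas)))
    colnames(areas) <- paste0(species, "_R", seq_len(ncol(areas)))
  structure(list(species = species, compounds = compounds, areas = areas),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("species_profile '%s': %d compounds, %d replicates\n",
              x$species, nrow(x$compounds), ncol(x$areas)))
  invisible(x)
}

#' Collapse screened feature records into a species profile
#'
#' Records sharing a normalized compound name collapse to one compound.
#' When the same name was detected in both ionization modes, the mode with
#' the higher maximum peak area is retained. Per-replicate areas are kept
#' as columns (a record missing in a replicate contributes 0).
#'
#' @param records screened `feature_table` rows for one species (must carry
#'   `compound_name` and `replicate_id`).
#' @param species species name (defaults to the records' species field).
#' @param superclass optional named vector compound -> superclass attached
#'   to the profile.
#' @return a `species_profile`.
#' @export
dedupe_profile <- function(records, species = NULL, superclass = NULL) {
  species <- species %||% records$species[1]
  records <- records[!is.na(records$compound_name), , drop = FALSE]
  records$.norm <- normalize_name(records$compound_name)
  reps <- sort(unique(records$replicate_id))
  if (!length(reps)) reps <- "R1"

  keys <- unique(records$.norm)
  comp <- data.frame(name = character(0), formula = character(0),
                     msi_level = integer(0), stringsAsFactors = FALSE)
  areas <- matrix(0, 0, length(reps), dimnames = list(NULL, reps))
  for (k in keys) {
    rows <- records[records$.norm == k, , drop = FALSE]
    modes <- unique(rows$ion_mode[!is.na(rows$ion_mode)])
    if (length(modes) > 1) {
      best <- vapply(modes, function(m)
        max(rows$peak_area[rows$ion_mode == m], na.rm = TRUE), numeric(1))
      rows <- rows[rows$ion_mode == modes[which.max(best)], , drop = FALSE]
    }
    a <- stats::setNames(numeric(length(reps)), reps)
    for (i in seq_len(nrow(rows))) {
      r <- rows$replicate_id[i] %||% reps[1]
      if (is.na(r)) r <- reps[1]
      a[r] <- max(a[r], rows$peak_area[i], na.rm = TRUE)
    }
    comp <- rbind(comp, data.frame(
      name = rows$compound_name[1], formula = rows$formula[1],
      msi_level = rows$msi_level[1], stringsAsFactors = FALSE))
    areas <- rbind(areas, a)
  }
  rownames(areas) <- NULL
  colnames(areas) <- paste0(species, "_", reps)
  if (!is.null(superclass))
    comp$superclass <- unname(superclass[normalize_name(comp$name)])
  species_profile(species, comp, areas)
}

## ---------------------------------------------------------------------------
## Venn regions

#' Venn membership regions over species compound sets
#'
#' Assigns every compound of the union to the exact subset of species whose
#' profiles contain it (normalized-name identity) and counts the
#' `2^k - 1` nonempty membership regions. With `by = "superclass"` the sets
#' are the superclass labels present in each species instead of compounds.
#'
#' @param profiles list of 2-6 `species_profile` with distinct species.
#' @param by `"compound"` (default) or `"superclass"`.
#' @return a `venn_result`: `region_counts` (named integer over all
#'   regions, names like `"Cascara&Frangula"`), `members` (named list of
#'   per-region member keys), `species`, `n_union`.
#' @export
venn_regions <- function(profiles, by = c("compound", "superclass")) {
  by <- match.arg(by)
  species <- vapply(profiles, function(p) p$species, character(1))
  if (anyDuplicated(species))
    had_stop("duplicate species names across profiles", "hadmet_domain_error")
  if (length(profiles) < 2 || length(profiles) > 6)
    had_stop("venn_regions supports 2-6 profiles", "hadmet_domain_error")
  sets <- lapply(profiles, function(p) {
    if (by == "compound") unique(p$compounds$norm_name)
    else unique(stats::na.omit(p$compounds$superclass))
  })
  names(sets) <- species
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, species))
  pattern <- apply(membership, 1, function(row)
    paste(species[row], collapse = "&"))

  k <- length(species)
  all_regions <- unlist(lapply(seq_len(k), function(m)
    utils::combn(species, m, paste, collapse = "&", simplify = TRUE)))
  counts <- stats::setNames(integer(length(all_regions)), all_regions)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  members <- split(universe, pattern)
  structure(list(region_counts = counts, members = members,
                 species = species, n_union = length(universe), by = by),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("Venn regions over %d %s sets (union %d)\n", length(x$species),
              x$by, x$n_union))
  nz <- x$region_counts[x$region_counts > 0]
  for (r in names(nz)) cat(sprintf("  %-40s %d\n", r, nz[[r]]))
  invisible(x)
}

#' Total overlap between two species (all regions containing both)
#' @param venn a `venn_result`.
#' @param a,b species names.
#' @return integer count of compounds present in both species.
#' @export
venn_pair_overlap <- function(venn, a, b) {
  in_region <- vapply(names(venn$region_counts), function(r) {
    sp <- strsplit(r, "&", fixed = TRUE)[[1]]
    a %in% sp && b %in% sp
  }, logical(1))
  sum(venn$region_counts[in_region])
}

## ---------------------------------------------------------------------------
## Distribution table

#' Superclass x species distribution table
#'
#' Cell (s, p): number of compounds of profile `p` with superclass `s`;
#' per-species percentage columns are appended. Superclasses are ordered by
#' decreasing total count.
#'
#' @param profiles list of `species_profile` whose compounds carry a
#'   `superclass` column.
#' @return data.frame with `superclass`, one count column per species and
#'   one `<species>_pct` column per species.
#' @export
distribution_table <- function(profiles) {
  species <- vapply(profiles, function(p) p$species, character(1))
  supers <- sort(unique(unlist(lapply(profiles, function(p)
    p$compounds$superclass))))
  counts <- sapply(profiles, function(p)
    vapply(supers, function(s)
      sum(!is.na(p$compounds$superclass) & p$compounds$superclass == s),
      integer(1)))
  counts <- matrix(counts, nrow = length(supers),
                   dimnames = list(supers, species))
  ord <- order(rowSums(counts), decreasing = TRUE)
  counts <- counts[ord, , drop = FALSE]
  out <- data.frame(superclass = rownames(counts), counts, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (sp in species) {
    tot <- sum(counts[, sp])
    out[[paste0(sp, "_pct")]] <- if (tot > 0)
      round(100 * counts[, sp] / tot, 1) else 0
  }
  out
}

## ---------------------------------------------------------------------------
## Abundance matrix, PCA, HCA, heatmap

#' Build the compound x replicate abundance matrix
#'
#' Rows are the union of compounds across species (normalized names),
#' columns the sample replicates of every species in order; a compound not
#' detected in a replicate is 0 (absence is informative presence/absence,
#' not missingness, so nothing is imputed).
#'
#' @param profiles list of `species_profile`.
#' @return numeric matrix with `species` and `display_name` attributes.
#' @export
build_abundance_matrix <- function(profiles) {
  rows <- sort(unique(unlist(lapply(profiles, function(p)
    p$compounds$norm_name))))
  display <- character(length(rows)); names(display) <- rows
  cols <- list()
  col_species <- character(0)
  for (p in profiles) {
    m <- matrix(0, length(rows), ncol(p$areas),
                dimnames = list(rows, colnames(p$areas)))
    m[p$compounds$norm_name, ] <- p$areas
    display[p$compounds$norm_name] <- p$compounds$name
    cols[[length(cols) + 1]] <- m
    col_species <- c(col_species, rep(p$species, ncol(p$areas)))
  }
  out <- do.call(cbind, cols)
  attr(out, "species") <- col_species
  attr(out, "display_name") <- unname(display)
  out
}

autoscale_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  keep <- sd > 0
  list(scaled = (m[keep, , drop = FALSE] - mu[keep]) / sd[keep],
       dropped = rownames(m)[!keep])
}

pareto_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  keep <- sd > 0
  list(scaled = (m[keep, , drop = FALSE] - mu[keep]) / sqrt(sd[keep]),
       dropped = rownames(m)[!keep])
}

scale_abundance <- function(matrix, scaling) {
  switch(scaling,
         autoscale = autoscale_rows(matrix),
         pareto = pareto_rows(matrix),
         none = list(scaled = matrix, dropped = character(0)))
}

#' PCA of an abundance matrix
#'
#' Samples (columns) are the observations, compounds (rows) the variables.
#' Default preprocessing is autoscaling (per-compound z-score), matching
#' standard metabolomics practice; constant rows are dropped before scaling
#' and reported. Explained-variance percentages are relative to the total
#' retained variance.
#'
#' @param matrix an abundance matrix from [build_abundance_matrix()].
#' @param scaling `"autoscale"` (default), `"pareto"`, or `"none"`.
#' @return a `pca_result`: `scores` (samples x components),
#'   `explained_variance_pct` (nonincreasing, sums to 100), `loadings`,
#'   `dropped_rows`, `species`.
#' @export
pca_abundance <- function(matrix, scaling = c("autoscale", "pareto", "none")) {
  scaling <- match.arg(scaling)
  if (ncol(matrix) < 2)
    had_stop("PCA needs at least 2 samples", "hadmet_domain_error")
  sc <- scale_abundance(matrix, scaling)
  if (nrow(sc$scaled) < 2)
    had_stop("PCA needs at least 2 nonconstant compounds", "hadmet_domain_error")
  fit <- stats::prcomp(t(sc$scaled), center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  structure(list(scores = fit$x,
                 explained_variance_pct = 100 * ev / sum(ev),
                 loadings = fit$rotation,
                 dropped_rows = sc$dropped,
                 species = attr(matrix, "species"),
                 scaling = scaling),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  v <- x$explained_variance_pct
  cat(sprintf("PCA (%s): PC1 %.1f%%, PC2 %.1f%% of total variance\n",
              x$scaling, v[1], if (length(v) > 1) v[2] else 0))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns on Euclidean distance
#' (the same preprocessing options as [pca_abundance()]; default
#' autoscaling so PCA and HCA describe the same geometry). Returns the
#' standard `hclust` object: `merge`, `height`, `order`, `labels`.
#'
#' @param matrix an abundance matrix.
#' @param linkage `"average"` (default), `"ward"` or `"complete"`.
#' @param scaling as in [pca_abundance()].
#' @return an `hclust` object.
#' @export
hca_abundance <- function(matrix, linkage = c("average", "ward", "complete"),
                          scaling = c("autoscale", "pareto", "none")) {
  linkage <- match.arg(linkage)
  scaling <- match.arg(scaling)
  if (ncol(matrix) < 2)
    had_stop("HCA needs at least 2 samples", "hadmet_domain_error")
  if (anyNA(matrix))
    had_stop("abundance matrix contains NA cells", "hadmet_validation_error")
  sc <- scale_abundance(matrix, scaling)
  d <- stats::dist(t(sc$scaled), method = "euclidean")
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}

#' Superclass x replicate heatmap matrix
#'
#' Cell: the number of compounds of a superclass detected (area > 0) in a
#' replicate — raw counts, not further normalized. Rows and columns are
#' ordered by average-linkage Euclidean clustering of the count matrix.
#'
#' @param profiles list of `species_profile` with superclass labels.
#' @return a `heatmap_matrix`: `counts` (superclass x replicate),
#'   `row_order`, `col_order`, `row_hclust`, `col_hclust`, `species` (per
#'   column).
#' @export
heatmap_matrix <- function(profiles) {
  supers <- sort(unique(unlist(lapply(profiles, function(p)
    p$compounds$superclass))))
  cols <- list(); col_species <- character(0)
  for (p in profiles) {
    cnt <- matrix(0L, length(supers), ncol(p$areas),
                  dimnames = list(supers, colnames(p$areas)))
    for (s in supers) {
      rows <- which(!is.na(p$compounds$superclass) & p$compounds$superclass == s)
      if (length(rows))
        cnt[s, ] <- colSums(p$areas[rows, , drop = FALSE] > 0)
    }
    cols[[length(cols) + 1]] <- cnt
    col_species <- c(col_species, rep(p$species, ncol(p$areas)))
  }
  counts <- do.call(cbind, cols)
  row_h <- if (nrow(counts) > 1)
    stats::hclust(stats::dist(counts), method = "average") else NULL
  col_h <- if (ncol(counts) > 1)
    stats::hclust(stats::dist(t(counts)), method = "average") else NULL
  structure(list(counts = counts,
                 row_order = if (is.null(row_h)) 1L else row_h$order,
                 col_order = if (is.null(col_h)) 1L else col_h$order,
                 row_hclust = row_h, col_hclust = col_h,
                 species = col_species),
            class = "heatmap_matrix")
}
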