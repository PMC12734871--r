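## synthetic_data: generators for every pipeline input, each paired with a
## ground-truth ledger sufficient to predict downstream counts exactly.

DEFAULT_SPECIES <- c("Cascara", "Frangula", "Rhubarb", "Senna")

#' Scaffold families for the molecule generator
#'
#' Four natural-product scaffold templates — flavone, 9,10-anthraquinone,
#' cinnamic acid and stilbene — with `({r})` substitution points and their
#' pathway/superclass/class hierarchy labels. Substituents are drawn from
#' hydroxyl, methoxy, methyl and a glyceryl-ether glycosyl stand-in.
#'
#' @return data.frame: family, template, pathway, superclass, class.
#' @export
scaffold_families <- function() {
  data.frame(
    family = c("flavone", "anthraquinone", "cinnamate", "stilbene"),
    template = c(
      "O=c1cc(-c2ccc({r})cc2)oc2cc({r})cc({r})c12",
      "O=C1c2cc({r})cc({r})c2C(=O)c2cc({r})cc({r})c21",
      "OC(=O)C=Cc1cc({r})c({r})c({r})c1",
      "Oc1cc(C=Cc2ccc({r})c({r})c2)cc({r})c1"),
    pathway = c("Shikimates and Phenylpropanoids", "Polyketides",
                "Shikimates and Phenylpropanoids",
                "Shikimates and Phenylpropanoids"),
    superclass = c("Flavonoids", "Polycyclic aromatic polyketides",
                   "Phenylpropanoids (C6-C3)", "Stilbenoids"),
    class = c("Flavones", "Anthraquinones and anthrones",
              "Cinnamic acids and derivatives", "Stilbenes"),
    stringsAsFactors = FALSE)
}

SUBSTITUENTS <- c("", "O", "OC", "C", "OCC(O)CO")

#' Generator specification
#'
#' Bundles every tunable of the synthetic-data module. Defaults emulate the
#' study conditions: four species in technical triplicate, per-species
#' compound totals 93/83/83/51 realized by [default_region_design()], the
#' per-species superclass distribution of [planted_distribution()], and
#' lognormal peak areas with species-level mean structure.
#'
#' @param seed integer master seed.
#' @param species species names.
#' @param replicates technical replicates per species.
#' @param violation_rates named fractions of rows planted to fail each
#'   screening rule (mutually exclusive per row; remainder passes).
#' @param region_design named integer vector of Venn-region sizes (names
#'   are `&`-joined species subsets); `NULL` for the default design.
#' @param distribution superclass x species count matrix the profile
#'   generator plants; `NULL` for the default (the study's distribution
#'   when `species` are the four defaults).
#' @param area_meanlog named per-species mean of log peak area.
#' @param area_sdlog replicate-level lognormal sd (multiplicative noise).
#' @param shift_sd sd of the per-compound loadings on the two latent
#'   species axes (controls how strongly PCA separates species).
#' @param rt_range retention-time range (min) for passing rows.
#' @return a `generator_spec`.
#' @export
generator_spec <- function(seed = 1, species = DEFAULT_SPECIES,
                           replicates = 3,
                           violation_rates = c(db = 0.05, ppm = 0.10,
                                               rt = 0.05, area = 0.05,
                                               ms2 = 0.05),
                           region_design = NULL, distribution = NULL,
                           area_meanlog = NULL, area_sdlog = 0.15,
                           shift_sd = 0.8, rt_range = c(6, 48)) {
  stopifnot(all(violation_rates >= 0), sum(violation_rates) <= 1,
            replicates >= 1)
  if (is.null(area_meanlog))
    area_meanlog <- stats::setNames(seq(14, 14.6, length.out = length(species)),
                                    species)
  structure(list(seed = seed, species = species, replicates = replicates,
                 violation_rates = violation_rates,
                 region_design = region_design, distribution = distribution,
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 shift_sd = shift_sd, rt_range = rt_range),
            class = "generator_spec")
}

#' Default Venn-region design
#'
#' The membership-region sizes for the four default species: a 4-compound
#' core shared by all, 21 compounds shared by Cascara and Frangula (10
#' exclusive to the pair), 13 shared by Senna and Rhubarb (5 exclusive),
#' and per-species totals of 93, 83, 83 and 51.
#'
#' @param species the four species names, in order.
#' @return named integer vector over the 15 regions.
#' @export
default_region_design <- function(species = DEFAULT_SPECIES) {
  stopifnot(length(species) == 4)
  C <- species[1]; F_ <- species[2]; R <- species[3]; S <- species[4]
  key <- function(...) paste(species[species %in% c(...)], collapse = "&")
  counts <- c(65, 56, 60, 32, 10, 3, 2, 3, 1, 5, 4, 3, 2, 2, 4)
  names(counts) <- c(key(C), key(F_), key(R), key(S),
                     key(C, F_), key(C, R), key(C, S), key(F_, R),
                     key(F_, S), key(R, S),
                     key(C, F_, R), key(C, F_, S), key(C, R, S),
                     key(F_, R, S), key(C, F_, R, S))
  counts
}

#' All-shared region design (every compound in every species)
#' @param species species names.
#' @param n number of shared compounds.
#' @return named integer vector with a single populated (core) region.
#' @export
shared_region_design <- function(species = DEFAULT_SPECIES, n = 100) {
  stats::setNames(n, paste(species, collapse = "&"))
}

#' Planted superclass distribution
#'
#' The superclass x species count table the default profile generator
#' realizes exactly; its column sums equal the per-species compound totals
#' of [default_region_design()].
#'
#' @param species the four species names, in order.
#' @return integer matrix, 19 superclasses x 4 species.
#' @export
planted_distribution <- function(species = DEFAULT_SPECIES) {
  m <- rbind(
    "Flavonoids" = c(50, 49, 52, 21),
    "Phenylpropanoids (C6-C3)" = c(14, 6, 2, 7),
    "Polycyclic aromatic polyketides" = c(9, 10, 10, 11),
    "Isoflavonoids" = c(7, 4, 8, 6),
    "Coumarins" = c(2, 1, 0, 1),
    "Diterpenoids" = c(2, 0, 1, 1),
    "Lignans" = c(2, 0, 0, 1),
    "Benzenoids" = c(1, 0, 0, 1),
    "Monoterpenoids" = c(1, 3, 0, 0),
    "Phloroglucinols" = c(1, 0, 0, 0),
    "Aromatic polyketides" = c(1, 1, 1, 1),
    "Pseudoalkaloids" = c(1, 0, 0, 0),
    "Stilbenoids" = c(1, 2, 3, 0),
    "Tyrosine alkaloids" = c(1, 1, 0, 0),
    "Fatty acids and conjugates" = c(0, 1, 0, 0),
    "Naphthalenes" = c(0, 1, 1, 1),
    "Phenolic acids (C6-C1)" = c(0, 0, 3, 0),
    "Chromanes" = c(0, 0, 2, 0),
    "Unclassified" = c(0, 4, 0, 0))
  colnames(m) <- species
  m
}

random_formula <- function(n) {
  c_n <- sample(10:30, n, replace = TRUE)
  h_n <- pmax(6L, c_n - sample(0:8, n, replace = TRUE))
  o_n <- sample(2:14, n, replace = TRUE)
  sprintf("C%dH%dO%d", c_n, h_n, o_n)
}

#' Generate a Compound-Discoverer-style feature table with planted
#' screening violations
#'
#' Emits `n_rows` feature rows spread over the spec's species and
#' replicates. Each row is planted either to pass all five screening rules
#' or to fail exactly one of them (mutually exclusive, at the spec's
#' per-rule rates): precursor m/z is the protonated/deprotonated formula
#' mass plus ppm noise inside (outside) the tolerance, retention time
#' inside (outside) the window, lognormal areas above (below) the floor,
#' random nonempty (empty) database-hit sets, and MS2 present (absent).
#'
#' @param spec a [generator_spec()].
#' @param n_rows total number of feature rows.
#' @param config the [screening_config()] the violations are planted
#'   against.
#' @param path optional path: when given, the table is also written there
#'   via [write_feature_table()].
#' @return list with `table` (a `feature_table`) and `ledger` (data.frame
#'   `row`, `species`, `replicate_id`, `planted` in
#'   `{"pass","db","ppm","rt","area","ms2"}`).
#' @export
generate_cd_table <- function(spec = generator_spec(), n_rows = 1000,
                              config = screening_config(), path = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  rates <- spec$violation_rates[SCREEN_RULES]
  rates[is.na(rates)] <- 0
  planted <- sample(c(SCREEN_RULES, "pass"), n_rows, replace = TRUE,
                    prob = c(rates, 1 - sum(rates)))
  species <- rep_len(rep(spec$species, each = spec$replicates), n_rows)
  replicate_id <- rep_len(rep(paste0("R", seq_len(spec$replicates)),
                              times = length(spec$species)), n_rows)
  formula <- random_formula(n_rows)
  mw <- formula_mass(formula)
  ion_mode <- sample(c("positive", "negative"), n_rows, replace = TRUE)

  ppm_noise <- stats::runif(n_rows, -0.8, 0.8) * config$ppm_tol
  bad <- planted == "ppm"
  ppm_noise[bad] <- sample(c(-1, 1), sum(bad), replace = TRUE) *
    stats::runif(sum(bad), 1.3, 4) * config$ppm_tol
  mz <- theoretical_mz(mw, ion_mode) * (1 + ppm_noise * 1e-6)

  rt <- stats::runif(n_rows, spec$rt_range[1], spec$rt_range[2])
  bad <- planted == "rt"
  lo <- stats::runif(sum(bad)) < 0.5
  rt[bad][lo] <- stats::runif(sum(lo), 0.2, config$rt_min * 0.9)
  rt[bad][!lo] <- stats::runif(sum(!lo), config$rt_max * 1.05,
                               config$rt_max * 2)

  ml <- spec$area_meanlog[species]
  area <- pmax(stats::rlnorm(n_rows, meanlog = ml, sdlog = 1),
               config$area_min * 1.05)
  bad <- planted == "area"
  area[bad] <- stats::runif(sum(bad), 10, config$area_min * 0.9)

  n_hits <- 1 + stats::rbinom(n_rows, length(DB_SOURCES) - 1, 0.3)
  db_hits <- vapply(n_hits, function(k)
    paste(sort(sample(DB_SOURCES, k)), collapse = ";"), character(1))
  db_hits[planted == "db"] <- ""

  has_ms2 <- rep(TRUE, n_rows)
  has_ms2[planted == "ms2"] <- FALSE

  tbl <- feature_table(data.frame(
    compound_name = sprintf("Feature-%04d", seq_len(n_rows)),
    formula = formula, ion_mode = ion_mode, precursor_mz = mz,
    calc_mw = mw, rt = rt, peak_area = area, db_hits = db_hits,
    has_ms2 = has_ms2, msi_level = NA_integer_,
    species = species, replicate_id = replicate_id,
    stringsAsFactors = FALSE))
  tbl$msi_level <- assign_msi_level(tbl, config$standards_list)
  if (!is.null(path)) write_feature_table(tbl, path)
  list(table = tbl,
       ledger = data.frame(row = seq_len(n_rows), species = species,
                           replicate_id = replicate_id, planted = planted,
                           stringsAsFactors = FALSE))
}

#' Generate scaffold-labelled molecules
#'
#' Builds valid, unique SMILES by random substitution (hydroxyl, methoxy,
#' methyl, glycosyl stand-in, or H) at the `({r})` points of each family
#' template; hierarchy labels are inherited from the family. Every emitted
#' SMILES is checked to parse through [smiles_to_graphs()].
#'
#' @param spec a [generator_spec()] (supplies the seed).
#' @param n_per_family molecules per family.
#' @param families subset of [scaffold_families()] rows (data.frame), at
#'   least 2 families.
#' @return list with `molecules` (data.frame: name, smiles, family,
#'   pathway, superclass, class) and `ledger` (the same data.frame — the
#'   labels are the ground truth).
#' @export
generate_labelled_molecules <- function(spec = generator_spec(),
                                        n_per_family = 100,
                                        families = scaffold_families()[1:3, ]) {
  if (nrow(families) < 2)
    had_stop("need at least 2 scaffold families", "hadmet_domain_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fill <- function(template) {
    while (grepl("({r})", template, fixed = TRUE)) {
      s <- sample(SUBSTITUENTS, 1)
      template <- sub("({r})", if (nzchar(s)) paste0("(", s, ")") else "",
                      template, fixed = TRUE)
    }
    template
  }
  out <- list()
  for (i in seq_len(nrow(families))) {
    fam <- families[i, ]
    n_sites <- lengths(regmatches(fam$template,
                                  gregexpr("({r})", fam$template, fixed = TRUE)))
    max_unique <- length(SUBSTITUENTS)^n_sites
    if (n_per_family > max_unique)
      had_stop(sprintf("family '%s' has only %d distinct substitution patterns",
                       fam$family, max_unique), "hadmet_generation_error")
    seen <- character(0)
    tries <- 0
    while (length(seen) < n_per_family) {
      s <- fill(fam$template)
      if (!s %in% seen) seen <- c(seen, s)
      tries <- tries + 1
      if (tries > 200 * n_per_family)
        had_stop(sprintf("substitution patterns exhausted for family '%s'",
                         fam$family), "hadmet_generation_error")
    }
    out[[i]] <- data.frame(
      name = sprintf("%s-%03d", fam$family, seq_len(n_per_family)),
      smiles = seen, family = fam$family, pathway = fam$pathway,
      superclass = fam$superclass, class = fam$class,
      stringsAsFactors = FALSE)
  }
  molecules <- do.call(rbind, out)
  ## validity contract: every emitted SMILES must parse
  invisible(smiles_to_graphs(molecules$smiles, molecules$name))
  list(molecules = molecules, ledger = molecules)
}

#' Generate multi-species compound profiles with planted structure
#'
#' Realizes the spec's Venn-region design exactly: each region's compounds
#' are present in precisely that subset of species. When the design and
#' species are the defaults, the all-species core carries the names
#' Phloretin, Kaempferol, Hispidulin and 4-Heptyloxyphenol, and the
#' per-species superclass counts equal [planted_distribution()] exactly
#' (shared compounds are Flavonoids apart from the aromatic-polyketide
#' core compound; species-unique compounds fill the remaining counts).
#' Peak areas are lognormal with a per-compound loading on two latent
#' species axes, so species separate in PCA score space.
#'
#' @param spec a [generator_spec()].
#' @return list with `profiles` (list of `species_profile`) and `ledger`
#'   (list: `region_design`, `membership` compound x species logical
#'   matrix, `superclass` named vector, `distribution` planted table,
#'   `expected_log_area` compound x species matrix).
#' @export
generate_species_profiles <- function(spec = generator_spec()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1)
  species <- spec$species
  k <- length(species)
  design <- spec$region_design %||%
    (if (k == 4) default_region_design(species) else
       had_stop("region_design required for non-default species counts",
                "hadmet_validation_error"))
  if (any(design < 0))
    had_stop("negative region sizes", "hadmet_validation_error")
  regions <- names(design)
  region_species <- lapply(regions, function(r) strsplit(r, "&", fixed = TRUE)[[1]])
  if (!all(unlist(region_species) %in% species))
    had_stop("region design names species outside the spec", "hadmet_validation_error")

  n_total <- sum(design)
  membership <- matrix(FALSE, n_total, k, dimnames = list(NULL, species))
  region_of <- character(n_total)
  idx <- 1L
  for (r in seq_along(regions)) {
    if (design[r] == 0) next
    rows <- idx:(idx + design[r] - 1L)
    membership[rows, region_species[[r]]] <- TRUE
    region_of[rows] <- regions[r]
    idx <- idx + design[r]
  }

  ## names: the reported core four for the default all-species region of 4
  name <- sprintf("Cmpd-%04d", seq_len(n_total))
  core_key <- paste(species, collapse = "&")
  core_rows <- which(region_of == core_key)
  core_names <- c("Phloretin", "Kaempferol", "Hispidulin", "4-Heptyloxyphenol")
  use_core_names <- length(core_rows) == 4 && k == 4
  if (use_core_names) name[core_rows] <- core_names

  ## superclass planting
  n_in <- rowSums(membership)
  shared <- n_in > 1
  superclass <- rep(NA_character_, n_total)
  superclass[shared] <- "Flavonoids"
  if (use_core_names)
    superclass[name == "4-Heptyloxyphenol"] <- "Aromatic polyketides"
  dist_target <- spec$distribution %||%
    (if (identical(species, DEFAULT_SPECIES) &&
         identical(design, default_region_design(species)))
      planted_distribution(species) else NULL)
  if (!is.null(dist_target)) {
    for (sp in species) {
      have <- table(superclass[membership[, sp] & shared])
      singles <- which(membership[, sp] & !shared)
      want <- dist_target[, sp]
      fill <- integer(0)
      for (s in rownames(dist_target)) {
        need <- want[[s]] - (if (s %in% names(have)) have[[s]] else 0L)
        if (need < 0)
          had_stop(sprintf(
            "infeasible distribution: %s already exceeds its %s target via shared compounds",
            sp, s), "hadmet_validation_error")
        fill <- c(fill, rep(match(s, rownames(dist_target)), need))
      }
      if (length(fill) != length(singles))
        had_stop(sprintf(
          "infeasible distribution for %s: %d unique compounds but %d needed",
          sp, length(singles), length(fill)), "hadmet_validation_error")
      superclass[singles] <- rownames(dist_target)[fill]
    }
  } else {
    pool <- rownames(planted_distribution())
    superclass[!shared] <- sample(pool, sum(!shared), replace = TRUE)
  }

  formula <- random_formula(n_total)
  onto <- default_ontology()
  loadings <- matrix(stats::rnorm(2 * n_total, sd = spec$shift_sd), n_total, 2)
  coords <- species_axes(species)

  expected_log_area <- matrix(NA_real_, n_total, k,
                              dimnames = list(name, species))
  profiles <- vector("list", k)
  for (si in seq_len(k)) {
    sp <- species[si]
    rows <- which(membership[, sp])
    mu <- spec$area_meanlog[[sp]] + loadings[rows, , drop = FALSE] %*% coords[, si]
    expected_log_area[rows, si] <- mu
    areas <- matrix(
      stats::rlnorm(length(rows) * spec$replicates,
                    meanlog = rep(mu, spec$replicates),
                    sdlog = spec$area_sdlog),
      length(rows), spec$replicates)
    colnames(areas) <- paste0("R", seq_len(spec$replicates))
    comp <- data.frame(name = name[rows], formula = formula[rows],
                       superclass = superclass[rows],
                       msi_level = 2L, stringsAsFactors = FALSE)
    profiles[[si]] <- species_profile(sp, comp, areas)
  }
  names(profiles) <- species

  dist_planted <- t(vapply(sort(unique(superclass)), function(s)
    colSums(membership[superclass == s, , drop = FALSE]), numeric(k)))
  list(profiles = profiles,
       ledger = list(region_design = design,
                     membership = membership,
                     name = name,
                     superclass = stats::setNames(superclass, name),
                     distribution = dist_planted,
                     expected_log_area = expected_log_area))
}

## Two latent axes of between-species variation: axis 1 separates the
## fourth species (Senna-like) from the rest, axis 2 spreads the others.
species_axes <- function(species) {
  k <- length(species)
  a1 <- seq(1.5, -1.5, length.out = k)
  if (k == 4) a1 <- c(1.6, 0.9, 0.8, -2.5)
  a2 <- rep(0, k)
  if (k >= 3) a2[seq_len(k)] <- c(1.2, -0.9, -1.1, 0.2)[seq_len(min(k, 4))]
  rbind(a1, a2)
}

#' Generate expert superclass labels with planted discordances
#'
#' Starts from a profile's true superclass labels and flips
#' `n_discordant` of them to a different superclass (and removes
#' `n_unassigned` compounds from the map), producing an expert-label set
#' whose concordance against the truth is known by construction.
#'
#' @param profile a `species_profile` with superclass labels.
#' @param n_discordant number of labels flipped.
#' @param n_unassigned number of compounds dropped from the expert map.
#' @param seed integer seed.
#' @return list with `expert` (data.frame compound, superclass),
#'   `flipped`, `dropped` (compound names).
#' @export
generate_expert_labels <- function(profile, n_discordant = 3,
                                   n_unassigned = 0, seed = 1) {
  comp <- profile$compounds
  stopifnot(n_discordant + n_unassigned <= nrow(comp))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- sample(nrow(comp), n_discordant + n_unassigned)
  flip <- pick[seq_len(n_discordant)]
  drop <- pick[-seq_len(n_discordant)]
  expert <- data.frame(compound = comp$name, superclass = comp$superclass,
                       stringsAsFactors = FALSE)
  pool <- rownames(planted_distribution())
  for (i in flip) {
    alt <- setdiff(pool, expert$superclass[i])
    expert$superclass[i] <- sample(alt, 1)
  }
  if (length(drop)) expert <- expert[-drop, , drop = FALSE]
  list(expert = expert, flipped = comp$name[flip], dropped = comp$name[drop])
}
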