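test_that("zero violation rates produce an all-pass table", {
  spec <- generator_spec(seed = 3, violation_rates = c(db = 0, ppm = 0,
                                                      rt = 0, area = 0,
                                                      ms2 = 0))
  gen <- generate_cd_table(spec, n_rows = 150)
  rep <- apply_screening(gen$table)
  expect_equal(rep$n_pass, 150L)
  expect_true(all(gen$ledger$planted == "pass"))
})

test_that("a 0.2 ppm-violation rate lands in its binomial 99% interval", {
  spec <- generator_spec(seed = 23, violation_rates = c(db = 0, ppm = 0.2,
                                                       rt = 0, area = 0,
                                                       ms2 = 0))
  gen <- generate_cd_table(spec, n_rows = 500)
  n_fail <- sum(apply_screening(gen$table)$fail_rule == "ppm")
  ci <- qbinom(c(0.005, 0.995), 500, 0.2)
  expect_gte(n_fail, ci[1])
  expect_lte(n_fail, ci[2])
})

test_that("the same seed reproduces byte-identical table files", {
  spec <- generator_spec(seed = 44)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  generate_cd_table(spec, n_rows = 100, path = p1)
  generate_cd_table(spec, n_rows = 100, path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("molecule generation yields valid, unique, labelled SMILES", {
  gen <- generate_labelled_molecules(generator_spec(seed = 9),
                                     n_per_family = 40)
  mol <- gen$molecules
  expect_equal(nrow(mol), 120)
  expect_equal(anyDuplicated(mol$smiles), 0)
  expect_equal(as.integer(table(mol$family)), rep(40L, 3))
  # labels are inherited from the family
  fam <- scaffold_families()
  for (i in seq_len(nrow(mol))) {
    f <- fam[fam$family == mol$family[i], ]
    expect_equal(mol$superclass[i], f$superclass)
    expect_equal(mol$class[i], f$class)
  }
  expect_error(generate_labelled_molecules(
    generator_spec(), families = scaffold_families()[1, , drop = FALSE]),
    class = "hadmet_domain_error")
  # requesting more molecules than distinct substitution patterns fails
  expect_error(generate_labelled_molecules(generator_spec(),
                                           n_per_family = 10000),
               class = "hadmet_generation_error")
})

test_that("species profiles realize the planted region design exactly", {
  gen <- generate_species_profiles(generator_spec(seed = 1))
  profs <- gen$profiles
  expect_equal(vapply(profs, function(p) nrow(p$compounds), integer(1)),
               c(Cascara = 93L, Frangula = 83L, Rhubarb = 83L, Senna = 51L))
  v <- venn_regions(profs)
  design <- default_region_design()
  for (r in names(design))
    expect_equal(unname(v$region_counts[r]), unname(design[r]), info = r)
  expect_equal(unname(v$region_counts[["Cascara&Frangula&Rhubarb&Senna"]]), 4)
  expect_equal(venn_pair_overlap(v, "Cascara", "Frangula"), 21)
  expect_equal(venn_pair_overlap(v, "Rhubarb", "Senna"), 13)
  # the four core compounds carry their reported names
  expect_setequal(v$members[["Cascara&Frangula&Rhubarb&Senna"]],
                  normalize_name(c("Phloretin", "Kaempferol", "Hispidulin",
                                   "4-Heptyloxyphenol")))
})

test_that("planted superclass counts equal the study distribution table", {
  gen <- generate_species_profiles(generator_spec(seed = 10))
  d <- distribution_table(gen$profiles)
  target <- planted_distribution()
  for (sp in colnames(target)) for (s in rownames(target)) {
    got <- d[[sp]][d$superclass == s]
    expect_equal(if (length(got)) got else 0L, target[s, sp],
                 info = paste(sp, s))
  }
  expect_equal(d$Cascara[d$superclass == "Flavonoids"], 50)
})

test_that("profile generation is deterministic and rejects infeasible designs", {
  g1 <- generate_species_profiles(generator_spec(seed = 5))
  g2 <- generate_species_profiles(generator_spec(seed = 5))
  expect_identical(g1$ledger$membership, g2$ledger$membership)
  expect_identical(g1$profiles$Cascara$areas, g2$profiles$Cascara$areas)
  # distribution demanding more compounds than a species has is infeasible
  bad <- planted_distribution()
  bad["Flavonoids", "Senna"] <- 200
  expect_error(generate_species_profiles(
    generator_spec(seed = 1, distribution = bad)),
    class = "hadmet_validation_error")
  expect_error(generate_species_profiles(generator_spec(
    seed = 1, region_design = c(Cascara = -1))),
    class = "hadmet_validation_error")
})

test_that("strong planted mean shifts concentrate PCA variance on two axes", {
  # an all-shared design expresses the two latent species axes in every
  # compound row; with the study-shaped default design species-unique compounds
  # spread the variance over three indicator axes instead
  spec <- generator_spec(seed = 14,
                         region_design = shared_region_design(n = 120))
  gen <- generate_species_profiles(spec)
  mat <- build_abundance_matrix(gen$profiles)
  p <- pca_abundance(mat, scaling = "autoscale")
  expect_gte(sum(p$explained_variance_pct[1:2]), 90)
})

test_that("expert-label planting flips exactly the requested compounds", {
  gen <- generate_species_profiles(generator_spec(seed = 4))
  prof <- gen$profiles$Cascara
  el <- generate_expert_labels(prof, n_discordant = 3, n_unassigned = 2,
                               seed = 11)
  expect_length(el$flipped, 3)
  expect_length(el$dropped, 2)
  expect_equal(nrow(el$expert), nrow(prof$compounds) - 2)
  truth <- setNames(prof$compounds$superclass, prof$compounds$name)
  flipped_now <- el$expert$compound[
    el$expert$superclass != unname(truth[el$expert$compound])]
  expect_setequal(flipped_now, el$flipped)
})
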