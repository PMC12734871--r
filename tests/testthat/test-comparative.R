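profile_from <- function(species, names, superclass = NULL, areas = NULL) {
  n <- length(names)
  comp <- data.frame(name = names, stringsAsFactors = FALSE)
  if (!is.null(superclass)) comp$superclass <- superclass
  if (is.null(areas)) areas <- matrix(1e6, n, 3,
                                      dimnames = list(NULL, paste0("R", 1:3)))
  species_profile(species, comp, areas)
}

test_that("dedupe keeps the higher-area ionization mode of a duplicate", {
  recs <- make_feature_table(
    make_feature_row("Emodin", ion_mode = "positive", peak_area = 2e6,
                     replicate_id = "R1"),
    make_feature_row("Emodin", ion_mode = "negative", peak_area = 9e6,
                     replicate_id = "R1"),
    make_feature_row("Rhein", "C15H8O6", replicate_id = "R2"))
  prof <- dedupe_profile(recs)
  expect_equal(nrow(prof$compounds), 2)
  emodin <- which(prof$compounds$name == "Emodin")
  expect_equal(unname(prof$areas[emodin, "Cascara_R1"]), 9e6)
  # all-unique names pass through one-to-one
  uniq <- make_feature_table(make_feature_row("A"), make_feature_row("B"),
                             make_feature_row("C"))
  expect_equal(nrow(dedupe_profile(uniq)$compounds), 3)
})

test_that("dedupe equals a brute-force group-by on a collision table", {
  set.seed(8)
  names <- sample(sprintf("cmpd-%02d", 1:12), 40, replace = TRUE)
  rows <- lapply(seq_along(names), function(i)
    make_feature_row(names[i],
                     ion_mode = sample(c("positive", "negative"), 1),
                     peak_area = runif(1, 1e5, 1e7),
                     replicate_id = sample(c("R1", "R2", "R3"), 1)))
  recs <- do.call(make_feature_table, rows)
  prof <- dedupe_profile(recs)
  expect_setequal(prof$compounds$norm_name, unique(normalize_name(names)))
  for (k in prof$compounds$norm_name) {
    sub <- recs[normalize_name(recs$compound_name) == k, ]
    best_mode <- if (length(unique(sub$ion_mode)) > 1) {
      by_mode <- tapply(sub$peak_area, sub$ion_mode, max)
      names(by_mode)[which.max(by_mode)]
    } else sub$ion_mode[1]
    kept <- sub[sub$ion_mode == best_mode, ]
    i <- which(prof$compounds$norm_name == k)
    for (r in c("R1", "R2", "R3")) {
      expected <- if (any(kept$replicate_id == r))
        max(kept$peak_area[kept$replicate_id == r]) else 0
      expect_equal(unname(prof$areas[i, paste0("Cascara_", r)]), expected)
    }
  }
})

test_that("degenerate Venn configurations give forced region counts", {
  common <- sprintf("m%02d", 1:7)
  profs <- lapply(c("A", "B", "C", "D"), profile_from, names = common)
  v <- venn_regions(profs)
  expect_equal(unname(v$region_counts[["A&B&C&D"]]), 7)
  expect_equal(sum(v$region_counts), 7)

  disjoint <- lapply(1:4, function(i)
    profile_from(LETTERS[i], sprintf("s%d-%02d", i, 1:(i + 2))))
  v2 <- venn_regions(disjoint)
  singles <- v2$region_counts[LETTERS[1:4]]
  expect_equal(unname(singles), 3:6)
  expect_equal(sum(v2$region_counts), sum(3:6))
  expect_error(venn_regions(list(profs[[1]], profs[[1]])),
               class = "hadmet_domain_error")
})

test_that("random 4-set instances match the 2^4 membership-pattern oracle", {
  set.seed(13)
  pool <- sprintf("cmpd-%02d", 1:50)
  for (rep in 1:10) {
    sets <- lapply(1:4, function(i) sample(pool, sample(5:40, 1)))
    profs <- Map(profile_from, LETTERS[1:4], sets)
    v <- venn_regions(profs)
    # oracle: enumerate each union member's membership pattern
    universe <- unique(unlist(sets))
    oracle <- table(vapply(universe, function(m) {
      inset <- vapply(sets, function(s) m %in% s, logical(1))
      paste(LETTERS[1:4][inset], collapse = "&")
    }, character(1)))
    expect_equal(sum(v$region_counts), length(universe))
    for (r in names(v$region_counts)) {
      expected <- if (r %in% names(oracle)) unname(oracle[r]) else 0L
      expect_equal(unname(v$region_counts[r]), as.integer(expected), info = r)
    }
  }
})

test_that("distribution tables tally superclasses with percentages", {
  p1 <- profile_from("A", c("x", "y", "z"), rep("Flavonoids", 3))
  p2 <- profile_from("B", c("u", "v"), c("Flavonoids", "Coumarins"))
  d <- distribution_table(list(p1, p2))
  expect_equal(d$A[d$superclass == "Flavonoids"], 3)
  expect_equal(d$A_pct[d$superclass == "Flavonoids"], 100)
  expect_equal(d$B_pct[d$superclass == "Coumarins"], 50)
  # column sums equal per-species compound counts
  expect_equal(sum(d$A), 3); expect_equal(sum(d$B), 2)
  # empty profile contributes a zero column
  p3 <- species_profile("C", data.frame(name = character(0)),
                        matrix(0, 0, 1, dimnames = list(NULL, "R1")))
  d3 <- distribution_table(list(p1, p3))
  expect_equal(sum(d3$C), 0)
})

test_that("abundance matrices align the compound union across replicates", {
  profs <- generate_species_profiles(generator_spec(seed = 2))$profiles
  mat <- build_abundance_matrix(profs)
  expect_equal(ncol(mat), 12) # 4 species x 3 technical replicates
  expect_equal(nrow(mat), 252)
  expect_true(all(mat >= 0))
  gen <- generate_species_profiles(generator_spec(seed = 2))
  # zeros exactly where the ledger says a compound is absent
  mem <- gen$ledger$membership
  rownames(mem) <- normalize_name(gen$ledger$name)
  for (sp in colnames(mem)) {
    cols <- attr(mat, "species") == sp
    detected <- rowSums(mat[, cols, drop = FALSE]) > 0
    expect_equal(unname(detected), unname(mem[rownames(mat), sp]))
  }
})

test_that("PCA limits: rank-1 data explains 100% on PC1; duplicates coincide", {
  base <- runif(20, 1, 5)
  m <- outer(base, c(1, 2, 3, 4.5)) # samples proportional -> rank 1
  colnames(m) <- paste0("S", 1:4)
  p <- pca_abundance(m, scaling = "none")
  expect_equal(p$explained_variance_pct[1], 100, tolerance = 1e-8)
  m2 <- cbind(m, m[, 2, drop = FALSE])
  p2 <- pca_abundance(m2, scaling = "none")
  expect_equal(p2$scores[2, ], p2$scores[5, ], tolerance = 1e-8)
  expect_true(all(diff(p2$explained_variance_pct) <= 1e-9))
  expect_lte(sum(p2$explained_variance_pct), 100 + 1e-6)
})

test_that("PCA matches an eigendecomposition oracle on a hand matrix", {
  m <- rbind(c(1, 2, 3), c(2, 1, 5), c(0.5, 4, 2), c(3, 3, 3.5))
  colnames(m) <- c("a", "b", "c")
  p <- pca_abundance(m, scaling = "autoscale")
  # oracle: eigenvalues of the sample covariance of the scaled samples
  sc <- t(scale(t(m))) # row z-scores
  cov <- stats::cov(t(sc))
  ev <- sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
  ev <- ev[ev > 1e-12]
  expect_equal(p$explained_variance_pct[seq_along(ev)],
               100 * ev / sum(ev), tolerance = 1e-8)
})

test_that("PCA drops constant rows and requires enough samples", {
  m <- rbind(rep(5, 4), c(1, 2, 3, 4), c(4, 1, 2, 2))
  rownames(m) <- c("const", "v1", "v2")
  p <- pca_abundance(m)
  expect_equal(p$dropped_rows, "const")
  expect_error(pca_abundance(m[, 1, drop = FALSE]),
               class = "hadmet_domain_error")
})

test_that("HCA forced geometries and the brute-force agglomeration oracle", {
  m <- cbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(9, 9, 9))
  h <- hca_abundance(m, scaling = "none")
  expect_equal(h$height[1], 0) # identical samples merge first at height 0
  # an outlier merges last
  m2 <- cbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(0.5, 1), s4 = c(40, 40))
  h2 <- hca_abundance(m2, scaling = "none")
  expect_true(-4 %in% h2$merge[nrow(h2$merge), ]) # s4 joins in the last merge
  expect_false(is.unsorted(h2$height))

  set.seed(19)
  for (rep in 1:5) {
    m3 <- matrix(runif(5 * 6), 5, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
    h3 <- hca_abundance(m3, linkage = "average", scaling = "none")
    expect_equal(h3$height, oracle_average_linkage_heights(m3),
                 tolerance = 1e-10)
  }
  m3[1, 1] <- NA
  expect_error(hca_abundance(m3), class = "hadmet_validation_error")
})

test_that("heatmap matrices count detected compounds per superclass/replicate", {
  areas <- rbind(c(1e6, 0, 1e6), c(2e6, 2e6, 0), c(0, 0, 5e5))
  colnames(areas) <- paste0("R", 1:3)
  p <- species_profile("A",
                       data.frame(name = c("x", "y", "z"),
                                  superclass = c("Flavonoids", "Flavonoids",
                                                 "Coumarins")),
                       areas)
  hm <- heatmap_matrix(list(p))
  expect_equal(unname(hm$counts["Flavonoids", ]), c(2, 1, 1))
  expect_equal(unname(hm$counts["Coumarins", ]), c(0, 0, 1))
  # bounded by the per-species compound totals
  expect_true(all(hm$counts <= nrow(p$compounds)))
  # single-superclass data yields one row
  p2 <- profile_from("B", c("u", "v"), rep("Flavonoids", 2))
  expect_equal(nrow(heatmap_matrix(list(p2))$counts), 1)
})

test_that("planted generator profiles reproduce their heatmap ledger", {
  gen <- generate_species_profiles(generator_spec(seed = 6))
  hm <- heatmap_matrix(gen$profiles)
  expect_equal(ncol(hm$counts), 12)
  expect_equal(nrow(hm$counts), 19)
  # all areas are positive, so counts equal the planted distribution
  dist <- planted_distribution()
  for (sp in colnames(dist)) {
    cols <- hm$species == sp
    for (s in rownames(dist))
      expect_equal(unname(hm$counts[s, cols]), rep(dist[s, sp], 3),
                   info = paste(sp, s))
  }
})
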