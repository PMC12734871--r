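test_that("stratified folds balance classes exactly when counts force it", {
  labels <- rep(c("a", "b"), each = 10)
  folds <- stratified_folds(labels, k = 10, seed = 1)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(labels[f], c("a", "b"))
  }
  # partition property
  expect_setequal(unlist(folds), seq_along(labels))
})

test_that("single-class input yields a plain balanced k-way split", {
  folds <- stratified_folds(rep("x", 23), k = 5, seed = 2)
  sizes <- lengths(folds)
  expect_equal(sum(sizes), 23)
  expect_lte(diff(range(sizes)), 1)
})

test_that("stratification holds on random label vectors (counting oracle)", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(30:120, 1)
    k <- sample(3:10, 1)
    labels <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    folds <- stratified_folds(labels, k = k, seed = rep)
    expect_setequal(unlist(folds), seq_len(n))
    expect_equal(anyDuplicated(unlist(folds)), 0)
    for (cl in unique(labels)) {
      n_c <- sum(labels == cl)
      per_fold <- vapply(folds, function(f) sum(labels[f] == cl), integer(1))
      expect_lte(max(per_fold), ceiling(n_c / k))
      expect_gte(min(per_fold), floor(n_c / k))
    }
  }
  expect_error(stratified_folds(c("a", "b"), k = 3),
               class = "hadmet_domain_error")
  expect_error(stratified_folds(letters, k = 1),
               class = "hadmet_domain_error")
})

test_that("macro-F1 matches hand-computed contingency values on 3-class toys", {
  truth <- rep(c("a", "b", "c"), each = 4)
  expect_equal(macro_f1(truth, truth), 1.0)
  # constant classifier on a balanced 3-class set:
  # F1(a) = 2*4/(2*4 + 8 + 0) = 0.5, F1(b) = F1(c) = 0 -> macro 1/6
  expect_equal(macro_f1(truth, rep("a", 12)), 1 / 6)
  # one b<->c swap: F1(a)=1; F1(b)=F1(c)=2*3/(2*3+1+1)=0.75 -> mean 2.5/3
  pred <- truth; pred[5] <- "c"; pred[9] <- "b"
  expect_equal(macro_f1(truth, pred), (1 + 0.75 + 0.75) / 3)
  expect_equal(accuracy(truth, pred), 10 / 12)
})

test_that("training is deterministic under a fixed seed", {
  fx <- small_molecule_fixture()
  hyper <- gin_hyper(n_layers = 2, hidden = 12, epochs = 15)
  m1 <- train_level_model(fx$batch, fx$molecules$superclass, "superclass",
                          hyper, seed = 9, k = 5)
  m2 <- train_level_model(fx$batch, fx$molecules$superclass, "superclass",
                          hyper, seed = 9, k = 5)
  expect_identical(m1$cv$per_fold, m2$cv$per_fold)
  expect_identical(m1$model$params, m2$model$params)
})

test_that("degenerate single-label training is refused", {
  fx <- small_molecule_fixture()
  expect_error(train_level_model(fx$batch, rep("only", nrow(fx$molecules)),
                                 "superclass"),
               "vacuous", class = "hadmet_domain_error")
})

test_that("hierarchy predictions are confident, consistent and normalized", {
  fx <- small_molecule_fixture()
  models <- small_model_fixture()
  preds <- predict_hierarchy(models, fx$batch)
  expect_equal(nrow(preds), nrow(fx$molecules))
  expect_true(all(preds$pathway_conf >= 0 & preds$pathway_conf <= 1))
  # the scaffold task is separable: labels recovered at every level
  expect_gte(mean(preds$superclass == fx$molecules$superclass), 0.95)
  expect_gte(mean(preds$class == fx$molecules$class), 0.95)
  # full distributions sum to 1
  probs <- gin_predict(models$superclass$model, fx$batch)
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  # consistency flag agrees with an explicit ontology lookup
  onto <- default_ontology()
  par <- ontology_parents(onto, preds$class)
  expect_equal(preds$consistent,
               !is.na(par$superclass) & par$superclass == preds$superclass &
                 par$pathway == preds$pathway)
})

test_that("flag_low_confidence equals a brute-force scan and orders ascending", {
  fx <- small_molecule_fixture()
  preds <- predict_hierarchy(small_model_fixture(), fx$batch)
  flagged <- flag_low_confidence(preds, threshold = 0.99)
  mc <- pmin(preds$pathway_conf, preds$superclass_conf, preds$class_conf)
  brute <- preds$compound[mc < 0.99 | !preds$consistent]
  expect_setequal(flagged$compound, brute)
  expect_false(is.unsorted(flagged$min_conf))
  all_consistent <- preds[preds$consistent, , drop = FALSE]
  expect_equal(nrow(flag_low_confidence(all_consistent, 0)), 0)
  expect_setequal(flag_low_confidence(preds, 1)$compound,
                  preds$compound[mc < 1 | !preds$consistent])
})

test_that("rare classes merge into per-superclass other buckets", {
  cls <- c(rep("Flavones", 12), rep("Flavonols", 3), rep("Stilbenes", 11))
  sc <- c(rep("Flavonoids", 15), rep("Stilbenoids", 11))
  merged <- merge_rare_classes(cls, sc, min_n = 10)
  expect_equal(unique(merged[cls == "Flavonols"]), "Other Flavonoids")
  expect_equal(merged[cls == "Flavones"], rep("Flavones", 12))
})

test_that("model bundles round-trip through the JSON persistence", {
  fx <- small_molecule_fixture()
  models <- small_model_fixture()
  dir <- withr::local_tempdir()
  save_level_models(models, dir)
  expect_setequal(list.files(dir), c("pathway.json", "superclass.json",
                                     "class.json"))
  back <- load_level_models(dir)
  p1 <- gin_predict(models$superclass$model, fx$batch)
  p2 <- gin_predict(back$superclass, fx$batch)
  expect_equal(p1, p2, tolerance = 1e-12)
})
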