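## np_classifier: per-level GIN training with stratified cross-validation,
## hierarchical prediction with confidences, and confidence-based curation.

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members round-robin over
#' the folds, rotating the starting fold between classes so remainders
#' spread evenly. Per fold, each class count differs from `n_c / k` by at
#' most 1; classes with fewer than `k` members are distributed round-robin.
#'
#' @param labels vector of class labels, one per sample.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the shuffles.
#' @return list of `k` integer index vectors partitioning `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  n <- length(labels)
  if (k < 2) had_stop("k must be >= 2", "hadmet_domain_error")
  if (k > n) had_stop("k exceeds the number of samples", "hadmet_domain_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    f <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (i in seq_len(k)) folds[[i]] <- c(folds[[i]], idx[f == i])
    offset <- (offset + length(idx)) %% k
  }
  lapply(folds, sort)
}

#' Macro-averaged F1 score
#'
#' Mean of per-class F1 over `levels` (union of truth and prediction labels
#' by default); a class with no true and no predicted members contributes
#' F1 = 0, the strict convention.
#'
#' @param truth,pred label vectors of equal length.
#' @param levels label set to average over.
#' @return macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  levels <- levels %||% sort(unique(c(truth, pred)))
  f1 <- vapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Classification accuracy
#' @inheritParams macro_f1
#' @return fraction of exact matches.
#' @export
accuracy <- function(truth, pred) mean(as.character(truth) == as.character(pred))

#' Merge rare classes into per-superclass "other" buckets
#'
#' Class-level labels with fewer than `min_n` training examples are renamed
#' `"Other <superclass>"` so that stratified folds keep at least one example
#' of every label per fold.
#'
#' @param class_labels character vector of class labels.
#' @param superclass_labels matching superclass labels.
#' @param min_n minimum class size kept un-merged.
#' @return character vector of (possibly merged) class labels.
#' @export
merge_rare_classes <- function(class_labels, superclass_labels, min_n = 10) {
  tab <- table(class_labels)
  rare <- names(tab)[tab < min_n]
  out <- as.character(class_labels)
  sel <- out %in% rare
  out[sel] <- paste("Other", superclass_labels[sel])
  out
}

#' Train a per-level GIN with stratified 10-fold cross-validation
#'
#' For the requested hierarchy level, runs stratified k-fold CV (each fold
#' trained from a seed derived from `seed`, so reruns reproduce the report
#' exactly), then refits a final model on all data. Performance is reported
#' as per-fold macro-averaged F1 and accuracy with their mean and sd.
#'
#' @param graphs list of `mol_graph` (or a prebuilt `graph_batch`).
#' @param labels label vector for the level, one per graph.
#' @param level `"pathway"`, `"superclass"` or `"class"`.
#' @param hyper a [gin_hyper()].
#' @param seed integer seed controlling fold assignment and weight init.
#' @param k folds (default 10).
#' @return a `level_model`: list with `model` (the refit `gin_model`),
#'   `level`, `label_set`, and `cv` (a `cv_report` with per-fold metrics).
#' @export
train_level_model <- function(graphs, labels, level = c("superclass",
                                                        "pathway", "class"),
                              hyper = gin_hyper(), seed = 1, k = 10) {
  level <- match.arg(level)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    had_stop("single-label dataset: classification at this level is vacuous",
             "hadmet_domain_error")
  batch <- if (inherits(graphs, "graph_batch")) graphs else
    featurize_batch(graphs)
  stopifnot(length(labels) == length(batch$n_nodes))

  folds <- stratified_folds(labels, k = k, seed = seed)
  per_fold <- data.frame(fold = seq_len(k), macro_f1 = NA_real_,
                         accuracy = NA_real_)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    tr <- subset_batch(batch, train_idx)
    te <- subset_batch(batch, test_idx)
    fit <- gin_train(tr, labels[train_idx], hyper, seed = seed + i)
    probs <- gin_predict(fit, te)
    pred <- fit$label_set[max.col(probs, ties.method = "first")]
    per_fold$macro_f1[i] <- macro_f1(labels[test_idx], pred,
                                     levels = levels(labels))
    per_fold$accuracy[i] <- accuracy(labels[test_idx], pred)
  }
  final <- gin_train(batch, labels, hyper, seed = seed)
  cv <- structure(list(level = level, per_fold = per_fold,
                       mean_macro_f1 = mean(per_fold$macro_f1),
                       sd_macro_f1 = stats::sd(per_fold$macro_f1),
                       mean_accuracy = mean(per_fold$accuracy),
                       sd_accuracy = stats::sd(per_fold$accuracy),
                       k = k, seed = seed),
                  class = "cv_report")
  structure(list(model = final, level = level,
                 label_set = final$label_set, cv = cv),
            class = "level_model")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV at level '%s' (seed %d)\n", x$k,
              x$level, x$seed))
  cat(sprintf("  macro-F1 : %.3f +/- %.3f\n", x$mean_macro_f1, x$sd_macro_f1))
  cat(sprintf("  accuracy : %.3f +/- %.3f\n", x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

## Restrict a featurized batch to a subset of its graphs.
subset_batch <- function(batch, idx) {
  keep_nodes <- unlist(lapply(idx, function(k) {
    off <- sum(batch$n_nodes[seq_len(k - 1)])
    off + seq_len(batch$n_nodes[k])
  }))
  n_nodes <- batch$n_nodes[idx]
  A <- batch$A[keep_nodes, keep_nodes, drop = FALSE]
  P <- Matrix::sparseMatrix(i = rep(seq_along(idx), n_nodes),
                            j = seq_len(length(keep_nodes)), x = 1,
                            dims = c(length(idx), length(keep_nodes)))
  structure(list(X = batch$X[keep_nodes, , drop = FALSE], A = A, P = P,
                 graph_names = batch$graph_names[idx], n_nodes = n_nodes,
                 vocab = batch$vocab),
            class = "graph_batch")
}

#' Hierarchical prediction for molecules
#'
#' Applies the three independently trained level models and reports, per
#' molecule, the argmax label and its softmax confidence at each level
#' (ties broken by label order), plus a `consistent` flag that is `TRUE`
#' iff the predicted class's ontology parents equal the predicted
#' superclass and pathway. With `mask_inconsistent = TRUE`, class logits
#' are restricted to children of the predicted superclass before the
#' argmax (a stricter decoding mode; confidences are renormalized).
#'
#' @param models named list with elements `pathway`, `superclass`, `class`
#'   (each a `level_model` or `gin_model`).
#' @param graphs list of `mol_graph` or a `graph_batch` (must be featurized
#'   with the shared model vocabulary if prebuilt).
#' @param ontology an `ontology` for the consistency check.
#' @param mask_inconsistent restrict class predictions to children of the
#'   predicted superclass.
#' @return a `class_prediction` data.frame: `compound`, then per level a
#'   label and confidence column, and `consistent`.
#' @export
predict_hierarchy <- function(models, graphs, ontology = default_ontology(),
                              mask_inconsistent = FALSE) {
  getm <- function(x) if (inherits(x, "level_model")) x$model else x
  ms <- lapply(models[c("pathway", "superclass", "class")], getm)
  if (any(vapply(ms, is.null, logical(1))))
    had_stop("models must be a named list with pathway, superclass and class entries",
             "hadmet_domain_error")
  batch <- if (inherits(graphs, "graph_batch")) graphs else
    featurize_batch(graphs, vocab = ms$superclass$vocab)

  probs <- lapply(ms, gin_predict, batch = batch)
  pick <- function(p) {
    j <- max.col(p, ties.method = "first")
    list(label = colnames(p)[j], conf = p[cbind(seq_len(nrow(p)), j)])
  }
  pw <- pick(probs$pathway)
  sc <- pick(probs$superclass)
  if (mask_inconsistent) {
    pcl <- probs$class
    for (i in seq_len(nrow(pcl))) {
      children <- names(ontology$class_parent)[
        ontology$class_parent == sc$label[i]]
      keep <- colnames(pcl) %in% children
      if (any(keep)) {
        pcl[i, !keep] <- 0
        pcl[i, ] <- pcl[i, ] / sum(pcl[i, ])
      }
    }
    cl <- pick(pcl)
  } else cl <- pick(probs$class)

  par <- ontology_parents(ontology, cl$label)
  consistent <- !is.na(par$superclass) & par$superclass == sc$label &
    !is.na(par$pathway) & par$pathway == pw$label
  out <- data.frame(compound = batch$graph_names,
                    pathway = pw$label, pathway_conf = pw$conf,
                    superclass = sc$label, superclass_conf = sc$conf,
                    class = cl$label, class_conf = cl$conf,
                    consistent = consistent,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_prediction", "data.frame")
  out
}

#' Flag predictions for manual curation
#'
#' Returns the predictions whose minimum per-level confidence falls below
#' `threshold`, or whose hierarchy is inconsistent, ordered ascending by
#' that minimum confidence — the review queue an analyst would work
#' through first.
#'
#' @param predictions a `class_prediction` data.frame.
#' @param threshold confidence threshold in `[0, 1]`.
#' @return subset of `predictions` with an extra `min_conf` column.
#' @export
flag_low_confidence <- function(predictions, threshold = 0.99) {
  stopifnot(threshold >= 0, threshold <= 1)
  mc <- pmin(predictions$pathway_conf, predictions$superclass_conf,
             predictions$class_conf)
  sel <- mc < threshold | !predictions$consistent
  out <- predictions[sel, , drop = FALSE]
  out$min_conf <- mc[sel]
  out[order(out$min_conf), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Model bundle persistence (text/JSON, no binary blobs).

#' Save / load a hierarchy of level models
#'
#' The bundle is a directory holding one JSON file per level with the
#' architecture spec, the label set, the feature vocabulary and the flat
#' parameter vector — plain text, re-loadable with [load_level_models()].
#'
#' @param models named list of `level_model`/`gin_model` per level.
#' @param dir bundle directory (created if needed).
#' @return `dir` (save) or the named model list (load), invisibly.
#' @export
save_level_models <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lvl in names(models)) {
    m <- if (inherits(models[[lvl]], "level_model")) models[[lvl]]$model else
      models[[lvl]]
    obj <- list(level = lvl, label_set = m$label_set,
                hyper = unclass(m$hyper), seed = m$seed,
                vocab = unclass(m$vocab),
                theta = flatten_params(m$params),
                d_in = nrow(m$params$layers[[1]]$W1))
    jsonlite::write_json(obj, file.path(dir, paste0(lvl, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname save_level_models
#' @export
load_level_models <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  out <- list()
  for (f in files) {
    o <- jsonlite::read_json(f, simplifyVector = TRUE)
    hyper <- do.call(gin_hyper, o$hyper)
    template <- local({
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(0)
      gin_init(o$d_in, length(o$label_set), hyper)
    })
    params <- unflatten_params(as.numeric(o$theta), template)
    vocab <- structure(o$vocab, class = "graph_vocab")
    vocab$elements <- as.character(vocab$elements)
    out[[o$level]] <- structure(
      list(params = params, label_set = o$label_set, hyper = hyper,
           vocab = vocab, seed = o$seed),
      class = "gin_model")
  }
  invisible(out)
}
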