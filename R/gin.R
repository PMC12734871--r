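## gin: a Graph Isomorphism Network for whole-molecule classification,
## implemented directly in dense/sparse linear algebra.
##
## Each layer computes H' = MLP((1 + eps) * H + A %*% H) with a two-layer
## ReLU MLP; the readout is sum pooling over the nodes of each graph
## followed by a linear layer and softmax. Sum aggregation plus shared
## per-node transformations make the whole map invariant to atom input
## order. Training is full-batch Adam on the mean cross-entropy.

#' GIN hyperparameters
#'
#' @param n_layers number of GIN message-passing layers.
#' @param hidden hidden width of every layer MLP.
#' @param epochs training epochs (full-batch).
#' @param lr Adam learning rate.
#' @param dropout dropout probability on hidden node states during training.
#' @param eps the GIN self-weighting; `(1 + eps)` multiplies the central
#'   node before aggregation. Fixed (not learned).
#' @return a `gin_hyper` list.
#' @export
gin_hyper <- function(n_layers = 3, hidden = 32, epochs = 60, lr = 0.01,
                      dropout = 0.1, eps = 0) {
  stopifnot(n_layers >= 1, hidden >= 2, epochs >= 1, lr > 0,
            dropout >= 0, dropout < 1)
  structure(list(n_layers = n_layers, hidden = hidden, epochs = epochs,
                 lr = lr, dropout = dropout, eps = eps),
            class = "gin_hyper")
}

## He-scaled parameter initialization; RNG state is the caller's seed.
gin_init <- function(d_in, n_classes, hyper) {
  lin <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / a)), a, b)
  layers <- vector("list", hyper$n_layers)
  d <- d_in
  for (l in seq_len(hyper$n_layers)) {
    layers[[l]] <- list(W1 = lin(d, hyper$hidden), b1 = numeric(hyper$hidden),
                        W2 = lin(hyper$hidden, hyper$hidden),
                        b2 = numeric(hyper$hidden))
    d <- hyper$hidden
  }
  list(layers = layers,
       Wo = lin(hyper$hidden, n_classes), bo = numeric(n_classes))
}

relu <- function(x) x * (x > 0)

add_bias <- function(M, b) sweep(M, 2, b, `+`)

## Forward pass. When `keep` is TRUE the intermediate activations needed by
## backprop are returned. Dropout masks are sampled from the current RNG.
gin_forward <- function(params, batch, hyper, training = FALSE, keep = FALSE) {
  H <- batch$X
  cache <- if (keep) list(H0 = H) else NULL
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    S <- as.matrix(batch$A %*% H) + (1 + hyper$eps) * H
    Z1 <- add_bias(S %*% ly$W1, ly$b1)
    H1 <- relu(Z1)
    Z2 <- add_bias(H1 %*% ly$W2, ly$b2)
    H <- relu(Z2)
    if (training && hyper$dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= hyper$dropout,
                     nrow(H), ncol(H)) / (1 - hyper$dropout)
      H <- H * mask
    } else mask <- NULL
    if (keep) cache[[paste0("l", l)]] <- list(S = S, Z1 = Z1, H1 = H1,
                                              Z2 = Z2, mask = mask, Hout = H)
  }
  G <- as.matrix(batch$P %*% H)
  logits <- add_bias(G %*% params$Wo, params$bo)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  if (keep) { cache$G <- G; cache$probs <- probs }
  list(logits = logits, probs = probs, cache = cache)
}

## Mean cross-entropy loss and full gradient via backprop.
gin_loss_grad <- function(params, batch, y_idx, hyper) {
  fw <- gin_forward(params, batch, hyper, training = TRUE, keep = TRUE)
  cache <- fw$cache
  n <- nrow(fw$probs)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), y_idx)], 1e-12)))

  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y_idx)] <- dlogits[cbind(seq_len(n), y_idx)] - 1
  dlogits <- dlogits / n

  grads <- list(Wo = crossprod(cache$G, dlogits), bo = colSums(dlogits),
                layers = vector("list", length(params$layers)))
  dG <- tcrossprod(dlogits, params$Wo)            # n_graphs x hidden
  dH <- as.matrix(Matrix::crossprod(batch$P, dG)) # nodes x hidden
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    cc <- cache[[paste0("l", l)]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dZ2 <- dH * (cc$Z2 > 0)
    gW2 <- crossprod(cc$H1, dZ2); gb2 <- colSums(dZ2)
    dH1 <- tcrossprod(dZ2, ly$W2)
    dZ1 <- dH1 * (cc$Z1 > 0)
    gW1 <- crossprod(cc$S, dZ1); gb1 <- colSums(dZ1)
    dS <- tcrossprod(dZ1, ly$W1)
    dH <- as.matrix(batch$A %*% dS) + (1 + hyper$eps) * dS  # A symmetric
    grads$layers[[l]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  list(loss = loss, grads = grads)
}

## Flatten/unflatten parameters so Adam state is a single vector pair.
flatten_params <- function(p) {
  unlist(c(lapply(p$layers, function(l) list(l$W1, l$b1, l$W2, l$b2)),
           list(p$Wo, p$bo)), use.names = FALSE)
}
unflatten_params <- function(v, template) {
  out <- template; pos <- 1
  take <- function(x) {
    n <- length(x)
    r <- v[pos:(pos + n - 1)]; pos <<- pos + n
    if (is.matrix(x)) matrix(r, nrow(x), ncol(x)) else r
  }
  for (l in seq_along(out$layers)) {
    out$layers[[l]]$W1 <- take(template$layers[[l]]$W1)
    out$layers[[l]]$b1 <- take(template$layers[[l]]$b1)
    out$layers[[l]]$W2 <- take(template$layers[[l]]$W2)
    out$layers[[l]]$b2 <- take(template$layers[[l]]$b2)
  }
  out$Wo <- take(template$Wo); out$bo <- take(template$bo)
  out
}

#' Train a GIN classifier on a featurized graph batch
#'
#' Deterministic given (`batch`, `labels`, `hyper`, `seed`): the seed fixes
#' weight initialization and the dropout stream. Training is full-batch
#' Adam on mean cross-entropy for a fixed number of epochs.
#'
#' @param batch a `graph_batch` from [featurize_batch()].
#' @param labels factor of graph labels (one per graph in the batch).
#' @param hyper a [gin_hyper()].
#' @param seed integer seed.
#' @return a `gin_model`: parameters, label levels, hyper, vocab.
#' @export
gin_train <- function(batch, labels, hyper = gin_hyper(), seed = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    had_stop("training needs at least 2 distinct labels; classification is vacuous otherwise",
             "hadmet_domain_error")
  stopifnot(length(labels) == length(batch$n_nodes))
  y_idx <- as.integer(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- gin_init(ncol(batch$X), nlevels(labels), hyper)
  ## Adam state
  theta <- flatten_params(params)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsi <- 1e-8
  for (t in seq_len(hyper$epochs)) {
    lg <- gin_loss_grad(params, batch, y_idx, hyper)
    g <- flatten_params(lg$grads)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    theta <- theta - hyper$lr * mh / (sqrt(vh) + epsi)
    params <- unflatten_params(theta, params)
  }
  structure(list(params = params, label_set = levels(labels), hyper = hyper,
                 vocab = batch$vocab, seed = seed),
            class = "gin_model")
}

#' Predict class probabilities with a trained GIN
#'
#' @param model a `gin_model`.
#' @param batch a `graph_batch` featurized with the model's vocabulary.
#' @return matrix (graphs x labels) of softmax probabilities; rows sum to 1.
#' @export
gin_predict <- function(model, batch) {
  fw <- gin_forward(model$params, batch, model$hyper)
  colnames(fw$probs) <- model$label_set
  rownames(fw$probs) <- batch$graph_names
  fw$probs
}

## Save/restore the global RNG state so model fitting does not perturb the
## caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
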