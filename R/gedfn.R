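# Graph-embedded deep feedforward network. The first layer is d -> d with its
# weight matrix Hadamard-multiplied by the binary feature-graph mask inside the
# forward pass, so masked slots contribute exactly zero and receive exactly
# zero gradient; dense hidden layers and a two-class softmax head follow:
#   Z1 = sigma(X (W_in . G) + b_in),  Z_{k+1} = sigma(Z_k W_k + b_k),
#   y  = softmax(Z_out W_out + b_out).

#' Network hyperparameter configuration
#'
#' Defaults: one masked d x d layer followed by dense layers of 64 and 16
#' units, rectifier activation, adaptive-moment (Adam) minimization of
#' class-weighted cross-entropy for 100 epochs at learning rate 1e-3, batch
#' size 32, L2 penalty 1e-4, dropout 0.1, training-fold standardization, and
#' balanced (inverse-prevalence) class weighting — sensible for the ~1:5.6
#' imbalanced tables this model targets.
#'
#' @param hidden integer vector of dense layer sizes after the masked layer.
#' @param activation "relu", "sigmoid" or "tanh".
#' @param learningRate positive step size.
#' @param epochs training epochs.
#' @param batchSize mini-batch size (training n must be >= batchSize).
#' @param l2 non-negative L2 penalty on all weights.
#' @param dropout dropout probability in [0, 1) on hidden activations.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param standardize z-score features using training statistics.
#' @param classWeighting "balanced" (inverse prevalence) or "none".
#' @return list of validated settings.
#' @export
netConfig <- function(hidden = c(64L, 16L), activation = c("relu", "sigmoid", "tanh"),
                      learningRate = 1e-3, epochs = 100L, batchSize = 32L,
                      l2 = 1e-4, dropout = 0.1, seed = 1L, standardize = TRUE,
                      classWeighting = c("balanced", "none")) {
  activation <- match.arg(activation)
  classWeighting <- match.arg(classWeighting)
  stopifnot(all(hidden >= 1L), learningRate > 0, epochs >= 1L, batchSize >= 1L,
    l2 >= 0, dropout >= 0, dropout < 1)
  list(hidden = as.integer(hidden), activation = activation,
    learningRate = learningRate, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), l2 = l2, dropout = dropout,
    seed = as.integer(seed), standardize = isTRUE(standardize),
    classWeighting = classWeighting)
}

.activate <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), sigmoid = 1 / (1 + exp(-z)), tanh = tanh(z))
}
.activateGrad <- function(z, kind) {
  switch(kind, relu = (z > 0) * 1,
    sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
    tanh = 1 - tanh(z)^2)
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a forgeNet model
#'
#' Chains the two halves of the method: (1) a tree ensemble is fitted to the
#' training data and its per-tree feature graphs are unioned and realized as a
#' binary d x d mask; (2) the graph-embedded network is trained by mini-batch
#' gradient descent on class-weighted cross-entropy, with the first-layer
#' weights Hadamard-masked so that masked slots stay exactly zero in every
#' forward pass and every update. Standardization statistics come from the
#' training data only. Fully reproducible given the seeds.
#'
#' @param X \linkS4class{FeatureMatrix} or numeric matrix (n x d).
#' @param y binary labels 0/1, both classes present.
#' @param forestParams list passed to \code{\link{fitForest}} (ntree, mtry,
#'   nodesize, maxnodes, seed).
#' @param config network settings from \code{\link{netConfig}}.
#' @param mask optional precomputed \linkS4class{MaskMatrix}; when supplied the
#'   forest step is skipped.
#' @param symmetrize,selfLoops mask realization options (see
#'   \code{\link{graphToMask}}).
#' @return a \linkS4class{ForgeNetModel}.
#' @export
trainForgeNet <- function(X, y, forestParams = list(), config = netConfig(),
                          mask = NULL, symmetrize = TRUE, selfLoops = TRUE) {
  tag <- if (is(X, "FeatureMatrix")) featureSetTag(X) else "custom"
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  y <- .checkBinaryLabels(y, nrow(X))
  d <- ncol(X)
  if (nrow(X) < config$batchSize)
    stop("training size must be at least batchSize")
  forest <- NULL
  if (is.null(mask)) {
    forest <- do.call(fitForest, c(list(X = X, y = y), forestParams))
    mask <- graphToMask(forestToGraph(forest), symmetrize = symmetrize,
      selfLoops = selfLoops)
  }
  M <- maskValues(mask)
  if (nrow(M) != d) stop("mask dimension must equal feature count")

  if (config$standardize) {
    mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
  } else {
    mu <- rep(0, d); sdv <- rep(1, d)
  }
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  set.seed(config$seed)
  sizes <- c(d, d, config$hidden, 2L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
      sd = sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  W[[1L]] <- W[[1L]] * M  # masked slots start (and stay) at zero

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8; t <- 0L

  n <- nrow(Xs)
  wts <- if (config$classWeighting == "balanced") {
    tabl <- table(factor(y, levels = c(0, 1)))
    as.numeric((n / (2 * tabl))[as.character(y)])
  } else rep(1, n)
  Y <- cbind(1 - y, y)

  act <- config$activation
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0
    for (idx in batches) {
      t <- t + 1L
      Xb <- Xs[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      wb <- wts[idx]; sw <- sum(wb)
      # forward
      A <- vector("list", L); Z <- vector("list", L); drop <- vector("list", L)
      a <- Xb
      for (l in seq_len(L)) {
        Wl <- if (l == 1L) W[[1L]] * M else W[[l]]
        A[[l]] <- a
        z <- sweep(a %*% Wl, 2L, b[[l]], "+")
        Z[[l]] <- z
        if (l < L) {
          a <- .activate(z, act)
          if (config$dropout > 0) {
            dm <- matrix(stats::rbinom(length(a), 1L, 1 - config$dropout),
              nrow(a)) / (1 - config$dropout)
            a <- a * dm
            drop[[l]] <- dm
          }
        } else a <- z
      }
      P <- .softmax(a)
      loss <- -sum(wb * log(pmax(P[cbind(seq_along(idx), Yb[, 2L] + 1L)], 1e-12))) / sw
      epochLoss <- epochLoss + loss * length(idx)
      # backward (gradients with the pre-update weights)
      delta <- (P - Yb) * (wb / sw)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(A[[l]], delta) + config$l2 * W[[l]]
        gb[[l]] <- colSums(delta)
        if (l == 1L) gW[[1L]] <- gW[[1L]] * M
        if (l > 1L) {
          Wl <- if (l == 1L) W[[1L]] * M else W[[l]]
          da <- tcrossprod(delta, Wl)
          da <- da * .activateGrad(Z[[l - 1L]], act)
          if (!is.null(drop[[l - 1L]])) da <- da * drop[[l - 1L]]
          delta <- da
        }
      }
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        W[[l]] <- W[[l]] - config$learningRate *
          (mW[[l]] / (1 - beta1^t)) / (sqrt(vW[[l]] / (1 - beta2^t)) + adamEps)
        b[[l]] <- b[[l]] - config$learningRate *
          (mb[[l]] / (1 - beta1^t)) / (sqrt(vb[[l]] / (1 - beta2^t)) + adamEps)
      }
      W[[1L]] <- W[[1L]] * M
    }
    if (!is.finite(epochLoss))
      stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", epoch))
  }

  new("ForgeNetModel", forest = forest, mask = mask, weights = W, biases = b,
    standardization = list(mean = mu, sd = sdv), config = config,
    featureSetTag = tag)
}

#' Forward pass: class probabilities
#'
#' Deterministic inference pass (dropout off): standardizes with the stored
#' training statistics, applies the masked first layer, the dense layers and
#' the softmax head. Rows sum to one.
#'
#' @param model a \linkS4class{ForgeNetModel}.
#' @param X matrix or \linkS4class{FeatureMatrix} with the model's feature
#'   count.
#' @return n x 2 matrix of class probabilities (columns: inactive, active).
#' @export
forwardPass <- function(model, X) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  d <- nrow(maskValues(model))
  if (ncol(X) != d)
    stop(sprintf("X has %d columns but the model expects %d", ncol(X), d))
  Xs <- sweep(sweep(X, 2L, model@standardization$mean), 2L,
    model@standardization$sd, "/")
  M <- maskValues(model)
  a <- Xs
  L <- length(model@weights)
  for (l in seq_len(L)) {
    Wl <- if (l == 1L) model@weights[[1L]] * M else model@weights[[l]]
    z <- sweep(a %*% Wl, 2L, model@biases[[l]], "+")
    a <- if (l < L) .activate(z, model@config$activation) else z
  }
  P <- .softmax(a)
  colnames(P) <- c("inactive", "active")
  rownames(P) <- rownames(X)
  P
}

#' Predicted active-class probability per compound
#'
#' @param model a \linkS4class{ForgeNetModel}.
#' @param X \linkS4class{FeatureMatrix} whose feature-set tag matches the
#'   model's training tag, or a plain matrix with matching width.
#' @return numeric vector of active-class probabilities in [0, 1].
#' @export
predictProba <- function(model, X) {
  if (is(X, "FeatureMatrix") && !identical(featureSetTag(X), featureSetTag(model)))
    stop(sprintf("feature set mismatch: model was trained on '%s', input is '%s'",
      featureSetTag(model), featureSetTag(X)))
  forwardPass(model, X)[, "active"]
}

#' @describeIn predictProba standard predict method; \code{type = "prob"}
#'   returns the two-column probability matrix, \code{type = "active"} (default)
#'   the active-class probability vector.
#' @param object a \linkS4class{ForgeNetModel}.
#' @param type "active" or "prob".
#' @param ... unused.
#' @export
setMethod("predict", "ForgeNetModel", function(object, X,
    type = c("active", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") forwardPass(object, X) else predictProba(object, X)
})

.writeNumericCsv <- function(x, path) {
  txt <- apply(rbind(x), 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}
.readNumericCsv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Persist / restore a fitted model as a text directory
#'
#' The model directory holds the configuration as YAML, the mask as sparse
#' coordinate triplets (TSV), and weights, biases and standardization
#' statistics as full-precision CSV. The tree ensemble itself is not persisted
#' (the mask it produced is); reloaded models predict identically.
#'
#' @param model a \linkS4class{ForgeNetModel}.
#' @param dir directory to create/fill.
#' @return \code{dir}, invisibly.
#' @export
saveForgeNetModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  cfg$featureSetTag <- featureSetTag(model)
  cfg$hidden <- as.list(cfg$hidden)
  cfg$maskSymmetrized <- model@mask@symmetrized
  cfg$maskSelfLoops <- model@mask@selfLoops
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  M <- maskValues(model@mask)
  ones <- which(M == 1, arr.ind = TRUE)
  utils::write.table(
    data.frame(d = nrow(M), row = ones[, 1L], col = ones[, 2L]),
    file.path(dir, "mask.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(mean = sprintf("%.17g", model@standardization$mean),
      sd = sprintf("%.17g", model@standardization$sd)),
    file.path(dir, "standardization.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  for (l in seq_along(model@weights)) {
    .writeNumericCsv(model@weights[[l]], file.path(dir, sprintf("weights_%d.csv", l)))
    .writeNumericCsv(model@biases[[l]], file.path(dir, sprintf("biases_%d.csv", l)))
  }
  invisible(dir)
}

#' @rdname saveForgeNetModel
#' @export
loadForgeNetModel <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  tag <- cfg$featureSetTag
  sym <- cfg$maskSymmetrized; loops <- cfg$maskSelfLoops
  cfg$featureSetTag <- NULL; cfg$maskSymmetrized <- NULL; cfg$maskSelfLoops <- NULL
  cfg$hidden <- as.integer(unlist(cfg$hidden))
  mt <- utils::read.table(file.path(dir, "mask.tsv"), header = TRUE, sep = "\t")
  d <- mt$d[1L]
  M <- matrix(0, d, d)
  M[cbind(mt$row, mt$col)] <- 1
  mask <- new("MaskMatrix", m = M, symmetrized = sym, selfLoops = loops)
  st <- utils::read.table(file.path(dir, "standardization.csv"), header = TRUE,
    sep = ",")
  nW <- length(list.files(dir, pattern = "^weights_[0-9]+\\.csv$"))
  W <- lapply(seq_len(nW), function(l)
    .readNumericCsv(file.path(dir, sprintf("weights_%d.csv", l))))
  b <- lapply(seq_len(nW), function(l)
    as.numeric(.readNumericCsv(file.path(dir, sprintf("biases_%d.csv", l)))))
  new("ForgeNetModel", forest = NULL, mask = mask, weights = W, biases = b,
    standardization = list(mean = as.numeric(st$mean), sd = as.numeric(st$sd)),
    config = cfg, featureSetTag = tag)
}
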