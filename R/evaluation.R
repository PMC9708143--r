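#' Confusion counts from binary truth and predictions
#'
#' The positive class is the active class (label 1); sensitivity is the
#' true-positive rate on actives.
#'
#' @param truth binary 0/1 vector.
#' @param predicted binary 0/1 vector.
#' @return named integer vector with TP, FP, TN, FN.
#' @export
confusionCounts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  c(TP = sum(truth == 1L & predicted == 1L),
    FP = sum(truth == 0L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FN = sum(truth == 1L & predicted == 0L))
}

#' Classification metrics from confusion counts
#'
#' Standard definitions: SN = TP/(TP+FN), SP = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN), Matthews correlation
#' MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and Cohen's kappa
#' (po - pe)/(1 - pe) with po = (TP+TN)/n and
#' pe = ((TP+FP)(TP+FN) + (TN+FN)(TN+FP))/n^2. A metric whose denominator
#' degenerates to zero is defined as 0 and flagged in the
#' \code{"degenerate"} attribute.
#'
#' @param counts named vector with TP, FP, TN, FN (see
#'   \code{\link{confusionCounts}}).
#' @return named numeric vector (SN, SP, Kappa, MCC, F1) with a
#'   \code{degenerate} attribute naming zero-denominator metrics.
#' @export
computeMetrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  n <- TP + FP + TN + FN
  if (n <= 0) stop("empty confusion table")
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  SN <- safe(TP, TP + FN, "SN")
  SP <- safe(TN, TN + FP, "SP")
  F1 <- safe(2 * TP, 2 * TP + FP + FN, "F1")
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  MCC <- safe(TP * TN - FP * FN, mccDen, "MCC")
  po <- (TP + TN) / n
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  Kappa <- safe(po - pe, 1 - pe, "Kappa")
  structure(c(SN = SN, SP = SP, Kappa = Kappa, MCC = MCC, F1 = F1),
    degenerate = degenerate)
}

#' ROC and PR curves with trapezoidal AUC
#'
#' Curves are evaluated at every distinct score threshold. The ROC curve is
#' (FPR, TPR); the PR curve is (Recall, Precision). Both areas are computed by
#' trapezoidal integration over the curve points.
#'
#' @param yTrue binary 0/1 labels; both classes must be present.
#' @param scores numeric scores (higher = more active).
#' @return list with \code{roc} (data.frame threshold, FPR, TPR), \code{pr}
#'   (data.frame threshold, Recall, Precision), \code{roc_auc}, \code{pr_auc}.
#' @export
rocPrCurves <- function(yTrue, scores) {
  yTrue <- as.integer(yTrue)
  stopifnot(length(yTrue) == length(scores))
  nPos <- sum(yTrue == 1L); nNeg <- sum(yTrue == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute ROC/PR curves")
  ord <- order(scores, decreasing = TRUE)
  ys <- yTrue[ord]; ss <- scores[ord]
  cumTP <- cumsum(ys == 1L); cumFP <- cumsum(ys == 0L)
  last <- !duplicated(ss, fromLast = TRUE)  # last index of each distinct score
  thr <- ss[last]
  TPR <- cumTP[last] / nPos
  FPR <- cumFP[last] / nNeg
  precision <- cumTP[last] / (cumTP[last] + cumFP[last])
  roc <- data.frame(threshold = c(Inf, thr), FPR = c(0, FPR), TPR = c(0, TPR))
  pr <- data.frame(threshold = thr, Recall = TPR, Precision = precision)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  roc_auc <- trapz(roc$FPR, roc$TPR)
  # anchor the PR staircase at the smallest attained recall with its precision
  prx <- c(pr$Recall[1L], pr$Recall); pry <- c(pr$Precision[1L], pr$Precision)
  pr_auc <- trapz(prx, pry) + pr$Recall[1L] * pr$Precision[1L]
  list(roc = roc, pr = pr, roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Classifier adapters with a common fit/score contract
#'
#' Wraps off-the-shelf baselines behind the contract \code{fit(X, y, seed)} ->
#' model and \code{score(model, X)} -> active-class probability, so
#' \code{\link{crossValidate}} can compare them with forgeNet: \code{"rf"}
#' (random forest), \code{"lr"} (logistic regression), \code{"nb"} (naive
#' Bayes).
#'
#' @param tag one of "rf", "lr", "nb".
#' @param ... extra arguments stored for the underlying fit (e.g. ntree).
#' @return classifier specification list with elements tag, fit, score.
#' @export
baselineAdapter <- function(tag = c("rf", "lr", "nb"), ...) {
  tag <- match.arg(tag)
  extra <- list(...)
  spec <- switch(tag,
    rf = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        do.call(randomForest::randomForest,
          c(list(x = X, y = factor(y, levels = c(0, 1))),
            if (length(extra)) extra else list(ntree = 500L)))
      },
      score = function(model, X) unname(stats::predict(model, X, type = "prob")[, "1"])),
    lr = list(
      fit = function(X, y, seed) {
        df <- data.frame(.y = y, X)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      score = function(model, X)
        unname(suppressWarnings(stats::predict(model, data.frame(X), type = "response")))),
    nb = list(
      fit = function(X, y, seed) e1071::naiveBayes(x = X, y = factor(y, levels = c(0, 1))),
      score = function(model, X)
        unname(stats::predict(model, X, type = "raw")[, "1"]))
  )
  c(list(tag = tag), spec)
}

#' forgeNet as a classifier specification
#'
#' @param forestParams list passed to \code{\link{fitForest}}.
#' @param config network configuration; its seed is replaced by the per-fold
#'   seed supplied by \code{\link{crossValidate}}.
#' @return classifier specification list (tag, fit, score).
#' @export
forgeNetClassifier <- function(forestParams = list(), config = netConfig()) {
  list(tag = "forgenet",
    fit = function(X, y, seed) {
      cfg <- config; cfg$seed <- as.integer(seed)
      fp <- forestParams; fp$seed <- as.integer(seed)
      trainForgeNet(X, y, forestParams = fp, config = cfg)
    },
    score = function(model, X) unname(predictProba(model, X)))
}

# Stratified fold assignment. Each class is spread as evenly as possible over
# the k folds; the two classes receive their remainder folds in opposite order
# so total fold sizes stay as equal as stratification permits (966 at k = 3
# gives exactly 322/322/322). Uses the caller's RNG state.
.stratifiedFolds <- function(y, k) {
  foldId <- integer(length(y))
  idx1 <- which(y == 1L); idx0 <- which(y == 0L)
  foldId[idx1] <- sample(rep(seq_len(k), length.out = length(idx1)))
  foldId[idx0] <- sample(rep(rev(seq_len(k)), length.out = length(idx0)))
  foldId
}

.deriveSeed <- function(seed, r, fold = 0L) {
  as.integer((as.numeric(seed) * 7919 + r * 104729 + fold * 31 + 17) %% 2147483647)
}

#' Repeated stratified k-fold / leave-one-out cross-validation
#'
#' Folds are stratified by class and reshuffled for each repeat from a
#' per-repeat seed. Each fold's model is trained on its training split only
#' (standardization and forest included), scored on the held-out split, hard
#' labels taken at probability 0.5, and SN/SP/Kappa/MCC/F1 plus trapezoidal
#' ROC/PR AUC recorded. Under leave-one-out the n held-out predictions of a
#' repeat are pooled into one row. The aggregate is mean and SD (n-1
#' denominator) over all rows.
#'
#' @param classifier a specification from \code{\link{baselineAdapter}} or
#'   \code{\link{forgeNetClassifier}}.
#' @param X numeric matrix or \linkS4class{FeatureMatrix}.
#' @param y binary 0/1 labels.
#' @param k folds (3, 5, 10, any 2 <= k <= n) or \code{"loo"}.
#' @param repeats number of repeats (default 10).
#' @param seed integer master seed; identical seed reproduces the report.
#' @return an \linkS4class{EvalReport}.
#' @export
crossValidate <- function(classifier, X, y, k = 5L, repeats = 10L, seed = 1L) {
  tag <- if (is(X, "FeatureMatrix")) featureSetTag(X) else "custom"
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  y <- .checkBinaryLabels(y, nrow(X))
  n <- nrow(X)
  loo <- identical(k, "loo")
  if (!loo) {
    k <- as.integer(k)
    if (k > n) stop("k must not exceed the number of samples")
    if (k < 2L) stop("k must be at least 2")
    if (min(table(y)) < k)
      stop("stratification infeasible: the minority class has fewer samples than folds")
  }
  metricNames <- c("SN", "SP", "Kappa", "MCC", "F1", "ROC_AUC", "PR_AUC")
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(.deriveSeed(seed, r))
    if (loo) {
      scores <- numeric(n)
      for (i in seq_len(n)) {
        model <- classifier$fit(X[-i, , drop = FALSE], y[-i],
          seed = .deriveSeed(seed, r, i))
        scores[i] <- classifier$score(model, X[i, , drop = FALSE])
      }
      mets <- computeMetrics(confusionCounts(y, as.integer(scores >= 0.5)))
      curves <- rocPrCurves(y, scores)
      rows[[length(rows) + 1L]] <- data.frame(repeatIdx = r, fold = NA_integer_,
        t(c(mets, ROC_AUC = curves$roc_auc, PR_AUC = curves$pr_auc)))
    } else {
      foldId <- .stratifiedFolds(y, k)
      for (f in seq_len(k)) {
        test <- which(foldId == f)
        model <- classifier$fit(X[-test, , drop = FALSE], y[-test],
          seed = .deriveSeed(seed, r, f))
        scores <- classifier$score(model, X[test, , drop = FALSE])
        mets <- computeMetrics(confusionCounts(y[test], as.integer(scores >= 0.5)))
        curves <- rocPrCurves(y[test], scores)
        rows[[length(rows) + 1L]] <- data.frame(repeatIdx = r, fold = f,
          t(c(mets, ROC_AUC = curves$roc_auc, PR_AUC = curves$pr_auc)))
      }
    }
  }
  perFold <- do.call(rbind, rows)
  aggregate <- data.frame(
    metric = metricNames,
    mean = vapply(metricNames, function(m) mean(perFold[[m]]), 0),
    sd = vapply(metricNames, function(m) stats::sd(perFold[[m]]), 0),
    row.names = NULL)
  new("EvalReport", perFold = perFold, aggregate = aggregate,
    protocol = list(k = if (loo) "loo" else k, repeats = as.integer(repeats),
      seed = as.integer(seed), classifier = classifier$tag,
      featureSetTag = tag))
}

#' Write an EvalReport as tidy CSV files
#'
#' Writes \code{per_fold.csv} (one row per fold x repeat x metric, long format)
#' and \code{summary.csv} (metric, mean, sd) into a directory.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- perFoldMetrics(report)
  metricNames <- setdiff(names(pf), c("repeatIdx", "fold"))
  long <- do.call(rbind, lapply(metricNames, function(m)
    data.frame(repeatIdx = pf$repeatIdx, fold = pf$fold, metric = m,
      value = pf[[m]])))
  utils::write.csv(long, file.path(dir, "per_fold.csv"), row.names = FALSE)
  utils::write.csv(aggregateMetrics(report), file.path(dir, "summary.csv"),
    row.names = FALSE)
  invisible(dir)
}
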