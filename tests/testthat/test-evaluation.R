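test_that("metrics are exact on canonical confusion tables", {
  perfect <- computeMetrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(as.numeric(perfect), rep(1, 5))
  chance <- computeMetrics(c(TP = 5, FP = 5, TN = 5, FN = 5))
  expect_equal(unname(chance[c("SN", "SP")]), c(0.5, 0.5))
  expect_equal(unname(chance[c("Kappa", "MCC")]), c(0, 0))
  expect_error(computeMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
})

test_that("metrics match independent closed-form oracles on random tables", {
  set.seed(101)
  for (i in seq_len(1000)) {
    counts <- randomConfusion()
    got <- computeMetrics(counts)
    TP <- counts[["TP"]]; FP <- counts[["FP"]]
    TN <- counts[["TN"]]; FN <- counts[["FN"]]
    # direct-formula oracles, written independently of the implementation
    if (TP + FN > 0) expect_equal(unname(got["SN"]), TP / (TP + FN), tolerance = 1e-12)
    if (TN + FP > 0) expect_equal(unname(got["SP"]), TN / (TN + FP), tolerance = 1e-12)
    if (2 * TP + FP + FN > 0)
      expect_equal(unname(got["F1"]), 2 * TP / (2 * TP + FP + FN), tolerance = 1e-12)
    ex <- expandConfusion(counts)
    # MCC equals the Pearson correlation of the binary label vectors
    if (stats::sd(ex$truth) > 0 && stats::sd(ex$pred) > 0)
      expect_equal(unname(got["MCC"]), stats::cor(ex$truth, ex$pred),
        tolerance = 1e-12)
    # Cohen's kappa from an independent implementation
    tab <- table(factor(ex$pred, levels = 0:1), factor(ex$truth, levels = 0:1))
    kap <- e1071::classAgreement(tab)$kappa
    if (is.finite(kap)) expect_equal(unname(got["Kappa"]), kap, tolerance = 1e-12)
  }
})

test_that("degenerate denominators yield zero and are flagged", {
  m <- computeMetrics(c(TP = 0, FP = 3, TN = 5, FN = 0))
  expect_equal(unname(m["SN"]), 0)
  expect_true("SN" %in% attr(m, "degenerate"))
})

test_that("ROC AUC equals exhaustive concordance counting, with and without ties", {
  set.seed(7)
  # perfect separation
  y <- rep(c(0L, 1L), 50)
  expect_equal(rocPrCurves(y, y)$roc_auc, 1)
  # random scores, continuous and heavily tied, n up to 300
  for (i in 1:25) {
    n <- sample(20:300, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- if (i %% 2 == 0) rnorm(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    res <- rocPrCurves(y, s)
    expect_equal(res$roc_auc, concordanceAUC(y, s), tolerance = 1e-12)
    expect_true(all(res$pr$Precision >= 0 & res$pr$Precision <= 1))
  }
  expect_error(rocPrCurves(rep(1L, 10), rnorm(10)), "both classes")
})

test_that("ROC and PR AUC agree with an independent curve implementation", {
  set.seed(17)
  y <- rbinom(200, 1, 0.25)
  s <- rnorm(200) + y
  res <- rocPrCurves(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(res$roc_auc, ref, tolerance = 1e-10)
})

test_that("chance-level scores give AUC near one half at large n", {
  set.seed(23)
  y <- rbinom(4000, 1, 0.5)
  s <- rnorm(4000)
  expect_lt(abs(rocPrCurves(y, s)$roc_auc - 0.5), 0.05)
})

test_that("cross-validation is perfect on a separable problem and fully reproducible", {
  toy <- separableToy(n = 90)
  for (k in c(3L, 5L)) {
    rep1 <- crossValidate(baselineAdapter("lr"), toy$X, toy$y, k = k,
      repeats = 2L, seed = 11L)
    agg <- aggregateMetrics(rep1)
    expect_equal(agg$mean[agg$metric == "SN"], 1)
    expect_equal(agg$mean[agg$metric == "SP"], 1)
    expect_equal(agg$sd[agg$metric == "SN"], 0)
  }
  a <- crossValidate(baselineAdapter("rf", ntree = 30L), toy$X, toy$y,
    k = 3L, repeats = 2L, seed = 5L)
  b <- crossValidate(baselineAdapter("rf", ntree = 30L), toy$X, toy$y,
    k = 3L, repeats = 2L, seed = 5L)
  expect_identical(perFoldMetrics(a), perFoldMetrics(b))
  expect_identical(aggregateMetrics(a), aggregateMetrics(b))
})

test_that("stratified folds at the reference size split 966 samples into thirds", {
  y <- c(rep(1L, 146), rep(0L, 820))
  set.seed(1)
  folds <- forgeNet:::.stratifiedFolds(y, 3L)
  expect_identical(as.integer(table(folds)), rep(322L, 3L))
  # every fold contains both classes
  for (f in 1:3) expect_identical(sort(unique(y[folds == f])), c(0L, 1L))
})

test_that("the aggregate block is recomputable from the per-fold rows", {
  toy <- separableToy(n = 60)
  set.seed(2)
  toy$y[sample(60, 12)] <- 1L - toy$y[sample(60, 12)]  # add noise
  rep <- crossValidate(baselineAdapter("nb"), toy$X, toy$y, k = 5L,
    repeats = 3L, seed = 3L)
  pf <- perFoldMetrics(rep)
  agg <- aggregateMetrics(rep)
  for (m in agg$metric) {
    expect_equal(agg$mean[agg$metric == m], mean(pf[[m]]), tolerance = 1e-12)
    expect_equal(agg$sd[agg$metric == m], stats::sd(pf[[m]]), tolerance = 1e-12)
  }
})

test_that("leave-one-out pools held-out predictions into one row per repeat", {
  toy <- separableToy(n = 24)
  rep <- crossValidate(baselineAdapter("nb"), toy$X, toy$y, k = "loo",
    repeats = 2L, seed = 9L)
  pf <- perFoldMetrics(rep)
  expect_identical(nrow(pf), 2L)
  expect_true(all(is.na(pf$fold)))
  expect_true(all(pf$SN >= 0 & pf$SN <= 1))
})

test_that("fold models never see held-out rows or labels", {
  toy <- separableToy(n = 60)
  seen <- list()
  spy <- list(tag = "spy",
    fit = function(X, y, seed) {
      seen[[length(seen) + 1L]] <<- list(n = nrow(X), keys = rowSums(X))
      list(mean1 = colMeans(X[y == 1, , drop = FALSE]))
    },
    score = function(model, X) {
      d <- sqrt(rowSums(sweep(X, 2, model$mean1)^2))
      1 / (1 + d)
    })
  rep <- crossValidate(spy, toy$X, toy$y, k = 3L, repeats = 1L, seed = 4L)
  expect_identical(nrow(perFoldMetrics(rep)), 3L)
  # each fit saw exactly the complement of one fold
  expect_setequal(vapply(seen, `[[`, 0, "n"), 60 - c(20, 20, 20))
  # and the three training sets jointly cover each row exactly twice
  counts <- table(round(unlist(lapply(seen, `[[`, "keys")), 9))
  expect_identical(length(counts), 60L)
  expect_true(all(counts == 2L))
})

test_that("protocol validation rejects impossible settings", {
  toy <- separableToy(n = 20)
  expect_error(crossValidate(baselineAdapter("lr"), toy$X, toy$y, k = 30L),
    "exceed")
  yRare <- c(rep(1L, 2), rep(0L, 18))
  expect_error(crossValidate(baselineAdapter("lr"), toy$X, yRare, k = 5L),
    "stratification")
  expect_error(baselineAdapter("svm"))
})

test_that("all baseline adapters produce complete reports on the synthetic benchmark", {
  dat <- generateTabular(syntheticSpec(n = 160L, d = 12L, informative = 1:4,
    classRatio = 3, seed = 2L))
  for (tag in c("rf", "lr", "nb")) {
    adapter <- if (tag == "rf") baselineAdapter(tag, ntree = 50L)
      else baselineAdapter(tag)
    rep <- crossValidate(adapter, dat$X, dat$y, k = 3L, repeats = 1L, seed = 6L)
    pf <- perFoldMetrics(rep)
    expect_identical(nrow(pf), 3L)
    expect_true(all(pf$ROC_AUC >= 0 & pf$ROC_AUC <= 1))
    expect_true(all(pf$Kappa >= -1 & pf$Kappa <= 1))
  }
})

test_that("rf separates the toy problem perfectly under cross-validation", {
  toy <- separableToy(n = 60)
  rep <- crossValidate(baselineAdapter("rf", ntree = 50L), toy$X, toy$y,
    k = 3L, repeats = 1L, seed = 2L)
  expect_equal(mean(perFoldMetrics(rep)$ROC_AUC), 1)
})

test_that("evaluation reports round-trip to tidy CSV", {
  toy <- separableToy(n = 60)
  rep <- crossValidate(baselineAdapter("lr"), toy$X, toy$y, k = 3L,
    repeats = 2L, seed = 1L)
  dir <- tempfile()
  writeEvalReport(rep, dir)
  long <- read.csv(file.path(dir, "per_fold.csv"))
  expect_identical(nrow(long), 6L * 7L)  # folds x repeats x metrics
  summ <- read.csv(file.path(dir, "summary.csv"))
  expect_identical(summ$metric, aggregateMetrics(rep)$metric)
})
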