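#' @import methods
NULL

#' FeatureMatrix: compounds-by-features numeric matrix
#'
#' Container for a featurized compound table. Rows are compounds (rownames =
#' compound ids), columns are named features. The \code{featureSetTag} records
#' which feature set the columns realize: \code{"full"} (208 descriptors
#' followed by 166 MACCS keys, 374 columns), \code{"descriptors_only"}
#' (208 columns) or \code{"custom"} (any width, e.g. synthetic benchmarks).
#'
#' @slot values numeric matrix, n compounds x d features, with dimnames.
#' @slot featureSetTag one of \code{"full"}, \code{"descriptors_only"},
#'   \code{"custom"}.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureSetTag = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  tag <- object@featureSetTag
  msg <- character(0)
  if (length(tag) != 1L || !tag %in% c("full", "descriptors_only", "custom"))
    msg <- c(msg, "featureSetTag must be one of 'full', 'descriptors_only', 'custom'")
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) > 0L && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msg <- c(msg, "values must have unique rownames (compound ids)")
  if (is.null(colnames(v))) msg <- c(msg, "values must have feature names as colnames")
  if (identical(tag, "full") && ncol(v) != 374L)
    msg <- c(msg, "feature set 'full' must have exactly 374 columns")
  if (identical(tag, "descriptors_only") && ncol(v) != 208L)
    msg <- c(msg, "feature set 'descriptors_only' must have exactly 208 columns")
  if (length(msg)) msg else TRUE
})

#' FeatureGraph: directed graph over feature indices
#'
#' Vertex set is the set of features that appear as tree splits; edges connect
#' the split feature of a node to the split features of its internal children,
#' accumulated over an ensemble by set union. Feature indices are 1-based
#' (R convention) in \code{[1, d]}.
#'
#' @slot d total number of features the graph is defined over.
#' @slot edges integer matrix with columns \code{from}, \code{to}; one row per
#'   distinct directed edge. Zero rows for an empty graph.
#' @export
setClass("FeatureGraph", representation(d = "integer", edges = "matrix"))

setValidity("FeatureGraph", function(object) {
  msg <- character(0)
  if (length(object@d) != 1L || is.na(object@d) || object@d < 1L)
    msg <- c(msg, "d must be a single positive integer")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns (from, to)")
  if (nrow(e)) {
    if (!all(e >= 1L & e <= object@d)) msg <- c(msg, "edge endpoints must lie in [1, d]")
    if (anyDuplicated(paste(e[, 1L], e[, 2L]))) msg <- c(msg, "duplicate edges (set semantics required)")
  }
  if (length(msg)) msg else TRUE
})

#' MaskMatrix: binary d x d first-layer connectivity mask
#'
#' Realization of a \linkS4class{FeatureGraph} as the binary adjacency operand
#' of the Hadamard-masked first network layer.
#'
#' @slot m binary (0/1) numeric d x d matrix.
#' @slot symmetrized logical; if TRUE, m equals its transpose by construction.
#' @slot selfLoops logical; if TRUE, the diagonal is all ones.
#' @export
setClass("MaskMatrix",
  representation(m = "matrix", symmetrized = "logical", selfLoops = "logical"))

setValidity("MaskMatrix", function(object) {
  m <- object@m
  msg <- character(0)
  if (nrow(m) != ncol(m)) msg <- c(msg, "mask must be square")
  if (!all(m %in% c(0, 1))) msg <- c(msg, "mask entries must be 0/1")
  if (isTRUE(object@symmetrized) && !identical(m, t(m)))
    msg <- c(msg, "symmetrized mask must equal its transpose")
  if (isTRUE(object@selfLoops) && !all(diag(m) == 1))
    msg <- c(msg, "self-loop mask must have a unit diagonal")
  if (length(msg)) msg else TRUE
})

#' FittedForest: tree ensemble plus its fit parameters
#'
#' Wraps a fitted \code{randomForest} classification ensemble together with the
#' parameters used to fit it and the feature count, so tree structures can be
#' extracted reproducibly.
#'
#' @slot forest the underlying \code{randomForest} object.
#' @slot params list of fit parameters (ntree, mtry, nodesize, maxnodes, seed).
#' @slot d number of features the forest was trained on.
#' @export
setClass("FittedForest", representation(forest = "ANY", params = "list", d = "integer"))

#' ForgeNetModel: fitted forest, mask and network weights
#'
#' The complete fitted classifier: the tree ensemble used to mine the feature
#' graph, the binary first-layer mask, the network weights/biases, and the
#' training-set standardization statistics applied at prediction time.
#'
#' @slot forest a \linkS4class{FittedForest} (or NULL when a mask was supplied
#'   directly).
#' @slot mask a \linkS4class{MaskMatrix}.
#' @slot weights list of weight matrices; element 1 is the d x d masked layer.
#' @slot biases list of bias vectors, parallel to \code{weights}.
#' @slot standardization list with numeric vectors \code{mean} and \code{sd}.
#' @slot config list of network hyperparameters (see \code{\link{netConfig}}).
#' @slot featureSetTag tag of the training FeatureMatrix (prediction inputs
#'   must match).
#' @export
setClass("ForgeNetModel",
  representation(forest = "ANY", mask = "MaskMatrix", weights = "list",
    biases = "list", standardization = "list", config = "list",
    featureSetTag = "character"))

#' EvalReport: per-fold and aggregated cross-validation metrics
#'
#' @slot perFold data.frame with one row per fold x repeat (or per repeat for
#'   leave-one-out) carrying SN, SP, Kappa, MCC, F1, ROC_AUC, PR_AUC.
#' @slot aggregate data.frame with columns metric, mean, sd.
#' @slot protocol list: k (integer or "loo"), repeats, seed, classifier tag,
#'   feature set tag.
#' @export
setClass("EvalReport",
  representation(perFold = "data.frame", aggregate = "data.frame", protocol = "list"))

#' RankTable: candidates ranked by predicted activity
#'
#' @slot rows data.frame with columns id, probability, rank (rank 1 = highest
#'   predicted active-class probability; ties broken by input order).
#' @slot modelTag label of the model/training set that produced the ranks.
#' @export
setClass("RankTable", representation(rows = "data.frame", modelTag = "character"))

setValidity("RankTable", function(object) {
  r <- object@rows
  msg <- character(0)
  if (!all(c("id", "probability", "rank") %in% names(r)))
    msg <- c(msg, "rows must have columns id, probability, rank")
  else if (nrow(r) && !setequal(r$rank, seq_len(nrow(r))))
    msg <- c(msg, "ranks must be a permutation of 1..n")
  if (length(msg)) msg else TRUE
})
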