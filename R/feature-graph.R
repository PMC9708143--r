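#' Fit the tree ensemble used for feature-graph mining
#'
#' Fits a random-forest classifier to labelled training data. Defaults follow
#' the package's forest configuration: 500 trees, sqrt(d) feature subsampling,
#' impurity splitting, unlimited depth. All are overridable; the shallow-forest
#' regime (small \code{maxnodes}, larger \code{mtry}) is the one in which the
#' mined feature graph concentrates on informative features (see the methods
#' vignette — many deep trees densify the edge union).
#'
#' @param X numeric matrix or \linkS4class{FeatureMatrix} (n x d).
#' @param y binary labels (0/1), both classes present.
#' @param ntree number of trees p.
#' @param mtry features tried per split; default \code{floor(sqrt(d))}.
#' @param nodesize minimum node size (1 = grow to purity).
#' @param maxnodes optional cap on terminal nodes per tree (NULL = unlimited).
#' @param seed integer seed; the fit is deterministic given it.
#' @return a \linkS4class{FittedForest}.
#' @export
fitForest <- function(X, y, ntree = 500L, mtry = NULL, nodesize = 1L,
                      maxnodes = NULL, seed = 1L) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  y <- .checkBinaryLabels(y, nrow(X))
  if (ntree < 1L) stop("ntree must be >= 1")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  rf <- if (is.null(maxnodes))
    randomForest::randomForest(X, factor(y, levels = c(0, 1)),
      ntree = ntree, mtry = mtry, nodesize = nodesize)
  else
    randomForest::randomForest(X, factor(y, levels = c(0, 1)),
      ntree = ntree, mtry = mtry, nodesize = nodesize, maxnodes = maxnodes)
  new("FittedForest", forest = rf,
    params = list(ntree = as.integer(ntree), mtry = as.integer(mtry),
      nodesize = as.integer(nodesize), maxnodes = maxnodes,
      seed = as.integer(seed)),
    d = ncol(X))
}

.checkBinaryLabels <- function(y, n) {
  y <- as.integer(as.character(factor(y)))
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("both classes must be present; single-class labels admit no splits")
  y
}

#' Extract tree structures from a fitted forest
#'
#' Each tree is a data.frame with one row per node: \code{node}, \code{left},
#' \code{right} (0 for leaves) and \code{splitFeature} (1-based feature index;
#' NA for leaves).
#'
#' @param forest a \linkS4class{FittedForest}.
#' @return list of tree data.frames.
#' @export
treeStructures <- function(forest) {
  stopifnot(is(forest, "FittedForest"))
  lapply(seq_len(forest@params$ntree), function(k) {
    tr <- randomForest::getTree(forest@forest, k, labelVar = FALSE)
    data.frame(node = seq_len(nrow(tr)),
      left = as.integer(tr[, "left daughter"]),
      right = as.integer(tr[, "right daughter"]),
      splitFeature = ifelse(tr[, "status"] == -1L, NA_integer_,
        as.integer(tr[, "split var"])))
  })
}

#' Convert one decision tree into a feature graph
#'
#' For every internal node u and every internal child c of u, the directed edge
#' (splitFeature(u), splitFeature(c)) is added. Leaves carry predictions, not
#' features, and contribute no edges; the vertex set is the set of split
#' features. A parent and child splitting on the same feature yield the
#' self-pair (f, f).
#'
#' @param tree a tree data.frame as returned by \code{\link{treeStructures}}.
#' @param d total feature count the graph is defined over.
#' @return a \linkS4class{FeatureGraph}.
#' @export
treeToGraph <- function(tree, d) {
  stopifnot(all(c("node", "left", "right", "splitFeature") %in% names(tree)))
  internal <- which(!is.na(tree$splitFeature))
  edges <- matrix(integer(0), 0L, 2L)
  if (length(internal)) {
    from <- integer(0); to <- integer(0)
    for (u in internal) {
      for (ch in c(tree$left[u], tree$right[u])) {
        if (ch > 0L && !is.na(tree$splitFeature[ch])) {
          from <- c(from, tree$splitFeature[u])
          to <- c(to, tree$splitFeature[ch])
        }
      }
    }
    edges <- unique(cbind(from, to))
  }
  colnames(edges) <- c("from", "to")
  new("FeatureGraph", d = as.integer(d), edges = edges)
}

#' Union of feature graphs
#'
#' Set union of vertex and edge sets over a list of graphs sharing the same
#' feature count d; duplicate edges collapse. Commutative and idempotent.
#'
#' @param graphs list of \linkS4class{FeatureGraph} objects.
#' @return a \linkS4class{FeatureGraph}.
#' @export
unionGraphs <- function(graphs) {
  stopifnot(length(graphs) >= 1L, all(vapply(graphs, is, logical(1), "FeatureGraph")))
  ds <- vapply(graphs, function(g) g@d, integer(1))
  if (length(unique(ds)) != 1L)
    stop("all graphs must share the same feature count d")
  edges <- unique(do.call(rbind, lapply(graphs, graphEdges)))
  colnames(edges) <- c("from", "to")
  new("FeatureGraph", d = ds[1L], edges = edges)
}

#' Aggregate a whole forest into one feature graph
#'
#' Convenience composition of \code{\link{treeStructures}},
#' \code{\link{treeToGraph}} and \code{\link{unionGraphs}}.
#'
#' @param forest a \linkS4class{FittedForest}.
#' @return a \linkS4class{FeatureGraph}.
#' @export
forestToGraph <- function(forest) {
  unionGraphs(lapply(treeStructures(forest), treeToGraph, d = forest@d))
}

#' Realize a feature graph as a binary first-layer mask
#'
#' \code{m[u, v] = 1} iff edge (u, v) is in the graph; with
#' \code{symmetrize = TRUE} (default) \code{m[v, u]} is set as well, since a
#' first-layer weight mask has no meaningful direction; with
#' \code{selfLoops = TRUE} (default) the diagonal is set to 1 so every feature
#' feeds its own first-layer unit even if it never split in the forest.
#'
#' @param g a \linkS4class{FeatureGraph}.
#' @param symmetrize logical.
#' @param selfLoops logical.
#' @return a \linkS4class{MaskMatrix}.
#' @export
graphToMask <- function(g, symmetrize = TRUE, selfLoops = TRUE) {
  stopifnot(is(g, "FeatureGraph"))
  d <- g@d
  m <- matrix(0, d, d)
  e <- graphEdges(g)
  if (nrow(e)) {
    m[e] <- 1
    if (symmetrize) m[e[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (selfLoops) diag(m) <- 1
  new("MaskMatrix", m = m, symmetrized = symmetrize, selfLoops = selfLoops)
}

#' Write / read a feature graph as edge-list TSV
#'
#' One edge per line (columns \code{from}, \code{to}); the feature count d is
#' stored in a header comment.
#'
#' @param g a \linkS4class{FeatureGraph}.
#' @param path output path.
#' @export
writeFeatureGraph <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# d: %d", g@d), con)
  utils::write.table(graphEdges(g), con, sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureGraph
#' @export
readFeatureGraph <- function(path) {
  first <- readLines(path, n = 1L)
  d <- as.integer(sub("# d:", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  edges <- as.matrix(df)
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("from", "to")
  new("FeatureGraph", d = d, edges = edges)
}
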