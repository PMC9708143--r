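#' Accessors and show methods
#'
#' Small accessor generics for the package's S4 containers, in place of direct
#' slot access.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("featureSetTag", function(x) standardGeneric("featureSetTag"))

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' @rdname accessors
#' @export
setGeneric("perFoldMetrics", function(x) standardGeneric("perFoldMetrics"))

#' @rdname accessors
#' @export
setGeneric("aggregateMetrics", function(x) standardGeneric("aggregateMetrics"))

#' @rdname accessors
#' @export
setGeneric("rankRows", function(x) standardGeneric("rankRows"))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureSetTag", "FeatureMatrix", function(x) x@featureSetTag)

#' @rdname accessors
#' @export
setMethod("featureSetTag", "ForgeNetModel", function(x) x@featureSetTag)

#' @rdname accessors
#' @export
setMethod("compoundIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("graphEdges", "FeatureGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("maskValues", "MaskMatrix", function(x) x@m)

#' @rdname accessors
#' @export
setMethod("maskValues", "ForgeNetModel", function(x) x@mask@m)

#' @rdname accessors
#' @export
setMethod("perFoldMetrics", "EvalReport", function(x) x@perFold)

#' @rdname accessors
#' @export
setMethod("aggregateMetrics", "EvalReport", function(x) x@aggregate)

#' @rdname accessors
#' @export
setMethod("rankRows", "RankTable", function(x) x@rows)

#' @rdname accessors
#' @param object an object.
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d compounds x %d features [%s]\n",
    nrow(object@values), ncol(object@values), object@featureSetTag))
})

#' @rdname accessors
#' @export
setMethod("show", "FeatureGraph", function(object) {
  cat(sprintf("FeatureGraph over d = %d features: %d vertices, %d directed edges\n",
    object@d, length(unique(as.vector(object@edges))), nrow(object@edges)))
})

#' @rdname accessors
#' @export
setMethod("show", "MaskMatrix", function(object) {
  cat(sprintf("MaskMatrix %d x %d: %d ones (symmetrized=%s, selfLoops=%s)\n",
    nrow(object@m), ncol(object@m), sum(object@m),
    object@symmetrized, object@selfLoops))
})

#' @rdname accessors
#' @export
setMethod("show", "FittedForest", function(object) {
  cat(sprintf("FittedForest: %d trees over %d features (mtry=%d, seed=%s)\n",
    object@params$ntree, object@d, object@params$mtry,
    format(object@params$seed)))
})

#' @rdname accessors
#' @export
setMethod("show", "ForgeNetModel", function(object) {
  d <- nrow(object@mask@m)
  hidden <- vapply(object@weights[-1L], ncol, integer(1))
  cat(sprintf("ForgeNetModel: d = %d, layers d -> %s [%s features]\n",
    d, paste(c(d, hidden), collapse = " -> "), object@featureSetTag))
  cat(sprintf("  mask: %d ones; epochs = %d, lr = %g\n",
    sum(object@mask@m), object@config$epochs, object@config$learningRate))
})

#' @rdname accessors
#' @export
setMethod("show", "EvalReport", function(object) {
  p <- object@protocol
  cat(sprintf("EvalReport: %s, k = %s, repeats = %d, seed = %d (%d rows)\n",
    p$classifier, format(p$k), p$repeats, p$seed, nrow(object@perFold)))
  agg <- object@aggregate
  cat(paste(sprintf("  %s = %.4f +/- %.4f", agg$metric, agg$mean, agg$sd),
    collapse = "\n"), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "RankTable", function(object) {
  cat(sprintf("RankTable [%s]: %d candidates\n", object@modelTag, nrow(object@rows)))
  print(utils::head(object@rows[order(object@rows$rank), ], 5L), row.names = FALSE)
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix with compound ids as rownames and feature names
#'   as colnames.
#' @param featureSetTag one of "full", "descriptors_only", "custom".
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, featureSetTag = "custom") {
  new("FeatureMatrix", values = values, featureSetTag = featureSetTag)
}
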