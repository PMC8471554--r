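# Accessor generics and show methods.  Slots are never accessed directly by
# user code; these are the supported surface.

#' @rdname GCMap-class
#' @param object,x a package object.
#' @export
setGeneric("gcWeights", function(x) standardGeneric("gcWeights"))

#' @rdname GCMap-class
#' @export
setMethod("gcWeights", "GCMap", function(x) x@weights)

#' @rdname GCMap-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname GCMap-class
#' @export
setMethod("nodeLabels", "GCMap", function(x) x@labels)

#' @rdname PatientRecord-class
#' @export
setMethod("nodeLabels", "PatientRecord",
          function(x) x@segments[[1L]]@labels)

#' @rdname NodeRanking-class
#' @export
setMethod("nodeLabels", "NodeRanking", function(x) names(x@ranks))

#' @rdname GCMap-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname GCMap-class
#' @export
setMethod("nNodes", "GCMap", function(x) nrow(x@weights))

#' @rdname PatientRecord-class
#' @export
setMethod("nNodes", "PatientRecord", function(x) nNodes(x@segments[[1L]]))

#' @rdname PatientRecord-class
#' @param x a [PatientRecord-class].
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname PatientRecord-class
#' @export
setMethod("segments", "PatientRecord", function(x) x@segments)

#' @rdname PatientRecord-class
#' @export
setGeneric("sozLabels", function(x) standardGeneric("sozLabels"))

#' @rdname PatientRecord-class
#' @export
setMethod("sozLabels", "PatientRecord", function(x) x@soz)

#' @rdname PatientRecord-class
#' @export
setGeneric("rzLabels", function(x) standardGeneric("rzLabels"))

#' @rdname PatientRecord-class
#' @export
setMethod("rzLabels", "PatientRecord", function(x) x@rz)

#' @rdname TransitionModel-class
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname TransitionModel-class
#' @param x a [TransitionModel-class].
#' @export
setMethod("transitionProbs", "TransitionModel", function(x) x@probs)

#' @rdname TransitionModel-class
#' @export
setGeneric("danglingNodes", function(x) standardGeneric("danglingNodes"))

#' @rdname TransitionModel-class
#' @export
setMethod("danglingNodes", "TransitionModel", function(x) x@dangling)

#' @rdname NodeRanking-class
#' @param x a [NodeRanking-class].
#' @export
setGeneric("nodeMetric", function(x) standardGeneric("nodeMetric"))

#' @rdname NodeRanking-class
#' @export
setMethod("nodeMetric", "NodeRanking", function(x) x@metric)

#' @rdname NodeRanking-class
#' @export
setGeneric("nodeRanks", function(x) standardGeneric("nodeRanks"))

#' @rdname NodeRanking-class
#' @export
setMethod("nodeRanks", "NodeRanking", function(x) x@ranks)

#' @rdname NodeRanking-class
#' @export
setGeneric("algorithmId", function(x) standardGeneric("algorithmId"))

#' @rdname NodeRanking-class
#' @export
setMethod("algorithmId", "NodeRanking", function(x) x@algorithm)

#' @rdname WalkOutcome-class
#' @param x a [WalkOutcome-class].
#' @export
setGeneric("visitCounts", function(x) standardGeneric("visitCounts"))

#' @rdname WalkOutcome-class
#' @export
setMethod("visitCounts", "WalkOutcome", function(x) x@visitCounts)

#' @rdname WalkOutcome-class
#' @export
setGeneric("meanIntervals", function(x) standardGeneric("meanIntervals"))

#' @rdname WalkOutcome-class
#' @export
setMethod("meanIntervals", "WalkOutcome", function(x) x@meanIntervals)

#' @rdname GCResult-class
#' @param x a [GCResult-class].
#' @export
setGeneric("gcMagnitudes", function(x) standardGeneric("gcMagnitudes"))

#' @rdname GCResult-class
#' @export
setMethod("gcMagnitudes", "GCResult", function(x) x@gc)

#' @rdname GCResult-class
#' @export
setGeneric("fStatistics", function(x) standardGeneric("fStatistics"))

#' @rdname GCResult-class
#' @export
setMethod("fStatistics", "GCResult", function(x) x@fstat)

#' @rdname RankOrderResult-class
#' @param x a [RankOrderResult-class].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname RankOrderResult-class
#' @export
setMethod("pValue", "RankOrderResult", function(x) x@pValue)

#' @rdname RankOrderResult-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname RankOrderResult-class
#' @export
setMethod("isSignificant", "RankOrderResult", function(x) x@significant)

#' @rdname RankOrderResult-class
#' @export
setGeneric("observedSum", function(x) standardGeneric("observedSum"))

#' @rdname RankOrderResult-class
#' @export
setMethod("observedSum", "RankOrderResult", function(x) x@observedSum)

#' @rdname NullDistribution-class
#' @param x a [NullDistribution-class].
#' @export
setGeneric("nullSums", function(x) standardGeneric("nullSums"))

#' @rdname NullDistribution-class
#' @export
setMethod("nullSums", "NullDistribution", function(x) x@sums)

#' @rdname NullDistribution-class
#' @export
setGeneric("nullMoments", function(x) standardGeneric("nullMoments"))

#' @rdname NullDistribution-class
#' @export
setMethod("nullMoments", "NullDistribution",
          function(x) c(mean = x@fittedMean, sd = x@fittedSd))

setMethod("show", "GCMap", function(object) {
  n <- nNodes(object)
  ne <- sum(object@weights > 0)
  cat(sprintf("GCMap: %d nodes, %d directed edges (density %.3f)\n",
              n, ne, if (n > 1) ne / (n * (n - 1)) else 0))
  cat("  labels:", paste(utils::head(object@labels, 5), collapse = ", "),
      if (n > 5) "..." else "", "\n")
})

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord: %d nodes, %d segment maps, |SOZ| = %d, |RZ| = %d\n",
              nNodes(object), length(object@segments),
              length(object@soz), length(object@rz)))
})

setMethod("show", "NodeRanking", function(object) {
  cat(sprintf("NodeRanking (%s, %s edges): %d nodes\n",
              object@algorithm, object@direction, length(object@ranks)))
  best <- names(sort(object@ranks))[seq_len(min(5, length(object@ranks)))]
  cat("  best-ranked:", paste(best, collapse = ", "), "\n")
})

setMethod("show", "RankOrderResult", function(object) {
  cat(sprintf(
    "RankOrderResult: sum = %.1f over k = %d of N = %d nodes\n",
    object@observedSum, object@nTarget, object@nTotal))
  cat(sprintf("  null mean = %.1f, sd = %.2f (%s); p = %.3g (%s at alpha = %g)\n",
              object@nullMean, object@nullSd, object@method, object@pValue,
              if (object@significant) "significant" else "not significant",
              object@alpha))
})

setMethod("show", "WalkOutcome", function(object) {
  cat(sprintf("WalkOutcome: %d nodes, %d completed + %d truncated restarts\n",
              length(object@visitCounts), object@completedRestarts,
              object@truncatedRestarts))
})

setMethod("show", "GCResult", function(object) {
  cat(sprintf("GCResult: %d channels, VAR order %d, F dof (%g, %g)\n",
              nrow(object@gc), object@order, object@dof[1], object@dof[2]))
})
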