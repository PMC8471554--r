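# S4 classes for the GC-network ranking pipeline.
#
# Matrix orientation convention used throughout the package: rows are SOURCE
# ("cause") nodes and columns are TARGET nodes, so weights[i, j] is the GC
# influence of node i on node j.  reverseEdges() transposes a map, so input
# files stored in the opposite orientation can be accommodated with one call.

#' GCMap: a Granger-causality connectivity map
#'
#' An N x N nonnegative directed weight matrix over labelled nodes
#' (iEEG electrodes).  `weights[i, j]` is the GC influence of node `i`
#' (source) on node `j` (target); the diagonal is identically zero (no
#' self-edges).  This is the central graph object every ranking algorithm
#' consumes.
#'
#' @slot weights numeric N x N matrix, nonnegative, zero diagonal.
#' @slot labels character vector of N unique node identifiers.
#' @export
setClass("GCMap", representation(weights = "matrix", labels = "character"))

setValidity("GCMap", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "'weights' must be a square numeric matrix")
  else {
    if (anyNA(w)) msg <- c(msg, "'weights' contains NA/NaN values")
    else {
      if (any(w < 0)) msg <- c(msg, "'weights' contains negative entries")
      if (nrow(w) > 0 && any(diag(w) != 0))
        msg <- c(msg, "diagonal of 'weights' must be exactly 0 (no self-edges)")
    }
    if (length(object@labels) != nrow(w))
      msg <- c(msg, "length of 'labels' must equal the matrix dimension")
  }
  if (anyDuplicated(object@labels))
    msg <- c(msg, "'labels' must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GCMap
#'
#' @param weights square nonnegative numeric matrix with zero diagonal;
#'   rows are source nodes, columns are target nodes.
#' @param labels node labels; defaults to the matrix dimnames, else
#'   `"n0" ... "n{N-1}"`.
#' @return a [GCMap-class] object.
#' @export
#' @examples
#' g <- GCMap(rbind(c(0, 0.5), c(0.2, 0)), labels = c("e1", "e2"))
#' gcWeights(g)
GCMap <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels))
      labels <- sprintf("n%d", seq_len(nrow(weights)) - 1L)
  }
  labels <- as.character(labels)
  dimnames(weights) <- list(labels, labels)
  new("GCMap", weights = weights, labels = labels)
}

#' TransitionModel: row-normalized walk probabilities of a GCMap
#'
#' Each non-dangling row of `probs` sums to one; rows of nodes with no
#' outgoing edges (dangling nodes) are all-zero and their indices are listed
#' in `dangling`.  Dangling nodes terminate random-walk chains.
#'
#' @slot probs numeric N x N matrix of transition probabilities.
#' @slot dangling integer indices of rows with no outgoing edges.
#' @export
setClass("TransitionModel",
         representation(probs = "matrix", dangling = "integer"))

setValidity("TransitionModel", function(object) {
  p <- object@probs
  if (any(p < 0) || any(p > 1)) return("'probs' entries must lie in [0, 1]")
  rs <- rowSums(p)
  isDangling <- seq_len(nrow(p)) %in% object@dangling
  if (any(rs[isDangling] != 0)) return("dangling rows must be all-zero")
  if (any(abs(rs[!isDangling] - 1) > 1e-9))
    return("non-dangling rows must sum to 1 within 1e-9")
  TRUE
})

#' PatientRecord: per-segment GC maps plus clinical label sets
#'
#' Holds the ordered per-time-segment [GCMap-class]s of one patient together
#' with the clinician-labelled seizure onset zone (SOZ) and resection zone
#' (RZ) node sets.  All segment maps must share the same node labels in the
#' same order; the RZ may be empty (not every monitored patient undergoes
#' resection).
#'
#' @slot segments list of [GCMap-class], one per analyzed time segment.
#' @slot soz character vector of SOZ node labels (subset of the node labels).
#' @slot rz character vector of RZ node labels (possibly empty).
#' @export
setClass("PatientRecord",
         representation(segments = "list", soz = "character", rz = "character"))

setValidity("PatientRecord", function(object) {
  if (length(object@segments) < 1L) return("'segments' must contain at least one GCMap")
  if (!all(vapply(object@segments, is, logical(1), "GCMap")))
    return("all 'segments' must be GCMap objects")
  labs <- object@segments[[1L]]@labels
  same <- vapply(object@segments, function(g) identical(g@labels, labs), logical(1))
  if (!all(same)) return("all segment GCMaps must share identical labels in identical order")
  if (!all(object@soz %in% labs)) return("'soz' contains labels not present in the maps")
  if (!all(object@rz %in% labs)) return("'rz' contains labels not present in the maps")
  TRUE
})

#' Construct a PatientRecord
#'
#' @param segments list of [GCMap-class] with identical labels.
#' @param soz character vector of seizure-onset-zone node labels.
#' @param rz character vector of resection-zone node labels (may be empty).
#' @return a [PatientRecord-class] object.
#' @export
PatientRecord <- function(segments, soz = character(), rz = character()) {
  if (is(segments, "GCMap")) segments <- list(segments)
  new("PatientRecord", segments = segments,
      soz = as.character(soz), rz = as.character(rz))
}

#' NodeRanking: per-node metric values and ranks
#'
#' The result of one ranking algorithm on one GC map (or one patient):
#' a metric value per node and midranks in `[1, N]` with rank 1 the best
#' node in the algorithm's declared direction.  Ties receive midranks, so
#' the ranks always sum to N(N+1)/2 exactly.
#'
#' @slot metric named numeric metric values (`NA` = undefined, ranked last).
#' @slot ranks named numeric midranks in `[1, N]`.
#' @slot direction `"forward"` or `"reverse"` (edge orientation used).
#' @slot algorithm identifier of the algorithm that produced the ranking.
#' @export
setClass("NodeRanking",
         representation(metric = "numeric", ranks = "numeric",
                        direction = "character", algorithm = "character"))

setValidity("NodeRanking", function(object) {
  n <- length(object@metric)
  if (length(object@ranks) != n) return("'metric' and 'ranks' lengths differ")
  if (is.null(names(object@ranks)) || anyDuplicated(names(object@ranks)))
    return("'ranks' must carry unique node names")
  if (n > 0 && abs(sum(object@ranks) - n * (n + 1) / 2) > 1e-8)
    return("ranks must sum to N(N+1)/2 (midrank property)")
  if (n > 0 && (min(object@ranks) < 1 || max(object@ranks) > n))
    return("ranks must lie in [1, N]")
  if (!object@direction %in% c("forward", "reverse"))
    return("'direction' must be 'forward' or 'reverse'")
  TRUE
})

# Internal constructor: metric -> midranks.
nodeRanking <- function(metric, algorithm, direction = "forward",
                        decreasing = TRUE) {
  new("NodeRanking", metric = metric,
      ranks = midranks(metric, decreasing = decreasing),
      direction = direction, algorithm = algorithm)
}

#' WalkOutcome: accumulated result of Monte Carlo walk sampling
#'
#' @slot visitCounts named numeric per-node visitation counts (for the
#'   multi-token variant: counts of all-token coincidences).
#' @slot meanIntervals named numeric mean revisit interval per node (`NA`
#'   where a node was never revisited within any single restart); only
#'   filled for `metric = "interval"` runs.
#' @slot completedRestarts number of restarts that reached the step cap.
#' @slot truncatedRestarts number of restarts stopped early at a dangling
#'   node.
#' @slot config the [WalkConfig-class] that produced the outcome.
#' @export
setClass("WalkOutcome",
         representation(visitCounts = "numeric", meanIntervals = "numeric",
                        completedRestarts = "integer",
                        truncatedRestarts = "integer", config = "ANY"))

#' WalkConfig: parameters of a Monte Carlo walk-sampling run
#'
#' @slot restarts number of random restarts.
#' @slot maxSteps maximum visitations per restart (the start node counts as
#'   the first visitation).
#' @slot direction `"forward"` walks along GC influence; `"reverse"`
#'   transposes the map first so walkers travel "uphill" toward generators
#'   of activity.
#' @slot metric `"count"` (visitation counts, more = better) or
#'   `"interval"` (mean revisit interval, shorter = better).
#' @slot tokens number of simultaneous tokens; with k >= 2 a visitation is
#'   recorded only when all tokens coincide on one node.
#' @slot seed integer RNG seed (NA = use the current RNG state).
#' @export
setClass("WalkConfig",
         representation(restarts = "integer", maxSteps = "integer",
                        direction = "character", metric = "character",
                        tokens = "integer", seed = "integer"))

setValidity("WalkConfig", function(object) {
  if (object@restarts < 1L) return("'restarts' must be >= 1")
  if (object@maxSteps < 1L) return("'maxSteps' must be >= 1")
  if (object@tokens < 1L) return("'tokens' must be >= 1")
  if (!object@direction %in% c("forward", "reverse"))
    return("'direction' must be 'forward' or 'reverse'")
  if (!object@metric %in% c("count", "interval"))
    return("'metric' must be 'count' or 'interval'")
  TRUE
})

#' Construct a WalkConfig
#'
#' Defaults mirror the standard sampling protocol: 1000 restarts of up to
#' 1000 visitations each, forward edges, visitation-count metric, a single
#' token.
#'
#' @param restarts,maxSteps,direction,metric,tokens,seed see
#'   [WalkConfig-class].
#' @return a [WalkConfig-class] object.
#' @export
walkConfig <- function(restarts = 1000, maxSteps = 1000,
                       direction = c("forward", "reverse"),
                       metric = c("count", "interval"),
                       tokens = 1, seed = NULL) {
  direction <- match.arg(direction)
  metric <- match.arg(metric)
  new("WalkConfig", restarts = as.integer(restarts),
      maxSteps = as.integer(maxSteps), direction = direction,
      metric = metric, tokens = as.integer(tokens),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' GCResult: pairwise Granger-causality statistics for one segment
#'
#' @slot gc N x N matrix of GC magnitudes `ln(RSS_restricted / RSS_full)`.
#' @slot fstat N x N matrix of F statistics for the nested-model comparison.
#' @slot dof numeric length-2 vector: numerator and denominator degrees of
#'   freedom of the F test.
#' @slot order VAR model order p used for the fits.
#' @slot labels channel labels.
#' @export
setClass("GCResult",
         representation(gc = "matrix", fstat = "matrix", dof = "numeric",
                        order = "integer", labels = "character"))

setValidity("GCResult", function(object) {
  if (any(object@gc < 0)) return("'gc' must be nonnegative")
  if (nrow(object@gc) > 0 &&
      (any(diag(object@gc) != 0) || any(diag(object@fstat) != 0)))
    return("diagonals of 'gc' and 'fstat' must be 0")
  TRUE
})

#' Segment: a multichannel time-series segment
#'
#' @slot data numeric C x T matrix (C channels, T samples).
#' @slot labels C channel identifiers.
#' @slot sampleRate samples per second (informational).
#' @export
setClass("Segment",
         representation(data = "matrix", labels = "character",
                        sampleRate = "numeric"))

setValidity("Segment", function(object) {
  if (anyNA(object@data)) return("'data' contains NA values")
  if (length(object@labels) != nrow(object@data))
    return("'labels' length must equal the number of channels (rows)")
  if (anyDuplicated(object@labels)) return("'labels' must be unique")
  TRUE
})

#' Construct a Segment
#'
#' @param data numeric channels x samples matrix.
#' @param labels channel labels; defaults to rownames or `"c1"..."cC"`.
#' @param sampleRate sampling rate in Hz (informational).
#' @return a [Segment-class] object.
#' @export
Segment <- function(data, labels = NULL, sampleRate = NA_real_) {
  data <- as.matrix(data)
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("c", seq_len(nrow(data)))
  }
  rownames(data) <- labels
  new("Segment", data = data, labels = as.character(labels),
      sampleRate = as.numeric(sampleRate))
}

#' NullDistribution: Monte Carlo null of rank-order sums
#'
#' @slot sums simulated rank-order sums, one per repetition.
#' @slot fittedMean,fittedSd sample moments of `sums`.
#' @slot repetitions number of Monte Carlo repetitions.
#' @slot seed seed used (NA if none supplied).
#' @slot nTotal,nTarget the N and k of the sampled subsets.
#' @slot replacement whether ranks were drawn with replacement.
#' @export
setClass("NullDistribution",
         representation(sums = "numeric", fittedMean = "numeric",
                        fittedSd = "numeric", repetitions = "integer",
                        seed = "integer", nTotal = "integer",
                        nTarget = "integer", replacement = "logical"))

setValidity("NullDistribution", function(object) {
  if (object@repetitions < 1L) return("'repetitions' must be >= 1")
  if (object@fittedSd < 0) return("'fittedSd' must be >= 0")
  TRUE
})

#' RankOrderResult: significance of a rank-order sum
#'
#' The observed sum of the (mid)ranks of a target node set, the null
#' mean/sd of sums of equally many random ranks, and a one-sided lower-tail
#' p-value: small sums mean the algorithm ranks the target nodes early.
#'
#' @slot observedSum sum of the midranks of the target nodes.
#' @slot nTotal total node count N.
#' @slot nTarget target-set size k.
#' @slot nullMean,nullSd moments of the null distribution used.
#' @slot pValue one-sided lower-tail p-value.
#' @slot significant `pValue < alpha`.
#' @slot alpha significance level used.
#' @slot method `"mc_normal"`, `"mc_empirical"` or `"closed_form"`.
#' @export
setClass("RankOrderResult",
         representation(observedSum = "numeric", nTotal = "integer",
                        nTarget = "integer", nullMean = "numeric",
                        nullSd = "numeric", pValue = "numeric",
                        significant = "logical", alpha = "numeric",
                        method = "character"))

setValidity("RankOrderResult", function(object) {
  k <- as.numeric(object@nTarget); n <- as.numeric(object@nTotal)
  lo <- k * (k + 1) / 2; hi <- k * n - k * (k - 1) / 2
  if (object@observedSum < lo - 1e-8 || object@observedSum > hi + 1e-8)
    return("'observedSum' outside the attainable range [k(k+1)/2, kN - k(k-1)/2]")
  if (object@pValue < 0 || object@pValue > 1) return("'pValue' must be in [0, 1]")
  TRUE
})

#' SynthConfig: parameters of the synthetic patient generator
#'
#' Defaults emulate a typical subdural-grid monitoring setting: about 100
#' electrodes of which about 20 form the epileptogenic hub set, 60 analyzed
#' interictal segments per patient, and sparse maps as left by per-edge
#' F-test pruning at the 5% level.
#'
#' @slot nNodes number of electrode nodes.
#' @slot nSoz number of planted causal-hub (ground-truth SOZ) nodes.
#' @slot edgeDensity background probability of a directed edge.
#' @slot hubOutMultiplier factor by which hub nodes' out-edge probability
#'   and mean out-edge weight exceed background (the planted effect size).
#' @slot weightScale mean of the exponential edge-weight draws.
#' @slot nSegments number of segment maps per patient.
#' @slot rzAdd,rzRemove number of non-hub nodes added to / hub nodes removed
#'   from the SOZ to form the RZ.
#' @slot seed integer RNG seed (NA = use current RNG state).
#' @export
setClass("SynthConfig",
         representation(nNodes = "integer", nSoz = "integer",
                        edgeDensity = "numeric", hubOutMultiplier = "numeric",
                        weightScale = "numeric", nSegments = "integer",
                        rzAdd = "integer", rzRemove = "integer",
                        seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@nSoz >= object@nNodes) return("'nSoz' must be < 'nNodes'")
  if (object@edgeDensity <= 0 || object@edgeDensity > 1)
    return("'edgeDensity' must be in (0, 1]")
  if (object@hubOutMultiplier < 1) return("'hubOutMultiplier' must be >= 1")
  if (object@edgeDensity * object@hubOutMultiplier > 1)
    return("'edgeDensity' * 'hubOutMultiplier' must be <= 1")
  if (object@weightScale <= 0) return("'weightScale' must be positive")
  if (object@nSegments < 1L) return("'nSegments' must be >= 1")
  if (object@rzRemove > object@nSoz) return("'rzRemove' cannot exceed 'nSoz'")
  TRUE
})

#' Construct a SynthConfig
#'
#' @param nNodes,nSoz,edgeDensity,hubOutMultiplier,weightScale,nSegments,rzAdd,rzRemove,seed
#'   see [SynthConfig-class].
#' @return a [SynthConfig-class] object.
#' @export
synthConfig <- function(nNodes = 100, nSoz = 20, edgeDensity = 0.05,
                        hubOutMultiplier = 3, weightScale = 1,
                        nSegments = 60, rzAdd = 2, rzRemove = 0,
                        seed = NULL) {
  new("SynthConfig", nNodes = as.integer(nNodes), nSoz = as.integer(nSoz),
      edgeDensity = as.numeric(edgeDensity),
      hubOutMultiplier = as.numeric(hubOutMultiplier),
      weightScale = as.numeric(weightScale),
      nSegments = as.integer(nSegments), rzAdd = as.integer(rzAdd),
      rzRemove = as.integer(rzRemove),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
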