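# Synthetic GC maps and VAR time series with planted causal-hub structure.
#
# The generator emulates the statistical shape of per-segment GC maps after
# F-test pruning: sparse directed graphs whose background edges appear at a
# rate comparable to the per-edge false-positive level, plus a planted
# subset of "causal hub" nodes with both more and heavier outgoing edges.
# The planted hubs play the role of the epileptogenic (SOZ) node set, so
# parameter-recovery of the hubs by a ranking algorithm can be measured
# without patient data.

#' Generate a synthetic patient with planted causal hubs
#'
#' For every segment, every ordered node pair (i, j), i != j, receives a
#' directed edge with probability `edgeDensity` (background) or
#' `edgeDensity * hubOutMultiplier` (when the source i is a planted hub);
#' edge weights are exponential with mean `weightScale` (background) or
#' `weightScale * hubOutMultiplier` (hub source).  The planted hub set
#' becomes the record's SOZ; the RZ is the SOZ with `rzAdd` random non-hub
#' nodes added and `rzRemove` hubs removed, emulating the clinical
#' discrepancy between onset zone and resected tissue.
#'
#' @param config a [SynthConfig-class]; see [synthConfig()].
#' @return a list: `record` (a [PatientRecord-class]), `hubs` (character
#'   labels of the planted hub set).
#' @export
#' @examples
#' sim <- genPatient(synthConfig(nNodes = 20, nSoz = 4, nSegments = 3,
#'                               seed = 1))
#' sim$record
genPatient <- function(config = synthConfig()) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  n <- config@nNodes
  labels <- sprintf("e%03d", seq_len(n))
  seed <- if (is.na(config@seed)) NULL else config@seed
  withSeed(seed, {
    hubs <- sort(sample.int(n, config@nSoz))
    pEdge <- matrix(config@edgeDensity, n, n)
    pEdge[hubs, ] <- config@edgeDensity * config@hubOutMultiplier
    wMean <- matrix(config@weightScale, n, n)
    wMean[hubs, ] <- config@weightScale * config@hubOutMultiplier
    segs <- lapply(seq_len(config@nSegments), function(s) {
      present <- matrix(runif(n * n) < pEdge, n, n)
      w <- matrix(0, n, n)
      idx <- which(present)
      w[idx] <- rexp(length(idx), rate = 1 / wMean[idx])
      diag(w) <- 0
      GCMap(w, labels = labels)
    })
    soz <- labels[hubs]
    rz <- soz
    if (config@rzRemove > 0L)
      rz <- setdiff(rz, sample(soz, config@rzRemove))
    if (config@rzAdd > 0L) {
      pool <- setdiff(labels, soz)
      rz <- c(rz, sample(pool, min(config@rzAdd, length(pool))))
    }
    list(record = PatientRecord(segs, soz = soz, rz = sort(rz)),
         hubs = soz)
  })
}

#' Simulate a stable VAR segment with planted causal edges
#'
#' Builds a vector autoregression of the given order with diagonal
#' self-decay (coefficient 0.5 at lag 1 for every channel) and coefficient
#' `coupling` at lag 1 for every planted directed edge `x -> y` (so channel
#' y's present depends on channel x's past), driven by unit-variance
#' Gaussian innovations.  If the companion matrix has spectral radius >= 1
#' the coefficients are rescaled toward stability (with a warning); a
#' configuration that cannot be stabilized raises an error.  The first 200
#' burn-in samples are discarded.
#'
#' @param nChannels number of channels C.
#' @param plantedEdges 2-column matrix (or empty) of directed edges, each
#'   row `c(source, target)` as channel indices.
#' @param coupling lag-1 cross coefficient on planted edges, default 0.5.
#' @param T number of retained samples, default 4000.
#' @param order VAR order (lags beyond 1 have zero coefficients but widen
#'   the fitted models), default 1.
#' @param seed integer seed.
#' @return a list: `segment` (a [Segment-class]), `edges` (the planted
#'   edge matrix, possibly empty).
#' @export
genVARSegment <- function(nChannels, plantedEdges = NULL, coupling = 0.5,
                          T = 4000, order = 1, seed = NULL) {
  C <- as.integer(nChannels)
  p <- as.integer(order)
  if (C < 1L || p < 1L) stopConfig("'nChannels' and 'order' must be >= 1")
  A1 <- diag(0.5, C)
  if (!is.null(plantedEdges) && length(plantedEdges)) {
    pe <- matrix(as.integer(plantedEdges), ncol = 2L)
    if (any(pe < 1L) || any(pe > C))
      stopConfig("'plantedEdges' indices out of range")
    A1[cbind(pe[, 2L], pe[, 1L])] <- coupling   # target row, source column
  } else {
    pe <- matrix(integer(), ncol = 2L)
  }
  # companion matrix: only lag 1 is nonzero, higher lags are zero blocks
  companion <- matrix(0, C * p, C * p)
  companion[seq_len(C), seq_len(C)] <- A1
  if (p > 1L)
    companion[(C + 1L):(C * p), seq_len(C * (p - 1L))] <- diag(C * (p - 1L))
  for (try in seq_len(10L)) {
    rad <- max(Mod(eigen(companion, only.values = TRUE)$values))
    if (rad < 1) break
    warning("VAR configuration unstable (spectral radius ", round(rad, 3),
            "); rescaling coefficients")
    A1 <- A1 * (0.95 / rad)
    companion[seq_len(C), seq_len(C)] <- A1
  }
  if (rad >= 1) stopConfig("could not stabilize the VAR configuration")
  burn <- 200L
  total <- T + burn
  x <- matrix(0, C, total)
  withSeed(seed, {
    eps <- matrix(rnorm(C * total), C, total)
    for (t in 2:total) x[, t] <- A1 %*% x[, t - 1L] + eps[, t]
  })
  seg <- Segment(x[, (burn + 1L):total, drop = FALSE],
                 labels = sprintf("ch%02d", seq_len(C)))
  list(segment = seg, edges = pe)
}
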