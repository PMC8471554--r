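# Monte Carlo random-walk sampling of GC maps.
#
# One restart = one chain: a uniform-random start node (counted as the first
# visitation) followed by weighted draws from the current node's normalized
# outgoing edges, until maxSteps visitations have occurred or a dangling
# node (no outgoing edges) terminates the chain early.  Nodes visited more
# often are considered more central to the epileptic network.
#
# All restarts are advanced synchronously (vectorized over chains).  RNG
# draws are consumed in a fixed documented order — first the start nodes of
# all restarts (token by token for multi-token runs), then per step one
# uniform per still-active chain in increasing chain index (token by token)
# — so a run is bit-reproducible from its seed.

# Row-wise cumulative transition table; each non-dangling row rescaled so
# its last entry is exactly 1 (guards inverse-CDF lookup against rounding).
.cumTransition <- function(tm) {
  p <- transitionProbs(tm)
  n <- nrow(p)
  cum <- t(apply(p, 1L, cumsum))
  if (n == 1L) cum <- matrix(cum, 1L, 1L)
  tot <- cum[, n]
  pos <- tot > 0
  cum[pos, ] <- cum[pos, , drop = FALSE] / tot[pos]
  cum
}

# Inverse-CDF draw of successor nodes for chains at nodes `cur`.
.drawNext <- function(cum, cur, u) {
  as.integer(rowSums(cum[cur, , drop = FALSE] < u) + 1L)
}

#' Monte Carlo walk sampling of a GC map
#'
#' Runs `restarts` independent chains of up to `maxSteps` visitations on
#' the row-normalized map (see [toTransition()]) and accumulates per-node
#' visitation counts.  Variants, all selected through the [walkConfig()]:
#' \describe{
#'   \item{`direction = "reverse"`}{the map is transposed first
#'     ([reverseEdges()]), so walkers travel "uphill" toward generators of
#'     activity; identical code path, hence bit-identical to forward
#'     sampling of the reversed map under the same seed.}
#'   \item{`metric = "interval"`}{additionally records, per node, the gaps
#'     between consecutive visitations within a chain (a visit, three other
#'     nodes, then a revisit is a gap of 4).  Gaps never carry over a
#'     restart.  Shorter mean intervals indicate tighter cyclic involvement.}
#'   \item{`tokens = k >= 2`}{k tokens start at independent uniform nodes
#'     and advance synchronously; a visitation is recorded only when all
#'     tokens coincide on one node.  A chain ends when any token reaches a
#'     dangling node (the arrival step still counts for coincidence) or
#'     after `maxSteps` synchronous steps.}
#' }
#'
#' @param g a [GCMap-class].
#' @param config a [WalkConfig-class]; see [walkConfig()].
#' @return a [WalkOutcome-class].
#' @export
#' @examples
#' g <- GCMap(rbind(c(0, 1, 0), c(0.5, 0, 0.5), c(1, 0, 0)))
#' sampleWalks(g, walkConfig(restarts = 50, maxSteps = 100, seed = 1))
sampleWalks <- function(g, config = walkConfig()) {
  stopifnot(is(g, "GCMap"), is(config, "WalkConfig"))
  validObject(config)
  if (nNodes(g) == 0L) stopData("cannot sample an empty graph (N = 0)")
  if (config@metric == "interval" && config@tokens > 1L)
    stopConfig("the revisit-interval metric is defined for single-token runs only")
  gWalk <- if (config@direction == "reverse") reverseEdges(g) else g
  seed <- if (is.na(config@seed)) NULL else config@seed
  withSeed(seed, {
    if (config@tokens == 1L) .walkSingle(gWalk, config)
    else .walkMulti(gWalk, config)
  })
}

.walkSingle <- function(g, config) {
  tm <- toTransition(g)
  cum <- .cumTransition(tm)
  n <- nNodes(g)
  R <- config@restarts
  S <- config@maxSteps
  danglingMask <- logical(n)
  danglingMask[danglingNodes(tm)] <- TRUE
  trackIntervals <- config@metric == "interval"

  counts <- numeric(n)
  gapSum <- numeric(n)
  gapCnt <- numeric(n)
  visits <- rep(1L, R)                       # start counts as visitation 1

  cur <- sample.int(n, R, replace = TRUE)
  counts <- counts + tabulate(cur, n)
  if (trackIntervals) {
    lastVisit <- matrix(0, R, n)
    lastVisit[cbind(seq_len(R), cur)] <- 1
  }
  active <- !danglingMask[cur]
  t <- 1L
  while (t < S && any(active)) {
    t <- t + 1L
    idx <- which(active)
    u <- runif(length(idx))
    nxt <- .drawNext(cum, cur[idx], u)
    counts <- counts + tabulate(nxt, n)
    visits[idx] <- visits[idx] + 1L
    if (trackIntervals) {
      prev <- lastVisit[cbind(idx, nxt)]
      rec <- prev > 0
      if (any(rec)) {
        agg <- rowsum(cbind(t - prev[rec], 1), group = nxt[rec])
        ids <- as.integer(rownames(agg))
        gapSum[ids] <- gapSum[ids] + agg[, 1L]
        gapCnt[ids] <- gapCnt[ids] + agg[, 2L]
      }
      lastVisit[cbind(idx, nxt)] <- t
    }
    cur[idx] <- nxt
    active[idx] <- !danglingMask[nxt]
  }
  truncated <- sum(visits < S)
  labs <- nodeLabels(g)
  mi <- ifelse(gapCnt > 0, gapSum / gapCnt, NA_real_)
  names(counts) <- names(mi) <- labs
  new("WalkOutcome", visitCounts = counts,
      meanIntervals = if (trackIntervals) mi else setNames(rep(NA_real_, n), labs),
      completedRestarts = as.integer(R - truncated),
      truncatedRestarts = as.integer(truncated), config = config)
}

.walkMulti <- function(g, config) {
  tm <- toTransition(g)
  cum <- .cumTransition(tm)
  n <- nNodes(g)
  R <- config@restarts
  S <- config@maxSteps
  k <- config@tokens
  danglingMask <- logical(n)
  danglingMask[danglingNodes(tm)] <- TRUE

  counts <- numeric(n)
  steps <- rep(1L, R)
  pos <- matrix(0L, R, k)
  for (m in seq_len(k)) pos[, m] <- sample.int(n, R, replace = TRUE)

  recordCoincidences <- function(idx) {
    same <- rowSums(pos[idx, -1L, drop = FALSE] ==
                      pos[idx, 1L]) == (k - 1L)
    if (any(same)) counts <<- counts + tabulate(pos[idx[same], 1L], n)
  }
  recordCoincidences(seq_len(R))
  active <- rowSums(matrix(danglingMask[pos], R, k)) == 0
  t <- 1L
  while (t < S && any(active)) {
    t <- t + 1L
    idx <- which(active)
    for (m in seq_len(k)) {
      u <- runif(length(idx))
      pos[idx, m] <- .drawNext(cum, pos[idx, m], u)
    }
    steps[idx] <- steps[idx] + 1L
    recordCoincidences(idx)
    stillOk <- rowSums(matrix(danglingMask[pos[idx, , drop = FALSE]],
                              length(idx), k)) == 0
    active[idx] <- stillOk
  }
  truncated <- sum(steps < S)
  labs <- nodeLabels(g)
  names(counts) <- labs
  new("WalkOutcome", visitCounts = counts,
      meanIntervals = setNames(rep(NA_real_, n), labs),
      completedRestarts = as.integer(R - truncated),
      truncatedRestarts = as.integer(truncated), config = config)
}

#' Extract the per-node metric from a walk outcome
#'
#' @param outcome a [WalkOutcome-class].
#' @param metric `"count"` (visitation counts; larger = better) or
#'   `"interval"` (mean revisit interval; smaller = better, `NA` =
#'   never revisited, ranked last).  Defaults to the metric the outcome was
#'   run with.
#' @return named numeric metric vector.
#' @export
outcomeToMetric <- function(outcome, metric = NULL) {
  stopifnot(is(outcome, "WalkOutcome"))
  if (is.null(metric)) metric <- outcome@config@metric
  metric <- match.arg(metric, c("count", "interval"))
  if (metric == "count") visitCounts(outcome) else meanIntervals(outcome)
}

#' Rank nodes from a walk outcome
#'
#' Counts are ranked descending (most visited = rank 1); mean intervals are
#' ranked ascending (shortest interval = rank 1) with never-revisited nodes
#' (undefined interval) placed last.  Ties receive midranks.
#'
#' @inheritParams outcomeToMetric
#' @return a [NodeRanking-class].
#' @export
walkRanking <- function(outcome, metric = NULL) {
  stopifnot(is(outcome, "WalkOutcome"))
  if (is.null(metric)) metric <- outcome@config@metric
  metric <- match.arg(metric, c("count", "interval"))
  m <- outcomeToMetric(outcome, metric)
  nodeRanking(m,
              algorithm = paste0("walk-", metric,
                                 if (outcome@config@tokens > 1L)
                                   paste0("-", outcome@config@tokens, "tok") else ""),
              direction = outcome@config@direction,
              decreasing = metric == "count")
}
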