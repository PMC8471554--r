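# Deterministic node-importance rankings of GC maps.
#
# Shortest-path dialect for betweenness/harmonic: the distance of an edge is
# the reciprocal of its GC weight, so a larger weight means a "shorter",
# easier-to-take path; zero-weight edges are absent.  Betweenness and
# harmonic centrality are computed through igraph; PageRank is implemented
# here because the dangling-node rule differs from library defaults (a
# dangling node's score is shared evenly over all OTHER nodes, never
# returned to itself).

# Column-stochastic-ish transfer matrix M[i, j]: fraction of node i's score
# sent to node j.  Non-dangling rows are weight-proportional; dangling rows
# spread evenly over the other N-1 nodes.
.transferMatrix <- function(g) {
  tm <- toTransition(g)
  M <- transitionProbs(tm)
  n <- nrow(M)
  for (i in danglingNodes(tm)) {
    if (n > 1L) {
      M[i, ] <- 1 / (n - 1)
      M[i, i] <- 0
    }
  }
  M
}

#' Weighted PageRank of a GC map
#'
#' Standard damped, normalized PageRank by power iteration.  Each node
#' splits its outgoing score proportionally to its outgoing edge weights; a
#' dangling node's score is distributed evenly amongst all other nodes; the
#' damping factor blends in a uniform teleport so the iteration converges.
#' Scores sum to one.  With `reverse = TRUE` the map is transposed
#' first, ranking generators ("uphill" nodes) rather than receivers of
#' activity.
#'
#' @param g a [GCMap-class].
#' @param damping damping factor in (0, 1], default 0.85.
#' @param reverse rank on the transposed map.
#' @param tol L1 convergence tolerance of the score vector, default 1e-8.
#' @param maxIter maximum power iterations, default 200.
#' @return a [NodeRanking-class] (algorithm `"pagerank"` or
#'   `"pagerank-rev"`); metric = scores, ranked descending.
#' @export
pageRank <- function(g, damping = 0.85, reverse = FALSE,
                     tol = 1e-8, maxIter = 200) {
  stopifnot(is(g, "GCMap"))
  if (damping <= 0 || damping > 1) stopConfig("'damping' must be in (0, 1]")
  gUse <- if (reverse) reverseEdges(g) else g
  n <- nNodes(gUse)
  if (n == 1L) {
    v <- stats::setNames(1, nodeLabels(gUse))
    return(nodeRanking(v, algorithm = "pagerank", direction = "forward"))
  }
  M <- .transferMatrix(gUse)
  v <- rep(1 / n, n)
  teleport <- (1 - damping) / n
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    vNew <- damping * as.vector(crossprod(M, v)) + teleport
    vNew <- vNew / sum(vNew)
    if (sum(abs(vNew - v)) < tol) {
      v <- vNew
      converged <- TRUE
      break
    }
    v <- vNew
  }
  if (!converged)
    stop(errorCondition(
      sprintf("PageRank did not converge in %d iterations (last L1 change above %g)",
              maxIter, tol),
      class = c("gcnetPagerankError", "error"), lastIterate = v))
  names(v) <- nodeLabels(gUse)
  nodeRanking(v,
              algorithm = if (reverse) "pagerank-rev" else "pagerank",
              direction = if (reverse) "reverse" else "forward")
}

#' Undamped mass-transfer PageRank update (didactic form)
#'
#' The textbook form of the update: every node starts with an equal score
#' (e.g. 10) and, in each synchronous iteration, transfers its ENTIRE
#' current score split over its outgoing edges in proportion to their
#' weights; a node without outgoing edges splits its score evenly over all
#' other nodes.  No damping, no renormalization — total mass is conserved
#' exactly.  This is the update whose first iterations can be followed by
#' hand; use [pageRank()] for actual ranking.
#'
#' @param g a [GCMap-class].
#' @param init initial score, a scalar (applied to every node) or one value
#'   per node.  Default 10.
#' @param iterations number of synchronous iterations.
#' @return named numeric vector of scores after `iterations` updates.
#' @export
#' @examples
#' # three pages: p1 links to p2 and p3, p2 links to p1, p3 links nowhere
#' g <- GCMap(rbind(c(0, 1, 1), c(1, 0, 0), c(0, 0, 0)),
#'            labels = c("p1", "p2", "p3"))
#' pageRankDidactic(g, init = 10, iterations = 1)  # 15, 10, 5
#' pageRankDidactic(g, init = 10, iterations = 2)  # 12.5, 10, 7.5
pageRankDidactic <- function(g, init = 10, iterations = 1) {
  stopifnot(is(g, "GCMap"))
  n <- nNodes(g)
  v <- if (length(init) == 1L) rep(as.numeric(init), n) else as.numeric(init)
  if (length(v) != n) stopConfig("'init' must be scalar or one value per node")
  M <- .transferMatrix(g)
  for (it in seq_len(iterations)) v <- as.vector(crossprod(M, v))
  stats::setNames(v, nodeLabels(g))
}

.asIgraph <- function(g, weighted = TRUE) {
  w <- gcWeights(g)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                            weighted = TRUE, diag = FALSE)
  dist <- if (weighted) 1 / igraph::E(ig)$weight else rep(1, igraph::ecount(ig))
  list(graph = ig, dist = dist)
}

#' Betweenness centrality of a GC map
#'
#' The fraction of shortest directed paths between all node pairs (p, q),
#' p != n != q, that pass through n, counting ties for shortest path.  Edge
#' distance is 1/weight (a stronger GC edge is an easier path).
#'
#' @param g a [GCMap-class].
#' @param weighted use inverse-weight distances (default); `FALSE` counts
#'   unweighted hops.
#' @return a [NodeRanking-class], metric ranked descending.
#' @export
betweennessCentrality <- function(g, weighted = TRUE) {
  stopifnot(is(g, "GCMap"))
  ig <- .asIgraph(g, weighted)
  m <- igraph::betweenness(ig$graph, directed = TRUE, weights = ig$dist)
  m <- stats::setNames(as.numeric(m)[match(nodeLabels(g), igraph::V(ig$graph)$name)],
                       nodeLabels(g))
  nodeRanking(m, algorithm = "betweenness", direction = "forward")
}

#' Harmonic centrality of a GC map
#'
#' For each node n, the sum of inverse shortest-path distances between n
#' and every other node, normalized by N - 1; unreachable pairs contribute
#' 0.  By default distances are measured INTO the node (from p to n, i.e.
#' how easily activity flows to n); `mode = "out"` measures outward
#' distances instead.  Edge distance is 1/weight unless `weighted = FALSE`.
#'
#' @param g a [GCMap-class].
#' @param mode `"in"` (default) or `"out"`.
#' @param weighted use inverse-weight distances (default) or unweighted
#'   hops.
#' @return a [NodeRanking-class], metric ranked descending.
#' @export
harmonicCentrality <- function(g, mode = c("in", "out"), weighted = TRUE) {
  stopifnot(is(g, "GCMap"))
  mode <- match.arg(mode)
  ig <- .asIgraph(g, weighted)
  m <- igraph::harmonic_centrality(ig$graph, mode = mode,
                                   weights = ig$dist, normalized = TRUE)
  m <- stats::setNames(as.numeric(m)[match(nodeLabels(g), igraph::V(ig$graph)$name)],
                       nodeLabels(g))
  nodeRanking(m, algorithm = paste0("harmonic-", mode), direction = "forward")
}

#' In/outdegree centrality of a GC map
#'
#' By default the COUNT of nonzero incoming (`mode = "in"`) or outgoing
#' (`mode = "out"`) edges — after F-test pruning the number of surviving
#' edges is itself informative, independent of their weights.  With
#' `weighted = TRUE` edge weights are summed instead (for `mode = "out"`
#' that equals [totalGCOutdegree()]).
#'
#' @param g a [GCMap-class].
#' @param mode `"in"` or `"out"`.
#' @param weighted sum weights instead of counting edges.
#' @return a [NodeRanking-class], metric ranked descending.
#' @export
degreeCentrality <- function(g, mode = c("in", "out"), weighted = FALSE) {
  stopifnot(is(g, "GCMap"))
  mode <- match.arg(mode)
  w <- gcWeights(g)
  if (!weighted) w <- (w > 0) + 0
  m <- if (mode == "out") rowSums(w) else colSums(w)
  nodeRanking(m, algorithm = paste0(mode, "degree"), direction = "forward")
}

#' Total-GC-outdegree baseline
#'
#' The sum of all GC edge weights originating at each node — the baseline
#' metric this package's graph algorithms are compared against.
#'
#' @param g a [GCMap-class].
#' @return a [NodeRanking-class], metric = row sums, ranked descending.
#' @export
totalGCOutdegree <- function(g) {
  stopifnot(is(g, "GCMap"))
  nodeRanking(rowSums(gcWeights(g)), algorithm = "gc-outdegree",
              direction = "forward")
}

#' Best-ranked k node labels
#'
#' @param r a [NodeRanking-class].
#' @param k how many labels, `1 <= k <= N`.
#' @return character vector of the k best-ranked labels; midrank ties at
#'   the boundary are broken by lexicographic label order.
#' @export
topK <- function(r, k) {
  stopifnot(is(r, "NodeRanking"))
  n <- length(nodeRanks(r))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stopConfig("'k' must be in [1, ", n, "]")
  ranks <- nodeRanks(r)
  ord <- order(ranks, names(ranks))
  names(ranks)[ord][seq_len(k)]
}

# Registry of ranking algorithms by identifier, used by evaluatePatient()
# and runCohort().  Stochastic algorithms accept a seed.
.rankingAlgorithms <- function() {
  list(
    "pagerank"      = function(g, ...) pageRank(g, ...),
    "pagerank-rev"  = function(g, ...) pageRank(g, reverse = TRUE, ...),
    "betweenness"   = function(g, ...) betweennessCentrality(g, ...),
    "harmonic"      = function(g, ...) harmonicCentrality(g, ...),
    "indegree"      = function(g, ...) degreeCentrality(g, mode = "in", ...),
    "outdegree"     = function(g, ...) degreeCentrality(g, mode = "out", ...),
    "gc-outdegree"  = function(g, ...) totalGCOutdegree(g),
    "walk-count"    = function(g, seed = NULL, restarts = 1000,
                               maxSteps = 1000, direction = "forward",
                               tokens = 1, ...) {
      walkRanking(sampleWalks(g, walkConfig(restarts = restarts,
                                            maxSteps = maxSteps,
                                            direction = direction,
                                            metric = "count",
                                            tokens = tokens, seed = seed)))
    },
    "walk-interval" = function(g, seed = NULL, restarts = 1000,
                               maxSteps = 1000, direction = "forward", ...) {
      walkRanking(sampleWalks(g, walkConfig(restarts = restarts,
                                            maxSteps = maxSteps,
                                            direction = direction,
                                            metric = "interval", seed = seed)))
    }
  )
}

#' Names of the available ranking algorithms
#' @return character vector of algorithm identifiers accepted by
#'   [evaluatePatient()] and [runCohort()].
#' @export
rankingAlgorithms <- function() names(.rankingAlgorithms())

# TRUE for algorithms whose output depends on a random seed.
.isStochastic <- function(algorithm) {
  algorithm %in% c("walk-count", "walk-interval")
}

#' Rank the nodes of a GC map with a named algorithm
#'
#' Dispatch by algorithm identifier (see [rankingAlgorithms()]); extra
#' arguments are passed to the algorithm (e.g. `seed`, `restarts` for walk
#' variants, `damping` for PageRank).
#'
#' @param g a [GCMap-class].
#' @param algorithm identifier string.
#' @param ... passed to the algorithm function.
#' @return a [NodeRanking-class].
#' @export
rankNodes <- function(g, algorithm, ...) {
  algs <- .rankingAlgorithms()
  if (!algorithm %in% names(algs))
    stopConfig("unknown algorithm '", algorithm, "'; available: ",
               paste(names(algs), collapse = ", "))
  algs[[algorithm]](g, ...)
}
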