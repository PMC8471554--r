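# Rank-order-sum evaluation of node rankings against SOZ/RZ label sets.
#
# The statistic: sum the (mid)ranks the algorithm assigned to the target
# node set.  Under the null that the algorithm carries no information about
# the targets, the sum behaves like the sum of k ranks drawn at random from
# {1..N} without replacement (the Wilcoxon rank-sum null), with
#   E[S]   = k (N + 1) / 2
#   Var[S] = k (N - k) (N + 1) / 12.
# A significantly SMALL observed sum means the target nodes are ranked
# early, i.e. the algorithm prioritizes the epileptogenic set.

#' Sum of the midranks of a target node set
#'
#' @param r a [NodeRanking-class].
#' @param targets nonempty character vector of node labels (e.g. the SOZ).
#' @return the rank-order sum (a single number).
#' @export
rankOrderSum <- function(r, targets) {
  stopifnot(is(r, "NodeRanking"))
  targets <- unique(as.character(targets))
  if (length(targets) < 1L) stopConfig("'targets' must be nonempty")
  ranks <- nodeRanks(r)
  missing <- setdiff(targets, names(ranks))
  if (length(missing))
    stopData("target label(s) not in the ranking: ",
             paste(missing, collapse = ", "))
  sum(ranks[targets])
}

#' Monte Carlo null distribution of rank-order sums
#'
#' Each repetition draws `nTarget` ranks from `1..nTotal` (by default
#' without replacement, since real node ranks are distinct) and sums them.
#' The fitted mean and sd are the sample moments of the simulated sums.
#'
#' @param nTotal total number of nodes N.
#' @param nTarget size k of the target set.
#' @param repetitions number of repetitions, default 1e5.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param replacement draw ranks with replacement (a looser null where
#'   duplicate ranks may be drawn).
#' @return a [NullDistribution-class].
#' @export
simulateNull <- function(nTotal, nTarget, repetitions = 1e5, seed = NULL,
                         replacement = FALSE) {
  nTotal <- as.integer(nTotal); nTarget <- as.integer(nTarget)
  repetitions <- as.integer(repetitions)
  if (nTarget < 1L || (!replacement && nTarget > nTotal))
    stopConfig("'nTarget' must be in [1, nTotal] when sampling without replacement")
  if (repetitions < 1L) stopConfig("'repetitions' must be >= 1")
  sums <- withSeed(seed, {
    if (replacement) {
      colSums(matrix(sample.int(nTotal, nTarget * repetitions, replace = TRUE),
                     nrow = nTarget))
    } else if (nTarget == nTotal) {
      rep(nTotal * (nTotal + 1) / 2, repetitions)
    } else {
      vapply(seq_len(repetitions),
             function(i) sum(sample.int(nTotal, nTarget)), numeric(1))
    }
  })
  new("NullDistribution", sums = as.numeric(sums),
      fittedMean = mean(sums), fittedSd = sd(sums),
      repetitions = repetitions,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nTotal = nTotal, nTarget = nTarget, replacement = replacement)
}

# Exact moments of the sum of k ranks from 1..N.
.nullMoments <- function(nTotal, nTarget, replacement = FALSE) {
  n <- as.numeric(nTotal); k <- as.numeric(nTarget)
  m <- k * (n + 1) / 2
  v <- if (replacement) k * (n^2 - 1) / 12 else k * (n - k) * (n + 1) / 12
  c(mean = m, sd = sqrt(v))
}

#' Significance of a rank-order sum for a target node set
#'
#' Computes the observed rank-order sum of `targets` under the ranking `r`
#' and a one-sided lower-tail p-value against the null of randomly placed
#' targets.  Methods:
#' \describe{
#'   \item{`"mc_normal"` (default)}{fit a normal distribution to a Monte
#'     Carlo sample of null sums and evaluate `P(S <= observed)`.}
#'   \item{`"mc_empirical"`}{the empirical tail
#'     `(#\{null <= obs\} + 1) / (repetitions + 1)`; preferable for small N,
#'     where the normal fit is rough.}
#'   \item{`"closed_form"`}{normal p-value from the exact null moments
#'     (no simulation).}
#' }
#'
#' @param r a [NodeRanking-class].
#' @param targets nonempty character vector of node labels.
#' @param repetitions Monte Carlo repetitions (ignored for
#'   `"closed_form"`), default 1e5.
#' @param alpha significance level, default 0.05.
#' @param seed integer seed for the Monte Carlo null.
#' @param method see above.
#' @param replacement see [simulateNull()].
#' @return a [RankOrderResult-class].
#' @export
#' @examples
#' r <- nodeRankingFromMetric(c(a = 9, b = 7, c = 3, d = 1), "example")
#' evaluateRanking(r, c("a", "b"), repetitions = 1000, seed = 1)
evaluateRanking <- function(r, targets, repetitions = 1e5, alpha = 0.05,
                            seed = NULL,
                            method = c("mc_normal", "mc_empirical",
                                       "closed_form"),
                            replacement = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopConfig("'alpha' must be in (0, 1)")
  obs <- rankOrderSum(r, targets)
  n <- length(nodeRanks(r))
  k <- length(unique(as.character(targets)))
  if (method == "closed_form") {
    mom <- .nullMoments(n, k, replacement)
    nullMean <- mom["mean"]; nullSd <- mom["sd"]
    p <- .normalTail(obs, nullMean, nullSd)
  } else {
    nd <- simulateNull(n, k, repetitions = repetitions, seed = seed,
                       replacement = replacement)
    nullMean <- nd@fittedMean; nullSd <- nd@fittedSd
    p <- if (method == "mc_normal") {
      .normalTail(obs, nullMean, nullSd)
    } else {
      (sum(nullSums(nd) <= obs) + 1) / (nd@repetitions + 1)
    }
  }
  new("RankOrderResult", observedSum = obs, nTotal = as.integer(n),
      nTarget = as.integer(k), nullMean = unname(nullMean),
      nullSd = unname(nullSd), pValue = unname(p),
      significant = unname(p < alpha), alpha = alpha, method = method)
}

.normalTail <- function(obs, m, s) {
  if (s == 0) return(as.numeric(obs < m) + 0.5 * (obs == m))
  pnorm(obs, mean = m, sd = s)
}

#' Build a NodeRanking directly from a metric vector
#'
#' Convenience constructor for external metrics (e.g. from a file):
#' midranks are computed with rank 1 the best node.
#'
#' @param metric named numeric vector (names = node labels).
#' @param algorithm identifier recorded in the ranking.
#' @param decreasing larger metric = better (default).
#' @param direction edge orientation tag, `"forward"` or `"reverse"`.
#' @return a [NodeRanking-class].
#' @export
nodeRankingFromMetric <- function(metric, algorithm = "external",
                                  decreasing = TRUE, direction = "forward") {
  if (is.null(names(metric))) stopConfig("'metric' must be named by node label")
  nodeRanking(metric, algorithm = algorithm, direction = direction,
              decreasing = decreasing)
}

#' Evaluate one patient: rank and test SOZ and RZ rank-order sums
#'
#' Runs the named ranking algorithm over the patient's segment maps and
#' evaluates the rank-order sums of the SOZ and (if present) RZ label
#' sets.  Two aggregation policies combine the per-segment maps:
#' \describe{
#'   \item{`"metrics"` (default)}{run the algorithm on every segment map and
#'     average the per-node metric across segments before ranking —
#'     preserves the per-segment sparsity structure left by F-test
#'     pruning.}
#'   \item{`"map"`}{elementwise-average the segment maps first
#'     ([aggregateMaps()]) and run the algorithm once on the mean map.}
#' }
#' For stochastic algorithms each segment receives its own seed derived
#' from `seed` and the segment index ([deriveSeed()]).
#'
#' @param p a [PatientRecord-class].
#' @param algorithm ranking algorithm identifier (see
#'   [rankingAlgorithms()]).
#' @param aggregate `"metrics"` or `"map"`.
#' @param repetitions,alpha,method,replacement passed to
#'   [evaluateRanking()].
#' @param seed global seed for this patient.
#' @param ... extra arguments for the ranking algorithm.
#' @return a list with elements `soz` and `rz` (each a
#'   [RankOrderResult-class]; `rz` is `NULL` when the patient has no
#'   resection zone) plus `ranking`, the [NodeRanking-class] used.
#' @export
evaluatePatient <- function(p, algorithm, aggregate = c("metrics", "map"),
                            repetitions = 1e5, alpha = 0.05, seed = NULL,
                            method = "mc_normal", replacement = FALSE, ...) {
  stopifnot(is(p, "PatientRecord"))
  aggregate <- match.arg(aggregate)
  segs <- segments(p)
  stochastic <- .isStochastic(algorithm)
  segSeed <- function(i) {
    if (is.null(seed) || !stochastic) NULL
    else deriveSeed(seed, paste0("segment", i))
  }
  ranking <- if (aggregate == "map") {
    args <- list(aggregateMaps(segs), ...)
    if (stochastic) args$seed <- segSeed(0L)
    do.call(rankNodes, c(args, algorithm = algorithm))
  } else {
    perSeg <- lapply(seq_along(segs), function(i) {
      args <- list(segs[[i]], ...)
      if (stochastic) args$seed <- segSeed(i)
      do.call(rankNodes, c(args, algorithm = algorithm))
    })
    metrics <- vapply(perSeg, nodeMetric, numeric(nNodes(p)))
    # average the metric across segments; NA (undefined interval) treated as
    # absent in the mean, nodes undefined in every segment stay NA
    m <- rowMeans(metrics, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    names(m) <- nodeLabels(p)
    nodeRanking(m, algorithm = algorithmId(perSeg[[1L]]),
                direction = perSeg[[1L]]@direction,
                decreasing = !grepl("interval", algorithm))
  }
  evalSeed <- if (is.null(seed)) NULL else deriveSeed(seed, "null")
  out <- list(
    soz = evaluateRanking(ranking, sozLabels(p), repetitions = repetitions,
                          alpha = alpha, seed = evalSeed, method = method,
                          replacement = replacement),
    rz = NULL, ranking = ranking)
  if (length(rzLabels(p))) {
    rzSeed <- if (is.null(seed)) NULL else deriveSeed(seed, "null-rz")
    out$rz <- evaluateRanking(ranking, rzLabels(p), repetitions = repetitions,
                              alpha = alpha, seed = rzSeed, method = method,
                              replacement = replacement)
  }
  out
}
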