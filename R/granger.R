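# Bivariate time-domain Granger causality with F-test edge pruning.
#
# For every ordered channel pair (i -> j) two nested OLS autoregressions of
# channel j are fitted: a restricted model on j's own p lags, and a full
# model that adds p lags of channel i.  The GC magnitude is the Geweke log
# variance ratio ln(RSS_restricted / RSS_full) >= 0, and the nested-model F
# statistic decides which edges survive pruning.  This is deliberately the
# pairwise (bivariate) formulation; conditional multivariate GC is out of
# scope.

#' Pairwise Granger causality over all channel pairs of a segment
#'
#' Channels are mean-centred, then for each ordered pair (i, j) the
#' restricted model regresses `x_j[t]` on lags `1..p` of `x_j` and the full
#' model additionally on lags `1..p` of `x_i` (both with intercept, fitted
#' by QR least squares on the last `T - p` samples).  Outputs:
#' `gc[i, j] = ln(RSS_r / RSS_f)` and
#' `F[i, j] = ((RSS_r - RSS_f) / p) / (RSS_f / (T_eff - 2p - 1))` with
#' `T_eff = T - p`, on `(p, T_eff - 2p - 1)` degrees of freedom.
#'
#' Degenerate pairs (rank-deficient design, e.g. a constant channel, or a
#' zero full-model residual) are set to `gc = 0`, `F = 0` with a warning.
#'
#' @param seg a [Segment-class] (or a channels x samples numeric matrix).
#' @param order VAR model order p (number of lags), default 10.
#' @return a [GCResult-class].
#' @seealso [significanceFilter()] to turn the result into a pruned
#'   [GCMap-class], [selectOrder()] for an AIC-based choice of `order`.
#' @export
pairwiseGC <- function(seg, order = 10) {
  if (is.matrix(seg)) seg <- Segment(seg)
  stopifnot(is(seg, "Segment"))
  p <- as.integer(order)
  if (p < 1L) stopConfig("'order' must be >= 1")
  x <- seg@data
  C <- nrow(x); T <- ncol(x)
  if (T <= 3L * p + 1L)
    stopData("segment too short: need T > 3*order + 1 samples, got T = ", T)
  x <- x - rowMeans(x)               # per-channel mean removal
  Teff <- T - p
  dfden <- Teff - 2L * p - 1L

  # lag design blocks: lagBlock[[c]] is Teff x p, column l = x_c lagged by l
  lagBlock <- lapply(seq_len(C), function(cc) {
    emb <- stats::embed(x[cc, ], p + 1L)
    emb[, -1L, drop = FALSE]
  })
  resp <- lapply(seq_len(C), function(cc) x[cc, (p + 1L):T])
  ones <- rep(1, Teff)

  rssOf <- function(X, y) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) return(NA_real_)
    sum(qr.resid(qrX, y)^2)
  }

  gc <- matrix(0, C, C)
  fs <- matrix(0, C, C)
  nBad <- 0L
  rssR <- vapply(seq_len(C), function(j) {
    rssOf(cbind(ones, lagBlock[[j]]), resp[[j]])
  }, numeric(1))
  for (j in seq_len(C)) {
    for (i in seq_len(C)) {
      if (i == j) next
      rf <- rssOf(cbind(ones, lagBlock[[j]], lagBlock[[i]]), resp[[j]])
      if (is.na(rssR[j]) || is.na(rf) || rf <= 0) {
        nBad <- nBad + 1L
        next                          # gc and F stay 0
      }
      gc[i, j] <- max(0, log(rssR[j] / rf))
      fs[i, j] <- max(0, ((rssR[j] - rf) / p) / (rf / dfden))
    }
  }
  if (nBad > 0L)
    warning(nBad, " channel pair(s) had singular or degenerate fits; ",
            "their GC set to 0")
  dimnames(gc) <- dimnames(fs) <- list(seg@labels, seg@labels)
  new("GCResult", gc = gc, fstat = fs, dof = c(p, dfden),
      order = p, labels = seg@labels)
}

#' AIC-based VAR model-order selection
#'
#' Chooses the lag order minimizing the mean univariate autoregressive AIC
#' across channels, evaluated on a common effective sample so orders are
#' comparable.  A pragmatic default when no physiological prior fixes the
#' order.
#'
#' @param seg a [Segment-class] or channels x samples matrix.
#' @param maxOrder largest order considered (default 20).
#' @return the selected integer order.
#' @export
selectOrder <- function(seg, maxOrder = 20) {
  if (is.matrix(seg)) seg <- Segment(seg)
  x <- seg@data - rowMeans(seg@data)
  T <- ncol(x)
  maxOrder <- min(as.integer(maxOrder), (T - 2L) %/% 3L)
  if (maxOrder < 1L) stopData("segment too short for order selection")
  Teff <- T - maxOrder
  aic <- vapply(seq_len(maxOrder), function(p) {
    mean(vapply(seq_len(nrow(x)), function(cc) {
      emb <- stats::embed(x[cc, ], maxOrder + 1L)
      y <- emb[, 1L]
      X <- cbind(1, emb[, 1L + seq_len(p), drop = FALSE])
      rss <- sum(qr.resid(qr(X), y)^2)
      Teff * log(rss / Teff) + 2 * (p + 1)
    }, numeric(1)))
  }, numeric(1))
  which.min(aic)
}

#' Prune non-significant GC edges with an F test
#'
#' Edges whose F statistic does not exceed the critical value of the
#' F(p, T_eff - 2p - 1) distribution at level `alpha` are removed (weight
#' set to 0); surviving edges keep their GC magnitude as edge weight.  No
#' multiple-comparison correction is applied by default (per-edge alpha);
#' `bonferroni = TRUE` divides alpha by the number of ordered pairs.
#'
#' @param res a [GCResult-class] from [pairwiseGC()].
#' @param alpha per-edge significance level in (0, 1), default 0.05.
#' @param bonferroni apply a Bonferroni correction over the N(N-1) tests.
#' @return a pruned [GCMap-class].
#' @export
significanceFilter <- function(res, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(is(res, "GCResult"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stopConfig("'alpha' must be a single value in (0, 1)")
  n <- nrow(res@gc)
  a <- if (bonferroni && n > 1) alpha / (n * (n - 1)) else alpha
  crit <- qf(1 - a, res@dof[1], res@dof[2])
  w <- res@gc
  w[res@fstat <= crit] <- 0
  GCMap(w, labels = res@labels)
}

#' Read a multichannel time-series segment from CSV
#'
#' Expects samples as rows and channels as columns, with a header row of
#' channel labels (the transpose of the in-memory channels x samples
#' layout, which keeps the file human-readable for long recordings).
#'
#' @param path CSV path.
#' @param sampleRate sampling rate in Hz (informational).
#' @return a [Segment-class].
#' @export
readSegment <- function(path, sampleRate = NA_real_) {
  if (!file.exists(path)) stopConfig("segment file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- t(as.matrix(df))
  if (!is.numeric(m)) stopData("non-numeric values in segment file: ", path)
  Segment(m, labels = colnames(df), sampleRate = sampleRate)
}
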