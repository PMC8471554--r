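# Independent oracles and fixture generators used across the suite.
# These deliberately take the dumbest correct route (exhaustive enumeration,
# dense linear algebra, direct distribution propagation) and share no code
# with the implementation they check.

# Random sparse nonnegative GC weight matrix (zero diagonal).
randomWeights <- function(n, density = 0.4) {
  w <- matrix(0, n, n)
  off <- which(row(w) != col(w))
  hit <- off[runif(length(off)) < density]
  w[hit] <- runif(length(hit), 0.1, 2)
  w
}

randomGCMap <- function(n, density = 0.4) {
  GCMap(randomWeights(n, density))
}

# Digraph whose edge distances (1/weight) are small integers, so shortest
# path lengths are exact in floating point and ties are detected identically
# by any correct implementation.
integerDistanceGCMap <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  off <- which(row(w) != col(w))
  hit <- off[runif(length(off)) < density]
  w[hit] <- 1 / sample(1:4, length(hit), replace = TRUE)
  GCMap(w)
}

# Exhaustive simple-path enumeration: exact shortest-path distances, path
# counts, betweenness and (incoming) harmonic centrality.  Feasible for
# n <= 7.  Distance of an edge = 1 / weight.
oracleCentrality <- function(w, eps = 1e-9) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- Inf
  dist <- matrix(Inf, n, n)
  btw <- numeric(n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      best <- Inf
      paths <- list()
      rec <- function(path, len) {
        v <- path[length(path)]
        if (v == q) {
          if (len < best - eps) {
            best <<- len
            paths <<- list(path)
          } else if (abs(len - best) <= eps) {
            paths[[length(paths) + 1L]] <<- path
          }
          return(invisible())
        }
        for (u in which(is.finite(d[v, ]))) {
          if (!(u %in% path) && len + d[v, u] <= best + eps)
            rec(c(path, u), len + d[v, u])
        }
      }
      rec(p, 0)
      dist[p, q] <- best
      if (length(paths)) {
        interior <- table(unlist(lapply(paths, function(pa) {
          pa[-c(1L, length(pa))]
        })))
        if (length(interior)) {
          ids <- as.integer(names(interior))
          btw[ids] <- btw[ids] + as.numeric(interior) / length(paths)
        }
      }
    }
  }
  harm <- vapply(seq_len(n), function(v) {
    sum(1 / dist[-v, v][is.finite(dist[-v, v])]) / (n - 1)
  }, numeric(1))
  list(dist = dist, betweenness = btw, harmonic = harm)
}

# Dense linear-solve PageRank with the package's dangling rule (score of a
# dangling node shared evenly over the other nodes), written independently
# of the power-iteration implementation.
oraclePageRank <- function(w, damping = 0.85) {
  n <- nrow(w)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(w[i, ])
    if (s > 0) {
      M[i, ] <- w[i, ] / s
    } else {
      M[i, ] <- 1 / (n - 1)
      M[i, i] <- 0
    }
  }
  v <- solve(diag(n) - damping * t(M), rep((1 - damping) / n, n))
  v / sum(v)
}

# Expected per-visitation-slot node frequencies of the restart-augmented
# walk: average over steps t = 1..S of the step-t occupancy distribution
# (uniform start propagated through the transition matrix).  Valid for
# graphs without dangling nodes.  Also returns the 2-token coincidence
# frequencies (squares of the occupancy, tokens being independent chains).
oracleWalkFrequencies <- function(w, steps) {
  P <- w / rowSums(w)
  n <- nrow(w)
  mu <- rep(1 / n, n)
  acc <- mu
  acc2 <- mu^2
  for (t in seq_len(steps - 1L)) {
    mu <- as.vector(mu %*% P)
    acc <- acc + mu
    acc2 <- acc2 + mu^2
  }
  list(visit = acc / steps, coincide = acc2 / steps)
}

# All C(N, k) rank-subset sums, exhaustively.
oracleNullSums <- function(n, k) {
  colSums(utils::combn(n, k))
}

# Run the walk sampler in independent chunks and return per-chunk,
# per-node frequencies (rows = chunks), for Monte-Carlo standard errors.
walkFrequencyRuns <- function(g, nRuns, restarts, steps, baseSeed,
                              tokens = 1) {
  t(vapply(seq_len(nRuns), function(r) {
    o <- sampleWalks(g, walkConfig(restarts = restarts, maxSteps = steps,
                                   tokens = tokens, seed = baseSeed + r))
    visitCounts(o) / (restarts * steps)
  }, numeric(nNodes(g))))
}
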