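# Deterministic rankings: PageRank (damped and didactic), centralities,
# degree metrics, topK.

threePage <- function() {
  # p1 links to p2 and p3, p2 links to p1, p3 links nowhere
  GCMap(rbind(c(0, 1, 1), c(1, 0, 0), c(0, 0, 0)),
        labels = c("p1", "p2", "p3"))
}

test_that("the didactic mass-transfer update reproduces the hand-worked scores", {
  g <- threePage()
  expect_identical(unname(pageRankDidactic(g, init = 10, iterations = 1)),
                   c(15, 10, 5))
  expect_identical(unname(pageRankDidactic(g, init = 10, iterations = 2)),
                   c(12.5, 10, 7.5))
})

test_that("the didactic update conserves total mass on arbitrary graphs", {
  set.seed(201)
  for (r in 1:5) {
    g <- randomGCMap(sample(3:8, 1), density = 0.4)
    for (it in c(1, 3, 7)) {
      s <- pageRankDidactic(g, init = 10, iterations = it)
      expect_equal(sum(s), 10 * nNodes(g))
    }
  }
})

test_that("pageRank matches a dense linear-solve oracle to 1e-10", {
  g <- threePage()
  r <- pageRank(g, damping = 0.85, tol = 1e-13)
  expect_equal(unname(nodeMetric(r)), oraclePageRank(gcWeights(g), 0.85),
               tolerance = 1e-10)
  set.seed(202)
  for (i in 1:8) {
    g <- randomGCMap(sample(3:10, 1), density = runif(1, 0.3, 0.8))
    r <- pageRank(g, tol = 1e-13, maxIter = 2000)
    expect_equal(unname(nodeMetric(r)), oraclePageRank(gcWeights(g)),
                 tolerance = 1e-10)
    expect_equal(sum(nodeMetric(r)), 1, tolerance = 1e-9)
  }
})

test_that("pageRank is symmetric on a symmetric 2-cycle for any damping", {
  g <- GCMap(rbind(c(0, 1), c(1, 0)))
  for (d in c(0.3, 0.85, 1)) {
    expect_equal(unname(nodeMetric(pageRank(g, damping = d))), c(0.5, 0.5))
  }
})

test_that("pageRank reports non-convergence with the last iterate attached", {
  g <- threePage()
  err <- tryCatch(pageRank(g, maxIter = 2, tol = 1e-15), error = identity)
  expect_s3_class(err, "gcnetPagerankError")
  expect_length(err$lastIterate, 3)
})

test_that("betweenness singles out the transit node of a directed path", {
  g <- GCMap(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
             labels = c("a", "b", "c"))
  m <- nodeMetric(betweennessCentrality(g))
  expect_gt(m["b"], 0)
  expect_equal(unname(m[c("a", "c")]), c(0, 0))
})

test_that("betweenness and harmonic match the exhaustive path oracle", {
  set.seed(203)
  for (i in 1:10) {
    g <- integerDistanceGCMap(sample(4:7, 1), density = 0.5)
    o <- oracleCentrality(gcWeights(g))
    expect_equal(unname(nodeMetric(betweennessCentrality(g))),
                 o$betweenness, tolerance = 1e-12)
    expect_equal(unname(nodeMetric(harmonicCentrality(g))),
                 o$harmonic, tolerance = 1e-12)
  }
})

test_that("equal-weight betweenness equals unweighted betweenness", {
  set.seed(204)
  w <- (randomWeights(6, 0.5) > 0) * 1
  g <- GCMap(w)
  expect_equal(nodeMetric(betweennessCentrality(g, weighted = TRUE)),
               nodeMetric(betweennessCentrality(g, weighted = FALSE)))
})

test_that("harmonic centrality handles unit cycles and isolated nodes", {
  g <- GCMap(rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(nodeMetric(harmonicCentrality(g))), c(1, 1))
  w <- matrix(0, 3, 3); w[1, 2] <- 1; w[2, 1] <- 1   # node 3 isolated
  expect_equal(unname(nodeMetric(harmonicCentrality(GCMap(w))))[3], 0)
})

test_that("degree centrality counts pruned-surviving edges", {
  w <- matrix(0, 6, 6); w[1, 2:6] <- runif(5, 0.5, 2)   # a 5-leaf star hub
  g <- GCMap(w)
  mOut <- nodeMetric(degreeCentrality(g, "out"))
  expect_equal(unname(mOut), c(5, 0, 0, 0, 0, 0))
  # weighted option recovers the GC-outdegree baseline
  expect_equal(nodeMetric(degreeCentrality(g, "out", weighted = TRUE)),
               nodeMetric(totalGCOutdegree(g)))
})

test_that("reversal dualities hold exactly for degree, total-GC and pagerank", {
  set.seed(205)
  for (i in 1:6) {
    g <- randomGCMap(sample(3:9, 1), density = 0.5)
    gr <- reverseEdges(g)
    expect_identical(nodeMetric(degreeCentrality(g, "out")),
                     nodeMetric(degreeCentrality(gr, "in")))
    expect_identical(nodeMetric(degreeCentrality(g, "in")),
                     nodeMetric(degreeCentrality(gr, "out")))
    expect_identical(nodeMetric(totalGCOutdegree(gr)),
                     setNames(colSums(gcWeights(g)), nodeLabels(g)))
    expect_identical(nodeMetric(pageRank(g, reverse = TRUE)),
                     nodeMetric(pageRank(gr)))
  }
})

test_that("an empty graph gives all-tied midranks", {
  g <- GCMap(matrix(0, 5, 5))
  r <- degreeCentrality(g, "out")
  expect_equal(unname(nodeRanks(r)), rep(3, 5))   # (N+1)/2
  expect_equal(sum(nodeRanks(r)), 5 * 6 / 2)
})

test_that("total GC outdegree is the row sums", {
  g <- GCMap(rbind(c(0, 0.2, 0.3), c(0, 0, 0), c(0.1, 0, 0)))
  expect_equal(unname(nodeMetric(totalGCOutdegree(g))), c(0.5, 0, 0.1))
  # binary weights: equals the outdegree edge count
  gb <- GCMap((gcWeights(g) > 0) * 1)
  expect_equal(nodeMetric(totalGCOutdegree(gb)),
               nodeMetric(degreeCentrality(gb, "out")))
})

test_that("ranks always satisfy the midrank-sum identity", {
  set.seed(206)
  for (i in 1:6) {
    n <- sample(3:12, 1)
    g <- randomGCMap(n, density = 0.4)
    for (alg in c("pagerank", "betweenness", "harmonic", "indegree",
                  "outdegree", "gc-outdegree")) {
      r <- rankNodes(g, alg)
      expect_equal(sum(nodeRanks(r)), n * (n + 1) / 2)
    }
  }
})

test_that("topK picks best ranks and breaks boundary ties lexicographically", {
  r <- nodeRankingFromMetric(c(a = 9, b = 5, c = 3), "m")
  expect_equal(topK(r, 2), c("a", "b"))
  expect_setequal(topK(r, 3), c("a", "b", "c"))
  # b and c tie at the k = 2 boundary; the lexicographically smaller wins
  r2 <- nodeRankingFromMetric(c(a = 9, c = 5, b = 5), "m")
  expect_equal(topK(r2, 2), c("a", "b"))
  expect_error(topK(r, 4), class = "gcnetConfigError")
  expect_error(topK(r, 0), class = "gcnetConfigError")
})
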