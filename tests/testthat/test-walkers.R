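# Monte Carlo walk sampling: termination, intervals, tokens, reproducibility.

twoCycle <- function(w12 = 1, w21 = 1) {
  GCMap(rbind(c(0, w12), c(w21, 0)), labels = c("a", "b"))
}

test_that("an edgeless graph truncates every restart after its start node", {
  g <- GCMap(matrix(0, 4, 4))
  o <- sampleWalks(g, walkConfig(restarts = 37, maxSteps = 10, seed = 1))
  expect_equal(sum(visitCounts(o)), 37)
  expect_equal(o@truncatedRestarts, 37L)
  expect_equal(o@completedRestarts, 0L)
})

test_that("a 2-node cycle alternates deterministically", {
  o <- sampleWalks(twoCycle(0.7, 0.2),
                   walkConfig(restarts = 1, maxSteps = 4, seed = 5))
  expect_equal(unname(visitCounts(o)), c(2, 2))
  expect_equal(o@truncatedRestarts, 0L)
})

test_that("revisit intervals follow the worked count (three intervening nodes -> 4)", {
  # deterministic 4-cycle: a node is revisited exactly every 4 visitations
  w <- matrix(0, 4, 4)
  w[cbind(1:4, c(2, 3, 4, 1))] <- 1
  g <- GCMap(w)
  o <- sampleWalks(g, walkConfig(restarts = 3, maxSteps = 9,
                                 metric = "interval", seed = 2))
  mi <- meanIntervals(o)
  expect_equal(unname(mi[!is.na(mi)]), rep(4, sum(!is.na(mi))))
  # 2-node cycle: every interval is 2
  o2 <- sampleWalks(twoCycle(), walkConfig(restarts = 1, maxSteps = 6,
                                           metric = "interval", seed = 3))
  expect_equal(unname(meanIntervals(o2)), c(2, 2))
})

test_that("intervals do not carry over restarts and lone visits stay undefined", {
  # a -> b only: each restart visits each node at most once, so no node is
  # ever revisited within a restart
  g <- GCMap(rbind(c(0, 1), c(0, 0)), labels = c("a", "b"))
  o <- sampleWalks(g, walkConfig(restarts = 50, maxSteps = 10,
                                 metric = "interval", seed = 4))
  expect_true(all(is.na(meanIntervals(o))))
  r <- walkRanking(o)
  # all-undefined intervals collapse to tied midranks
  expect_equal(unname(nodeRanks(r)), c(1.5, 1.5))
})

test_that("interval ranking places undefined intervals last", {
  o <- new("WalkOutcome",
           visitCounts = c(a = 10, b = 8, c = 1),
           meanIntervals = c(a = 2, b = 5, c = NA),
           completedRestarts = 1L, truncatedRestarts = 0L,
           config = walkConfig(metric = "interval"))
  expect_equal(nodeRanks(walkRanking(o)), c(a = 1, b = 2, c = 3))
  # count metric ranks descending
  expect_equal(nodeRanks(walkRanking(o, metric = "count")),
               c(a = 1, b = 2, c = 3))
})

test_that("two tokens on a 2-cycle preserve start parity", {
  # in-phase starts record a coincidence on every step; out-of-phase starts
  # record none, so per-restart coincidence totals are 0 or maxSteps exactly
  S <- 8
  o <- sampleWalks(twoCycle(), walkConfig(restarts = 40, maxSteps = S,
                                          tokens = 2, seed = 6))
  total <- sum(visitCounts(o))
  expect_equal(total %% S, 0)
  expect_gt(total, 0)                       # some restarts start in phase
  expect_lt(total, 40 * S)                  # some start out of phase
})

test_that("same seed and config give bit-identical outcomes", {
  set.seed(77)
  g <- randomGCMap(8, density = 0.5)
  cfg <- walkConfig(restarts = 100, maxSteps = 50, metric = "interval",
                    seed = 123)
  o1 <- sampleWalks(g, cfg)
  o2 <- sampleWalks(g, cfg)
  expect_identical(visitCounts(o1), visitCounts(o2))
  expect_identical(meanIntervals(o1), meanIntervals(o2))
  cfg2 <- walkConfig(restarts = 100, maxSteps = 50, tokens = 2, seed = 123)
  expect_identical(visitCounts(sampleWalks(g, cfg2)),
                   visitCounts(sampleWalks(g, cfg2)))
})

test_that("visit totals hit the restarts x steps budget iff nothing dangles", {
  set.seed(78)
  gFull <- GCMap(1 - diag(3))               # complete graph, no dangling
  o <- sampleWalks(gFull, walkConfig(restarts = 30, maxSteps = 20, seed = 1))
  expect_equal(sum(visitCounts(o)), 30 * 20)
  expect_equal(o@truncatedRestarts, 0L)

  w <- 1 - diag(4); w[2, ] <- 0             # node 2 dangles
  o2 <- sampleWalks(GCMap(w), walkConfig(restarts = 50, maxSteps = 20, seed = 2))
  expect_lt(sum(visitCounts(o2)), 50 * 20)
  expect_gt(o2@truncatedRestarts, 0L)
  expect_equal(o2@completedRestarts + o2@truncatedRestarts, 50L)
})

test_that("reverse-direction sampling equals forward sampling of the reversed map", {
  set.seed(79)
  g <- randomGCMap(7, density = 0.5)
  oRev <- sampleWalks(g, walkConfig(restarts = 80, maxSteps = 40,
                                    direction = "reverse", seed = 11))
  oFwd <- sampleWalks(reverseEdges(g),
                      walkConfig(restarts = 80, maxSteps = 40, seed = 11))
  expect_identical(visitCounts(oRev), visitCounts(oFwd))
})

test_that("reverse-direction sampling favours planted high-outdegree hubs", {
  set.seed(80)
  wins <- vapply(1:20, function(r) {
    sim <- genPatient(synthConfig(nNodes = 30, nSoz = 5, nSegments = 1,
                                  hubOutMultiplier = 3, seed = 1000 + r))
    g <- segments(sim$record)[[1]]
    o <- sampleWalks(g, walkConfig(restarts = 300, maxSteps = 100,
                                   direction = "reverse", seed = r))
    counts <- visitCounts(o)
    hubs <- sim$hubs
    mean(counts[hubs]) > mean(counts[setdiff(names(counts), hubs)])
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("empty graphs and invalid configs are rejected", {
  expect_error(sampleWalks(GCMap(matrix(0, 0, 0)), walkConfig()),
               class = "gcnetDataError")
  expect_error(walkConfig(restarts = 0), "restarts")
  expect_error(sampleWalks(twoCycle(),
                           walkConfig(metric = "interval", tokens = 2)),
               class = "gcnetConfigError")
})
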