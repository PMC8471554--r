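# Rank-order-sum statistic, Monte Carlo null, patient-level evaluation.

test_that("rankOrderSum adds the target midranks", {
  r <- nodeRankingFromMetric(c(a = 9, b = 7, c = 3, d = 1), "m")
  expect_equal(rankOrderSum(r, c("a", "b")), 3)
  expect_equal(rankOrderSum(r, c("c", "d")), 7)
  expect_equal(rankOrderSum(r, c("a", "b", "c", "d")), 10)  # N(N+1)/2
  expect_error(rankOrderSum(r, character()), class = "gcnetConfigError")
  expect_error(rankOrderSum(r, "zz"), class = "gcnetDataError")
})

test_that("simulateNull reproduces the exact moments of the rank-sum null", {
  nd <- simulateNull(100, 20, repetitions = 2e4, seed = 1)
  m <- nullMoments(nd)
  exactMean <- 20 * 101 / 2
  exactSd <- sqrt(20 * 80 * 101 / 12)
  seMean <- exactSd / sqrt(2e4)
  expect_lt(abs(m["mean"] - exactMean), 3 * seMean)
  expect_lt(abs(m["sd"] - exactSd) / exactSd, 0.05)
})

test_that("degenerate and replacement nulls behave as forced", {
  nd <- simulateNull(6, 6, repetitions = 50, seed = 2)
  expect_true(all(nullSums(nd) == 21))
  expect_equal(unname(nullMoments(nd)["sd"]), 0)
  expect_error(simulateNull(5, 6, 10), class = "gcnetConfigError")
  ndr <- simulateNull(5, 6, repetitions = 100, seed = 3, replacement = TRUE)
  expect_equal(ndr@repetitions, 100L)
  expect_true(all(nullSums(ndr) >= 6 & nullSums(ndr) <= 30))
})

test_that("the simulated null matches exhaustive enumeration at N = 8, k = 3", {
  exact <- oracleNullSums(8, 3)
  nd <- simulateNull(8, 3, repetitions = 2e4, seed = 4)
  lev <- sort(unique(exact))
  obs <- table(factor(nullSums(nd), levels = lev))
  p <- as.numeric(table(factor(exact, levels = lev))) / length(exact)
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("evaluateRanking flags extreme placements and is calibrated at the mean", {
  metric <- setNames(seq(40, 1), paste0("e", 1:40))
  r <- nodeRankingFromMetric(metric, "m")
  best <- evaluateRanking(r, paste0("e", 1:5), repetitions = 5000, seed = 5)
  expect_lt(pValue(best), 0.05)
  expect_true(isSignificant(best))
  # a target set whose sum sits exactly at the null mean: k (N+1)/2
  mid <- evaluateRanking(r, c("e10", "e31"), method = "closed_form")
  expect_equal(observedSum(mid), 2 * 41 / 2)
  expect_equal(pValue(mid), 0.5, tolerance = 0.01)
})

test_that("the three p-value methods broadly agree away from the tails", {
  metric <- setNames(seq(30, 1), paste0("e", 1:30))
  r <- nodeRankingFromMetric(metric, "m")
  targets <- c("e3", "e9", "e14", "e22")
  ps <- vapply(c("mc_normal", "mc_empirical", "closed_form"), function(m) {
    pValue(evaluateRanking(r, targets, repetitions = 2e4, seed = 6,
                           method = m))
  }, numeric(1))
  expect_lt(max(ps) - min(ps), 0.02)
})

test_that("p-values decrease monotonically as the observed sum decreases", {
  metric <- setNames(seq(25, 1), paste0("e", 1:25))
  r <- nodeRankingFromMetric(metric, "m")
  sets <- list(c("e1", "e2"), c("e5", "e8"), c("e10", "e15"), c("e20", "e25"))
  ps <- vapply(sets, function(tg) {
    pValue(evaluateRanking(r, tg, method = "closed_form"))
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("random targets under a random ranking reject at roughly the alpha rate", {
  set.seed(301)
  nTrials <- 400
  rejects <- vapply(seq_len(nTrials), function(i) {
    metric <- setNames(runif(50), paste0("e", 1:50))
    r <- nodeRankingFromMetric(metric, "m")
    tg <- sample(names(metric), 10)
    isSignificant(evaluateRanking(r, tg, method = "closed_form"))
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / nTrials)
  expect_lt(abs(mean(rejects) - 0.05), 3 * se)
})

test_that("evaluatePatient recovers planted hubs and respects empty RZs", {
  set.seed(302)
  sim <- genPatient(synthConfig(nNodes = 50, nSoz = 10, nSegments = 10,
                                hubOutMultiplier = 3, rzAdd = 0, seed = 7))
  res <- evaluatePatient(sim$record, "outdegree", repetitions = 5000,
                         seed = 8)
  expect_true(isSignificant(res$soz))
  expect_true(isSignificant(res$rz))   # rz == soz when rzAdd = rzRemove = 0

  noRz <- PatientRecord(segments(sim$record), soz = sozLabels(sim$record))
  res2 <- evaluatePatient(noRz, "outdegree", repetitions = 2000, seed = 8)
  expect_null(res2$rz)
  expect_error(evaluatePatient(sim$record, "no-such-algorithm"),
               class = "gcnetConfigError")
})

test_that("map-aggregation and metric-aggregation both expose strong hubs", {
  set.seed(303)
  sim <- genPatient(synthConfig(nNodes = 40, nSoz = 8, nSegments = 8,
                                hubOutMultiplier = 3, seed = 9))
  pm <- evaluatePatient(sim$record, "gc-outdegree", aggregate = "metrics",
                        repetitions = 3000, seed = 10)
  pa <- evaluatePatient(sim$record, "gc-outdegree", aggregate = "map",
                        repetitions = 3000, seed = 10)
  expect_true(isSignificant(pm$soz))
  expect_true(isSignificant(pa$soz))
  # gc-outdegree metric commutes with elementwise-mean aggregation, so the
  # two policies give identical rankings for this algorithm
  expect_equal(nodeRanks(pm$ranking), nodeRanks(pa$ranking))
})

test_that("the full patient pipeline is deterministic given seeds", {
  set.seed(304)
  sim <- genPatient(synthConfig(nNodes = 30, nSoz = 6, nSegments = 4,
                                seed = 11))
  r1 <- evaluatePatient(sim$record, "walk-count", restarts = 100,
                        maxSteps = 50, repetitions = 2000, seed = 12)
  r2 <- evaluatePatient(sim$record, "walk-count", restarts = 100,
                        maxSteps = 50, repetitions = 2000, seed = 12)
  expect_identical(pValue(r1$soz), pValue(r2$soz))
  expect_identical(nodeRanks(r1$ranking), nodeRanks(r2$ranking))
})
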