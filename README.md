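# gcnetrank

Graph-algorithm ranking of Granger-causality (GC) networks for epileptic
zone localization.

## What problem this solves, and for whom

Planning epilepsy surgery requires identifying the seizure onset zone
(SOZ): the set of intracranial electrodes overlying the tissue that
originates seizures.  The clinical standard derives the SOZ (and the
eventually resected zone, RZ) from invasive monitoring of seizures
themselves.  A complementary research program asks how much of that
information is already present in *interictal* recordings: pairwise Granger
causality between electrode signals turns each recording segment into a
directed weighted graph — a **GC map** — whose edge `i → j` measures how
strongly activity at electrode `i` predicts subsequent activity at
electrode `j`.  If epileptogenic tissue is an unusually *causal* part of
this network, graph-importance rankings should place SOZ/RZ electrodes
early.

`gcnetrank` is for researchers working on iEEG network analysis who want a
tested, reproducible implementation of that pipeline:

* **GC stage** — bivariate time-domain Granger causality with F-test edge
  pruning (`pairwiseGC()`, `significanceFilter()`);
* **graph model** — the `GCMap` container (rows = source electrodes,
  columns = targets), CSV I/O, edge reversal, row-normalization,
  per-patient collections with SOZ/RZ label sets (`readGCMap()`,
  `reverseEdges()`, `readPatient()`);
* **rankings** — Monte Carlo random-walk sampling with reversed-edge,
  revisit-interval and multi-token variants (`sampleWalks()`); weighted
  PageRank with explicit dangling-node handling (`pageRank()`, plus the
  hand-checkable undamped update `pageRankDidactic()`); betweenness,
  harmonic and in/outdegree centrality; the total-GC-outdegree baseline;
* **validation statistic** — the rank-order sum with Monte Carlo and
  closed-form nulls (`evaluateRanking()`, `evaluatePatient()`,
  `runCohort()`);
* **synthetic data** — generators of GC maps and VAR time series with
  planted causal hubs (`genPatient()`, `genVARSegment()`), so the whole
  pipeline can be exercised and calibrated without patient data.

## The statistic at the core

Each algorithm assigns every node a metric and hence a rank
`r(n) ∈ [1, N]` (rank 1 = most important; ties get midranks, so ranks
always sum to `N(N+1)/2`).  A ranking is validated against a clinical
label set `Z` (SOZ or RZ, `|Z| = k`) through the **rank-order sum**

    S = Σ_{n ∈ Z} r(n).

Under the null of an uninformative ranking, `S` is the sum of `k` of `N`
distinct ranks drawn at random:

    E[S] = k(N+1)/2,   Var[S] = k(N−k)(N+1)/12.

The package simulates this null (default 10^5 draws without replacement),
fits a normal, and reports the one-sided lower-tail `P(S ≤ S_obs)`: a
significantly *small* sum means the algorithm concentrates the clinical
nodes at the top of its ranking.  Empirical-tail and closed-form methods
are available (`method = "mc_empirical"` / `"closed_form"`).

## Worked example

Simulate a 100-electrode patient with 20 planted causal-hub electrodes
(the ground-truth SOZ) across 60 interictal segment maps, rank electrodes
by outdegree centrality, and test the SOZ and RZ rank-order sums:

```r
library(gcnetrank)

sim <- genPatient(synthConfig(nNodes = 100, nSoz = 20, nSegments = 60,
                              hubOutMultiplier = 3, seed = 11))
rec <- sim$record
rec
#> PatientRecord: 100 nodes, 60 segment maps, |SOZ| = 20, |RZ| = 22

res <- evaluatePatient(rec, "outdegree", repetitions = 1e5, seed = 11)
res$soz
#> RankOrderResult: sum = 210.0 over k = 20 of N = 100 nodes
#>   null mean = 1010.3, sd = 116.29 (mc_normal); p = 2.95e-12 (significant at alpha = 0.05)
res$rz
#> RankOrderResult: sum = 386.0 over k = 22 of N = 100 nodes
#>   null mean = 1110.8, sd = 120.18 (mc_normal); p = 8.17e-10 (significant at alpha = 0.05)
```

Reading the output: the 20 SOZ electrodes received rank sum 210 — close to
the best attainable `20·21/2 = 210` — against a null expectation of about
1010 (sd ≈ 116), so the probability of a sum this small by chance is
~3 × 10⁻¹². Here the top of the ranking recovers the planted hub set
exactly:

```r
length(intersect(topK(res$ranking, 20), sozLabels(rec)))
#> [1] 20
```

The same evaluation runs over real data through patient manifests
(`readPatient("patient01/manifest.json")`), over raw time series through
`pairwiseGC()` + `significanceFilter()`, and over whole cohorts through
`runCohort()`, which replicates stochastic algorithms with derived seeds
and reports the mean ± SE count of patients with significant rank-order
sums.  A thin command-line front end covering
`simulate / gc / walk / rank / evaluate / cohort` is installed at
`inst/scripts/gcnet.R`.

See the methods vignette (`vignettes/gcnetrank-methods.Rmd`) for the model
assumptions, parameter defaults and their rationale, and known
limitations.

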