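---
title: "Ranking epileptic-network nodes on Granger-causality maps: methods and design"
author: "gcnetrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking epileptic-network nodes on Granger-causality maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnetrank)
```

## The problem

Epilepsy surgery planning asks which intracranial electrodes sit over the
tissue that originates seizures.  The clinical gold standards — the
neurologist-determined seizure onset zone (SOZ) and the surgically removed
resection zone (RZ) — come from invasive monitoring of ictal (seizure)
events.  A complementary line of work asks how much can be read off
*interictal* (between-seizure) recordings alone: pairwise Granger causality
(GC) between electrode signals turns each recording segment into a directed,
weighted graph — a *GC map* — in which an edge $i \to j$ carries the degree
to which activity at electrode $i$ statistically predicts subsequent
activity at electrode $j$.  The hypothesis is that the epileptogenic
electrodes are unusually *causal* nodes of this graph, so graph-theoretic
importance rankings should place SOZ/RZ electrodes early.

`gcnetrank` implements that pipeline end to end:

1. **granger** — bivariate time-domain GC on a channels × samples segment,
   with per-edge F-test pruning (`pairwiseGC()`, `significanceFilter()`);
2. **gcmap** — the `GCMap` graph container, file I/O, edge reversal,
   row-normalization, aggregation (`readGCMap()`, `reverseEdges()`,
   `toTransition()`, `aggregateMaps()`);
3. **walkers** — Monte Carlo random-walk node sampling with reversed-edge,
   revisit-interval and multi-token variants (`sampleWalks()`);
4. **ranking** — weighted PageRank, betweenness, harmonic, in/outdegree
   centrality and the total-GC-outdegree baseline (`pageRank()`,
   `betweennessCentrality()`, ...);
5. **stats** — the rank-order-sum statistic with Monte Carlo and
   closed-form nulls (`rankOrderSum()`, `evaluateRanking()`,
   `evaluatePatient()`);
6. **synthetic** — generators of GC maps and VAR time series with planted
   causal-hub structure (`genPatient()`, `genVARSegment()`), so every stage
   is testable without patient data;
7. **cohort** — multi-patient evaluation with replicate runs for stochastic
   algorithms (`runCohort()`), plus a thin command-line front end
   (`inst/scripts/gcnet.R`).

Matrix orientation is fixed throughout: rows are sources, columns targets,
`weights[i, j]` = influence of `i` on `j`.  `reverseEdges()` transposes a
map, both to accommodate input files of the opposite convention and as a
scientific variant: on the reversed map, walkers and centrality mass travel
"uphill" toward the *generators* of activity rather than its receivers.

## Granger stage

For each ordered channel pair $(i, j)$ we compare two nested least-squares
autoregressions of $x_j$ with $p$ lags: restricted (own lags only) and full
(own lags plus $p$ lags of $x_i$).  The GC magnitude is the Geweke log
variance ratio

$$\mathrm{gc}_{i \to j} = \ln \frac{\mathrm{RSS}_r}{\mathrm{RSS}_f} \ge 0,$$

and edges are pruned with the nested-model F statistic
$F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_f)/p}
          {\mathrm{RSS}_f/(T_{\mathrm{eff}} - 2p - 1)}$
on $(p,\; T_{\mathrm{eff}} - 2p - 1)$ degrees of freedom,
$T_{\mathrm{eff}} = T - p$.  Design choices:

* **Bivariate, not conditional** GC: each pair is assessed in isolation.
  Conditional (multivariate) GC would partial out the other channels and is
  a deliberate non-goal; the interpretation of the maps changes
  accordingly (common-driver effects are not removed).
* **Per-edge alpha** (default 0.05) with no multiplicity correction by
  default, because the downstream graph statistics are designed around maps
  pruned at a fixed per-edge level; `bonferroni = TRUE` is available.
* **Mean removal only**; no detrending, filtering or artifact handling —
  preprocessing belongs upstream of this package.
* **Model order** is caller-supplied (default 10, a common choice for
  iEEG sampled at clinical rates); `selectOrder()` offers an AIC-based
  selection over 1..20 when no prior fixes it.  Degenerate fits (constant
  channels, rank-deficient designs) yield `gc = 0` with a warning rather
  than an error, so one dead channel does not abort a segment.

## Random-walk sampling

A restart places a token on a uniformly random node (that placement counts
as the first visitation); the token then repeatedly moves to a successor
drawn with probabilities proportional to the current node's outgoing
weights (`toTransition()` row-normalizes; rows summing to zero are
*dangling*).  A restart ends after `maxSteps` visitations (default 1000) or
when the token reaches a dangling node — dangling rows are deliberately
*not* patched with uniform jump probabilities, because chain termination at
F-test-silenced nodes is part of the method's semantics.  Visit counts are
accumulated over `restarts` chains (default 1000).

Variant semantics and the choices behind them:

* **Revisit intervals** (`metric = "interval"`): the gap between successive
  visits of a node within one chain, counted inclusively of the return step
  — a visit, three other nodes, then a revisit records an interval of 4.
  Intervals never carry over a restart.  Nodes revisited in no chain have
  an *undefined* mean interval and are ranked last: a node that is never
  revisited shows no evidence of the cyclic involvement this metric is
  meant to detect.
* **Multi-token** (`tokens = k`): $k$ tokens start at independent uniform
  nodes and move synchronously, each by its own draw; a visitation is
  recorded only when all $k$ occupy the same node.  Defaults: $k = 2$; the
  synchronized start configuration is itself checked for coincidence; a
  step that lands a token on a dangling node still counts for coincidence
  before the chain terminates.  These last two conventions are this
  package's choices where reasonable alternatives exist.
* **Determinism**: one seeded generator per run, draws consumed in a fixed
  documented order (all start nodes first, then one uniform per active
  chain per step, token by token).  Same seed and configuration give
  bit-identical outcomes, and reverse-direction sampling is routed through
  `reverseEdges()` into the identical code path, so it is bit-identical to
  forward sampling of the transposed map.

The implementation advances all restarts as one vectorized cohort (one
inverse-CDF lookup per step across active chains), which is what makes
1000 × 1000 sampling runs practical in pure R.

## PageRank, twice

Two operations share the name deliberately, because one update rule cannot
be both convergent and hand-checkable:

* `pageRank()` is the production algorithm: damped (default 0.85),
  weighted — each node's score flows out proportionally to its outgoing
  weights — normalized to sum to one, iterated to an L1 tolerance of 1e-8
  (at most 200 iterations; non-convergence is an error carrying the last
  iterate).  The dangling rule is that a node with no outgoing edges
  shares its score evenly over all *other* nodes — note this excludes the
  node itself, which is why the power iteration is implemented here rather
  than delegated to a graph library whose teleport-style dangling handling
  includes it.
* `pageRankDidactic()` is the undamped, unnormalized synchronous
  mass-transfer update (every node transfers its whole score each
  iteration; total mass conserved exactly).  Its first iterations on a
  3-node example are the package's hand-verifiable reference computation;
  it is not meant for ranking.

## Centralities and distances

Betweenness and harmonic centrality use the inverse-weight distance
dialect: the length of an edge is $1/w$, so a stronger GC edge is a
shorter path.  Betweenness counts, for each node, the fraction of
all-pairs shortest directed paths passing through it (ties included);
harmonic centrality of $n$ is $\sum_{p \ne n} (1/L_{pn})/(N-1)$ with
distances measured *into* $n$ by default (how easily activity reaches
$n$; `mode = "out"` for the outward reading) and unreachable pairs
contributing zero.  Both are computed through `igraph`; the test suite
checks them against an exhaustive simple-path enumeration oracle on small
random digraphs, using graphs whose edge distances are small integers so
that shortest-path ties are exact in floating point rather than
tolerance-dependent.

Degree centralities *count* surviving edges rather than summing weights —
after F-test pruning, the sheer number of significant edges is a signal
distinct from the weighted total — while `totalGCOutdegree()` (the row
sums) is retained as the literature baseline; `weighted = TRUE` bridges
the two.  All rankings assign midranks to ties, so every ranking sums to
$N(N+1)/2$ and downstream sums are invariant to node order; `topK()`
breaks boundary ties lexicographically, and that rule is documented
rather than meaningful.

## The rank-order-sum statistic

A ranking is validated against a clinical label set by summing the ranks
it assigns to the set's nodes.  Under the null of an uninformative
ranking, the sum of $k$ of $N$ distinct ranks has

$$E[S] = \frac{k(N+1)}{2}, \qquad
  \mathrm{Var}[S] = \frac{k(N-k)(N+1)}{12},$$

the classical sampling-without-replacement (Wilcoxon) moments.  The
default evaluation simulates the null ($10^5$ draws of $k$ ranks without
replacement), fits a normal, and reports the one-sided lower-tail
$P(S \le S_{\mathrm{obs}})$ — a small sum means the target nodes are
ranked early.  Drawing *without* replacement is the faithful null because
real node ranks are distinct; a with-replacement flag reproduces the
looser reading of "selecting $k$ integers from $\{1..N\}$".  Alternatives:
`method = "mc_empirical"` uses the empirical tail
$(\#\{S_{\mathrm{null}} \le S_{\mathrm{obs}}\} + 1)/(\mathrm{reps} + 1)$
and is preferable at small $N$ where the normal fit is rough;
`method = "closed_form"` skips simulation entirely.  The significance
level defaults to 0.05 and is configurable everywhere it appears.

Per-patient evaluation must combine 60 per-segment maps.  Two policies are
provided because the combine step is genuinely open: the default ranks
every segment and averages the per-node *metrics* (preserving each
segment's pruning-induced sparsity, and averaging away per-segment
sampling noise); the alternative averages the *maps* elementwise and ranks
once.  For linear metrics (total GC outdegree) the two coincide exactly;
for nonlinear ones (PageRank, betweenness) they need not.

## The synthetic generator

`genPatient()` emulates what per-segment GC maps look like *after* F-test
pruning: sparse directed graphs in which a planted subset of nodes (the
ground-truth epileptogenic set) has both more and heavier outgoing edges.
Defaults are the package's fixed study conditions: 100 nodes with 20
planted hubs and 60 segments per patient (typical subdural-grid monitoring
scale); background edge probability 0.05, matching the per-edge F-test
level that generates background edges under the null — this also
reproduces the empirical feature that many nodes end up with no outgoing
edges at all and dangle; exponential edge weights (mean 1), a minimal
right-skewed nonnegative choice for unitless GC magnitudes, as a modelling
decision rather than an empirical claim; hub out-multiplier 3 as the
"strong effect" setting, scaling both hub edge probability and mean hub
edge weight; and an RZ formed from the SOZ by adding 2 non-hub nodes
(clinical resections are typically slightly larger than, and not identical
to, the onset zone).  `genVARSegment()` provides the matching time-series
substrate: a stable VAR with diagonal self-decay 0.5, planted lag-1 cross
coefficients (default 0.5), unit innovations, spectral-radius check with
rescaling, and a 200-sample burn-in.

What the generator does **not** emulate — and therefore what passing tests
do not show about clinical data: volume conduction and common reference
effects, non-stationarity and state changes across segments, spatially
correlated noise, electrode geometry, and any realistic neural dynamics
(edges are independent across segments given the hub set).  Recovery
results here demonstrate algorithmic correctness and statistical
calibration, not clinical performance.

## Numerical and testing choices

* PageRank: L1 tolerance 1e-8, 200 iterations, dense power iteration —
  maps at electrode scale ($N \approx 100$) are small and dense enough
  that sparse machinery would be noise.
* Walk sampling draws successors by inverse-CDF lookup on row-cumulative
  probabilities, with each row rescaled so its final entry is exactly 1.
* Degenerate cases are decided, not left to chance: empty target sets and
  unknown labels are errors; a ranking over an edgeless map gives all-tied
  midranks $(N+1)/2$; `simulateNull(n, n)` has sd 0 and the normal-tail
  p-value at a zero-sd null is 0/0.5/1 by sign.
* Seeds: every stochastic operation takes an explicit seed;
  pipeline stages derive per-stage seeds from a global seed and a stage
  tag via a stable string hash (`deriveSeed()`), so adding a patient to a
  cohort does not change any other patient's stream.  Seeded operations
  restore the caller's RNG state on exit.
* Test problem sizes are chosen to keep the full suite fast while leaving
  Monte-Carlo assertions well-powered: walker frequency checks use 2000
  restarts × 500 steps on 3–5-node ergodic graphs against an exact
  propagated-occupancy oracle; the null-distribution checks use $10^5$
  repetitions; end-to-end hub recovery uses 50 patients per effect level
  at the full 100-node × 60-segment scale with $10^4$-repetition nulls.

## Known limitations

* Bivariate GC inherits all caveats of pairwise predictive "causality":
  common drivers and indirect paths create edges a conditional analysis
  would remove.
* The F-pruning threshold interacts with segment length and model order;
  rankings are comparable across patients only when those are held fixed.
* The rank-order-sum validates *rankings*, not clinical decisions: turning
  a ranking into a proposed resection set (beyond the trivial `topK()`) is
  intentionally out of scope.
* Pure-R walk sampling is vectorized but still $O(\mathrm{restarts}
  \times \mathrm{steps})$ memory-light loop work; very large
  configurations (e.g. $10^4 \times 10^4$) take minutes, not seconds.
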