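---
title: "Methods: weighted connectome analysis of sleep-deprivation vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome analysis of sleep-deprivation vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdnet)
```

## The scientific question

Some people tolerate a night of total sleep deprivation with little loss of
vigilance; others accumulate many psychomotor vigilance task (PVT) lapses
(reaction times ≥ 500 ms). `sdnet` implements a structural-connectome account
of that difference for a two-group design — *vulnerable* (n = 25) versus
*resistant* (n = 24) subjects classified by their lapse increase — in which
each subject contributes a weighted white-matter network: 90 parcellated grey
matter regions, edge weights equal to the number of tractography streamlines
connecting each pair, thresholded at 10 streamlines to suppress
false-positive connections.

The working hypothesis is topological: the brain's *rich club* — the densely
interconnected set of high-degree hub regions that carries a disproportionate
share of long-range integration — is the substrate whose connection strength
separates the groups, and whose weakness predicts lapsing.

## Network construction and metrics

Edges are streamline counts; an edge with fewer than `t` streamlines is set
to zero (`apply_fiber_threshold()`, inclusive rule: exactly `t` survives,
`t = 0` keeps all positive edges). A region-size control divides each weight
by the mean volume of its two endpoint regions
(`roi_volume_correction()`); thresholding is applied to raw counts *before*
volume correction, because the count threshold is a minimum-evidence rule on
the tractography itself. The two operations do not commute; the test suite
demonstrates a counterexample.

Weighted distances use the reciprocal length map `l_ij = 1 / w_ij` — the
standard convention for streamline-count weights, making stronger connections
shorter. All path-based metrics run on the dense all-pairs shortest-path
matrix (Floyd–Warshall, implemented in C++ since a 90-node dense matrix makes
the O(N³) scan both simplest and fastest):

* network strength `Sp`: mean node strength;
* global efficiency `Eglob`: mean inverse shortest distance over ordered
  pairs (unreachable pairs contribute 0);
* nodal efficiency `E_nodal(i)`: the per-node version; its mean equals
  `Eglob` exactly;
* local efficiency `Eloc`: mean over nodes of the efficiency of each node's
  neighbour subgraph (node excluded, weights retained; degree < 2 gives 0);
* characteristic path length `Lp`: mean distance over ordered pairs. The
  design assumes connected networks; disconnected synthetic edge cases are
  averaged over finite pairs with a warning (configurable to an error);
* clustering `Cp`: Onnela's geometric-mean formula on weights normalised by
  the per-subject maximum, bounded in [0, 1].

Small-world coefficients normalise against an ensemble of degree-preserving
rewired null networks (`matched_ensemble()`): `gamma = Cp / mean(Cp_rand)`,
`lambda = Lp / mean(Lp_rand)`. Each null is produced by double-edge swaps (10
attempts per edge, a standard mixing heuristic) followed by a random
permutation of the original weights over the rewired edge set, so both the
exact degree sequence and the weight multiset are preserved — the strongest
reading of "matched" available without a strength-sequence-preserving model,
which is out of scope.

## Rich-club pipeline

1. **Backbone.** For each group, an edge enters the group backbone when a
   one-tailed sign test rejects a zero median weight across subjects. With
   zeros dropped, all `m` positive observations lie above zero, so the exact
   tail probability is `0.5^m`; this closed form is the only one-tailed sign
   test against zero for nonnegative data. The p-values are corrected across
   all N(N−1)/2 candidate pairs — Benjamini–Hochberg by default (the
   procedure the rest of the analysis uses), Bonferroni by option.
2. **Hubs.** Nodes whose backbone degree is at least one sample standard
   deviation above the mean backbone degree. A regular graph (sd = 0)
   trivially admits every node; the rule is taken literally with a warning.
3. **Edge classes.** Rich (hub–hub), feeder (hub–periphery), local
   (periphery–periphery); class strengths are weight sums and conserve the
   total weight exactly.
4. **Weighted rich-club coefficient.** With `n` the number of hub–hub edges,
   `phi` = (sum of hub–hub weights) / (sum of the `n` strongest weights
   network-wide, hub–hub edges included in the pool). Ties at the n-th
   strongest weight are irrelevant to the sum. `phi_norm` divides by the mean
   `phi` of the matched nulls; values above 1 indicate rich-club organisation
   beyond what the degree sequence explains.

Hub identification is a group-level decision (the backbone), but `phi` and
the class strengths are computed per subject with the subject's own weights
under the group hub set — the group comparison and the behavioural
correlation need subject-level quantities.

## Network-based statistic

Edge-wise pooled two-sample t statistics (resistant − vulnerable) are
computed on the union of the two group backbones, thresholded one-tailed at
the t value corresponding to edge-wise p < 0.01 (the direction fixed to
"decreased in the vulnerable group"). Connected components of the
supra-threshold graph are the candidate subnetworks; their family-wise error
is controlled by permuting group labels and recording the maximal component
size (in edges) each time, with the add-one estimate
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`. The primary threshold and
permutation count are exposed in `analysis_config()` since no canonical
values exist.

## Group and behavioural statistics

Pooled-variance Student t (df = 47 at the design's group sizes) is the
default two-sample test — it reproduces published mean ± SD tables exactly,
which Welch does not; Welch-style analyses can be built from the raw samples
if needed. The 2×2 chi-square is uncorrected (again matching the printed
worked example). Lapse counts are compared by the rank-sum Z test with
midranks and tie-corrected variance, because lapse counts are overdispersed,
skewed and zero-inflated. Spearman correlations use midranks with the
t-approximation for p (adequate at n = 49; exact enumeration is
unnecessary). FDR correction is Benjamini–Hochberg, applied across the 90
regions within one nodal-efficiency analysis.

## The synthetic cohort generator

No imaging data ship with the package; `generate_cohort()` produces cohorts
whose qualitative structure matches what the pipeline is designed to detect.

* **Topology** (shared template per cohort): a planted-hub stochastic block
  model on 90 nodes. Twelve hubs connect to each other with probability 0.9,
  to the periphery with 0.2; peripheral pairs connect with mean probability
  0.08, concentrated on nearby region indices with an exponential decay
  (scale 8 indices). The locality term emulates the distance-dependent
  connection probability of cortical networks and is what gives the networks
  clustering above degree-matched nulls (gamma > 1); a pure block model has
  essentially none. Overall density lands near 0.12, typical of
  streamline-count networks thresholded at 10. Disconnected samples are
  repaired with random bridging edges because every path-based metric
  assumes finite distances.
* **Weights**: per-edge log-normal baselines (median 30 streamlines, log-SD
  0.9), shared across subjects, times per-subject multiplicative log-normal
  noise (log-SD 0.25), rounded to integers. Hub–hub baselines are enriched
  by a factor of 3: rich-club edges in real structural networks carry the
  strongest connections, and without a topology–weight coupling the
  weight-permuting null would reproduce the observed coefficient
  (phi_norm ≈ 1).
* **Planted group difference**: vulnerable subjects' hub–hub weights are
  attenuated by `delta_rich` (default 0.6) before rounding — a deficit
  specific to rich-club connections, leaving feeder and local edges
  untouched.
* **Behaviour**: lapse counts are negative binomial (dispersion 3, which
  reproduces the overdispersion of the design's lapse summaries, 9.56 ± 5.96
  vs 0.54 ± 1.06). The post-deprivation log-mean is the group baseline plus
  `behavior_link_slope` (default −0.5) times the subject's *within-group*
  standardised rich-club strength, with a `−slope²/2` correction so the
  group means stay at their configured baselines. Within-group
  standardisation matters: cohort-wide z-scores absorb the planted group
  difference and inflate the vulnerable group's mean by ~20%.
  Rested-wakefulness counts are drawn at a common baseline of 1.
* **Reproducibility**: one seed governs the cohort; each subject's RNG
  stream is derived from (seed, subject index), so individual subjects are
  bit-reproducible independent of group sizes.

What the generator does *not* emulate: spatial geometry beyond index
locality, hemispheric symmetry, distance-dependent weight decay, tractography
biases (gyral bias, crossing fibres), or any physiological model of sleep
pressure. Passing tests therefore certify the statistical machinery — that
the pipeline recovers a planted rich-club deficit at realistic sample sizes
and noise levels, and stays at its nominal error rate without one — not that
the biological claims hold in new imaging data.

## Numerical and design choices

* Asymmetry tolerance on input matrices: 10⁻⁶ relative; smaller asymmetries
  are averaged, larger ones are errors. Nonzero diagonals are zeroed with a
  warning.
* Inclusive threshold semantics (`w ≥ t` survives) make the threshold a
  minimum-evidence rule and `t = 0` the keep-all-nonzero limit; an exclusive
  reading would differ only on ties at exactly `t`.
* Unreachable pairs contribute 0 to efficiency; `Lp` over finite pairs with
  a warning. Degenerate hub rules, undefined ratios (zero denominators) and
  undefined `phi` (no hub–hub edge) are flagged, never silently dropped.
* Skewness is the bias-corrected sample form.
* Problem sizes in the shipped analyses: 200 matched nulls per subject for
  `phi_norm`, 100-network ensembles for gamma/lambda, 500–2000 NBS
  permutations — chosen so a complete desk run of every analysis finishes in
  minutes while keeping Monte-Carlo error well inside the decision margins;
  all are single-argument changes for larger runs (the full design uses
  1000 nulls).

## Worked check against published summaries

The statistical layer is validated against printed group summary tables:
recomputing the pooled t for the insula nodal-efficiency row
(235.0 ± 46.9, n = 24 vs 184.4 ± 42.4, n = 25) returns

```{r}
pooled_t_from_summary(235.0, 46.9, 24, 184.4, 42.4, 25)
```

matching the printed 3.967 to input rounding, and the gender table gives

```{r}
chi_square_2x2(gender_table()$table)
```

## Known limitations

* The sign-test backbone treats subjects as exchangeable; no covariates.
* Null networks preserve degrees and the weight multiset but not node
  strengths; a strength-preserving null would be stricter for weighted
  rich-club inference.
* The NBS contrast is a two-group pooled t without covariate adjustment.
* Subject noise is independent per edge, so it averages out of
  network-level sums; between-subject variance of the global metrics is
  therefore optimistic and the planted group differences yield much larger
  t values than real cohorts (tens rather than 2–4). The generator has no
  per-subject global scaling term; power conclusions transfer
  qualitatively, not numerically.
* The vulnerable/resistant cutoff in real designs is a substantive choice;
  `classify_vulnerability()` offers a median split and a fixed cutoff without
  asserting either is canonical, and at the generator's realistic lapse
  dispersions a median split misassigns a few boundary subjects (recovery
  0.86–0.94 across seeds).
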