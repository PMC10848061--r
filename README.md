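# sdnet — structural connectome analysis of vulnerability to sleep deprivation

`sdnet` is an R package and analysis workflow for a two-group structural
brain-network study: subjects classified as **vulnerable** or **resistant**
to total sleep deprivation by their increase in psychomotor vigilance task
(PVT) lapses, each contributing a weighted white-matter connectome — an
N × N matrix of tractography streamline counts between parcellated regions
(90 AAL-style regions in the reference design, n = 25 / 24).

It is written for researchers who want the full group-comparison pipeline
behind such studies as tested, reusable functions:

* **Network construction** — plain-text matrix I/O, fiber-count thresholding
  (w<sub>ij</sub> ≥ t, default t = 10), region-volume correction
  (w′<sub>ij</sub> = w<sub>ij</sub> / ((v<sub>i</sub>+v<sub>j</sub>)/2)),
  BrainNet Viewer `.node`/`.edge` export.
* **Weighted graph metrics** — strength S<sub>p</sub>, global efficiency
  E<sub>glob</sub> = ⟨1/d<sub>ij</sub>⟩, local and nodal efficiency,
  characteristic path length L<sub>p</sub>, Onnela weighted clustering
  C<sub>p</sub>, and small-world coefficients γ = C<sub>p</sub>/⟨C<sub>p</sub><sup>rand</sup>⟩,
  λ = L<sub>p</sub>/⟨L<sub>p</sub><sup>rand</sup>⟩ against degree-preserving
  rewired nulls (distances use edge lengths 1/w<sub>ij</sub>).
* **Rich club** — group backbone by one-tailed sign test (p = 0.5<sup>m</sup>,
  FDR-corrected), hubs at degree ≥ mean + 1 SD, rich/feeder/local edge
  classes, and the weighted rich-club coefficient
  φ = Σ w<sub>hub–hub</sub> / Σ (n strongest weights), normalised by matched
  random networks (φ<sub>norm</sub> > 1 ⇒ rich-club organisation).
* **Network-based statistic (NBS)** — edge-wise pooled t, one-tailed primary
  threshold, max-component permutation null with family-wise error control.
* **Group/behavioural statistics** — pooled two-sample t (from raw samples or
  from printed mean ± SD summaries), uncorrected 2×2 χ², rank-sum Z with tie
  correction, Benjamini–Hochberg FDR, Spearman correlation.
* **Synthetic cohorts** — a planted-hub stochastic-block generator with
  log-normal integer weights, an enriched and (for vulnerable subjects)
  attenuated rich club, and negative-binomial lapse counts linked to each
  subject's rich-club strength, so the whole pipeline is testable without
  imaging data.

The methods vignette
(`vignettes/connectome-vulnerability-methods.Rmd`) documents every model,
convention and default in detail.

## Worked example

```r
library(sdnet)
cfg <- cohort_config(n_nodes = 40, n_hubs = 6,
                     n_vulnerable = 8, n_resistant = 8, seed = 1)
cohort <- generate_lapse_scores(generate_cohort(cfg))
subj <- apply_fiber_threshold(cohort$subjects[[1]], 10)
global_metrics(subj)
#>      Sp Eglob  Eloc      Lp      Cp gamma lambda
#> 1 252.6 26.17 12.36 0.05722 0.02472    NA     NA

backbone <- backbone_network(
  lapply(cohort$subjects[cohort$group == "resistant"],
         apply_fiber_threshold, t = 10))
backbone
#> <backbone: 40 nodes, 68 edges retained from 8 subjects>
hubs <- identify_hubs(backbone)
hubs
#> [1]  1  2  3  4  6 25

ens <- matched_ensemble(subj, n = 100, seed = 2)
nr <- normalized_rich_club(subj, hubs, ens)
sprintf("phi = %.3f, phi_norm = %.3f", nr$phi, nr$phi_norm)
#> "phi = 0.354, phi_norm = 1.209"
```

`Sp` is the mean node strength (streamline counts), `Eglob`/`Eloc` are
efficiencies on reciprocal-weight distances, and `phi_norm = 1.209` means
this subject's hub–hub connections carry ~21% more weight than
degree-and-weight-matched random networks place there — rich-club
organisation. The statistics layer reproduces published summary tables
directly:

```r
pooled_t_from_summary(235.0, 46.9, 24, 184.4, 42.4, 25)
#> pooled two-sample t: statistic = 3.965, df = 47, p = 0.0002467 (two-tailed)
chi_square_2x2(gender_table()$table)
#> chi-square (2x2, uncorrected): statistic = 0.0196, df = 1, p = 0.8887 (two-tailed)
```

## The analysis workflow

The `analysis/` scripts run the study end to end on a simulated cohort with
a planted rich-club deficit (δ = 0.6) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R 1             # cohort + manifest on disk
Rscript analysis/02_network_metrics.R 1      # global/nodal metrics + group tests
Rscript analysis/03_rich_club.R 1            # backbones, hubs, phi, phi_norm
Rscript analysis/04_nbs.R 1                  # NBS component + permutation null
Rscript analysis/05_reproducibility_sweep.R 1  # thresholds 0/10/50/100 x ROI
```

With seed 1 the pipeline recovers the planted pattern: rich-club strength
lower in the vulnerable group (t = 35.8) with feeder and local strengths not
significantly different, both strength ratios lower, a significant NBS
component of 62 edges between 13 nodes (p ≈ 0.0005), Spearman
ρ = −0.79 between rich-club strength and the lapse change, and
φ<sub>norm</sub> > 1 in both groups.

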