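# synkin

Synapse-versus-kinapse analysis of T-cell migration tracks and masks.

T cells signal through two modes of contact: the **stable immunological
synapse** (spread, symmetric, positionally fixed) and the motile **kinapse**
(the cell keeps crawling while signalling). `synkin` is for imaging groups
who track T cells on uniformly coated stimulatory surfaces or on
micro-contact-printed stimulatory spots (10- or 20-µm anti-CD3 disks on a
30-µm square lattice) and want to quantify, per cell and per cohort:

* **Transient confinement** along a track, via a Simson–Saxton-type
  probability level: for sliding windows, the chance that free diffusion
  with the cell's diffusion coefficient `D` stays within the observed
  excursion radius `r` over the window duration `t` is
  `log10(psi) = 0.2048 − 2.5117·D·t/r²`, mapped to a score
  `L = max(0, −ln(psi) − 1)` so that `L > 3` means chance probability
  ≈ 0.017. Runs of `L > 3` are confined periods.
* **Positional stability index (PSI)** — a confined period with positional
  spread `R²/t < 0.666 µm²/frame` (R = confined-zone diameter) is a stable
  synapse; PSI is the fraction of frames spent in stable periods.
* **Half-life of interaction** with stimulatory spots — arrest and exit
  detection against a spot grid, then a log-linear fit of the percent of
  initially arrested cells remaining: `t½ = ln 2 / |slope|` (first-order
  exit kinetics; re-engagements of neighbouring spots are excluded).
* **Mask metrics** — sampling efficiency (unique pixels visited over 20
  frames / total footprint pixels) and protrusion index
  (`min(1, spot/cell) − overlap/cell`), plus the pooled fractional-overlap
  contour.
* **Synthetic data with ground truth** — a two-state (synapse/kinapse)
  motility simulator, Brownian null tracks, exponential residence times,
  and disk mask movies, all seeded and labelled.
* **Reporting** — cohort comparisons with paired t (donor means) or
  Mann–Whitney U (cell level), star codes, and an end-to-end pipeline that
  writes tidy CSVs and a manifest of every tunable.

## Worked example

Simulate a cell that alternates between synapse dwells (mean 30 min,
confined within 2 µm) and kinapse crawling (mean 15 min at 8 µm/min), then
classify it:

```r
library(synkin)
sim <- simulate_two_state_track(
  two_state_params(dwell_synapse = 1800, dwell_kinapse = 900, seed = 2))
res <- classify_track(sim$track)
res$classification
#> <sk_track_classification> cell sim: PSI = 0.429 (240 frames)
res$periods
#>   start_frame end_frame  t        R    spread stable
#> 1           1        25 25 2.066085 0.1707483   TRUE
#> 2          50       127 78 2.624059 0.0882780   TRUE
sim$truth$stable_fraction   # ground truth for this realization
#> [1] 0.425
```

Two confined periods were demarcated; both have positional spread below
0.666 µm²/frame, so their frames count as stable synapse, giving PSI 0.429
against a planted truth of 0.425.

Half-life from exponential residence times (planted 3.6 h, 300 cells,
8-h horizon):

```r
fit <- fit_survival(simulate_residence_times(3.6, 300, 8, seed = 3),
                    bin = 0.25, horizon = 8)
fit
#> <sk_survival_fit> half-life 3.49 h (slope -0.1986 /h, R^2 0.996, 33 bins)
```

Full pipeline on the bundled two-cohort demo (a motile "naive-like" cohort
vs a more synaptic "memory-like" cohort):

```r
res <- run_pipeline(demo_config(seed = 1, n_cells = 8), "demo_out")
aggregate(psi_index ~ cohort, res$psi, mean)
#>        cohort psi_index
#> 1 memory_like 0.6260417
#> 2  naive_like 0.2072917
res$survival[c("cohort", "half_life_h", "planted_half_life_h")]
#>        cohort half_life_h planted_half_life_h
#> 1  naive_like    3.562855                 3.6
#> 2 memory_like    1.255109                 1.1
```

The report orders the cohorts as designed: the naive-like cohort has the
lower PSI (more kinapse time) yet the longer half-life of interaction, and
`demo_out/` contains `psi.csv`, `survival.csv`, `shape.csv`,
`comparisons.csv` and `manifest.json`.

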