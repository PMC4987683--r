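# ebclock

Quantifying early mesendoderm differentiation in embryoid bodies (EBs)
from live reporter imaging and single-EB qPCR.

EBs seeded side by side switch on the Brachyury-GFP mesendoderm reporter
at very different times — the onset spread within one experiment exceeds
20 hours — so sampling EBs by wall-clock time mixes developmental
stages. `ebclock` implements the analysis that resolves this: each EB's
reporter time course is fitted with a five-parameter impulse model

    N(t) = A · L(β₁(t − t₁)) · L(−β₂(t − t₂)),   L(x) = 1/(1 + e⁻ˣ)

(amplitude `A` in segmentation points; rise/decline rates `β₁`, `β₂`
per hour; half-peak onset/decline times `t₁ < t₂`). Onset is the
300-point threshold crossing of the fitted curve, and each EB's
**developmental age** (DevA) is the time between that onset and its
harvest. Gene expression measured per EB (CT values, normalized to
−ΔΔCT against the two most stable housekeeping genes and the
control-group median) is then analyzed along this internal clock
instead of harvest time.

The package covers the full pipeline:

* **Synthetic cohorts** (`cohort_config()`, `gen_cohort()`,
  `gen_expression_panel()`) — reporter count curves, 3D shell point
  clouds and CT panels with known ground truth, at the study's reported
  conditions (onset 83.3 ± 3.7 h, onset-to-peak 12.8 ± 2.2 h, radii
  113 ± 19 µm, perturbation presets shifting onset from 70 h to 50 h).
* **Point-cloud filtering** (`neighbor_filter()`, `bbox_filter()`,
  `counts_from_clouds()`) and EB geometry (`estimate_radius()` —
  minimal enclosing circle of the 2D projection; `volume_occupancy()`).
* **Kinetics** (`fit_impulse()`, `detect_onset()`, `detect_peak()`,
  `dev_age()`, `cohort_timing_stats()`, `size_dependence()`,
  `threshold_robustness()`).
* **qPCR normalization** (`genorm_stability()`,
  `normfinder_stability()`, `select_normalizers()`,
  `normalize_neg_ddct()`, `impute_nn()`, `cluster_corr()`,
  `fold_range()`).
* **Clock trends** (`variance_explained()`, `local_linear_trend()`,
  `sort_by_devA()`).
* **Perturbation analysis** (`group_shift()`, `pca_groups()`,
  `classify_dependency_modes()` — four Wnt3-dependency modes under
  canonical Wnt activation by CHIR).

See the vignette (`vignettes/eb-developmental-clock.Rmd`) for the model,
the design decisions and the generator's assumptions.

## Worked example

Simulate one experiment of 50 co-seeded EBs, fit every reporter curve,
and summarize the cohort's timing:

```r
library(ebclock)

cfg <- cohort_config(n_ebs = 50, seed = 11)
coh <- gen_cohort(cfg)
clocks <- fit_cohort(coh$series, threshold = 300)
str(cohort_timing_stats(clocks))
#> List of 7
#>  $ onset_mean        : num 82.2
#>  $ onset_sd          : num 3.12
#>  $ onset_range       : num [1:2] 75.3 89
#>  $ onset_to_peak_mean: num 13.3
#>  $ onset_to_peak_sd  : num 4.08
#>  $ n_onset           : int 50
#>  $ n_peak            : int 50
```

All 50 EBs cross the 300-point threshold; the recovered onset
distribution (82.2 ± 3.1 h, range 75–89 h) matches the cohort the
generator drew (its true onsets for this seed average 82.2 h), and the
mean onset-to-peak interval is ~13 h. `clock_table(clocks)` flattens the
per-EB fits:

```r
head(clock_table(clocks), 3)
#>   eb_id        A beta1 beta2    t1    t2     rss onset_h peak_h status
#> 1  eb01 3426.1  0.727 0.422  84.2 115.8  59303.    81.0   96.3     ok
#> 2  eb02 2455.4  0.774 0.366  85.9 114.3  46772.    83.4   95.7     ok
#> 3  eb03 3543.3  0.739 0.333  81.1 102.4  48000.    77.9   88.4     ok
```

Now a 78-EB expression panel harvested at 92 h and 101 h, normalized
against the housekeeping pair both stability methods agree on, with
Brachyury examined along the clock versus harvest time:

```r
set.seed(11)
harvest <- c(rep(92, 23), rep(101, 55))
devA <- harvest - rnorm(78, 83.3, 3.7)
gp <- gen_expression_panel(devA, default_gene_panel(),
                           harvest_h = harvest, seed = 11)
pair <- select_normalizers(gp$panel, c("Rock2", "Ywhaz", "Wnt3", "Klf4"))
norm <- normalize_neg_ddct(gp$panel, pair)
norm
#> Normalized panel: 10 genes x 78 EBs (-ddCt, normalizers Rock2 + Ywhaz,
#>   reference 'control')

variance_explained(norm$neg_ddct["T", ], devA)     # 96.2 %
variance_explained(norm$neg_ddct["T", ], harvest)  # 50.9 %
fold_range(norm$neg_ddct["T", ])                   # 107-fold
```

Developmental age explains 96% of this Brachyury trend where harvest
time explains only 51% — the clock's entire point: two EBs harvested
together can sit hours apart in their differentiation program.

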