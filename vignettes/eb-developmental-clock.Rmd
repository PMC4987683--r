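---
title: "Methods: a Brachyury-GFP developmental clock for embryoid bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Brachyury-GFP developmental clock for embryoid bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebclock)
```

## The problem

Embryoid bodies (EBs) — 3D aggregates of embryonic stem cells — start
mesendoderm differentiation at very different times after seeding, even
when cultured side by side: Brachyury reporter (Bry-GFP) onset within one
experiment spreads over roughly 20 hours. Sampling EBs by wall-clock time
therefore mixes developmental stages. `ebclock` implements the analysis
that resolves this: fit each EB's reporter time course with a
five-parameter impulse model, read the onset event from the fitted curve,
and replace harvest time by *developmental age* (DevA) — the time elapsed
between reporter onset and harvest — when interpreting each EB's
single-EB qPCR profile.

## The impulse model

The total number of filtered Bry-GFP segmentation points over time is
pulse-shaped: a sigmoidal rise, a plateau, then a decline. We model it as
a product of two logistic functions,

$$ N(t) = A \cdot L(\beta_1 (t - t_1)) \cdot L(-\beta_2 (t - t_2)),
   \qquad L(x) = \frac{1}{1 + e^{-x}}, $$

with amplitude $A$ (points), rise and decline rates $\beta_1, \beta_2$
(per hour), and $t_1 < t_2$ the approximate half-peak times of onset and
decline. This is the simplest form with exactly these five degrees of
freedom; when $t_2 - t_1 \gg 1/\beta$ the curve reaches $\approx A$ and
$N(t_1) \approx A/2$, so $t_1, t_2$ really are half-peak times. $N$ is
bounded by $A$ and vanishes at $\pm\infty$.

```{r impulse}
p <- impulse_params(A = 3000, beta1 = 0.7, beta2 = 0.35, t1 = 85, t2 = 100)
curve(impulse_value(p, x), 60, 125, xlab = "hours after seeding",
      ylab = "Bry-GFP points")
abline(h = 300, lty = 2)
```

### Fitting and event detection

`fit_impulse()` minimizes the residual sum of squares with
Levenberg–Marquardt under box constraints ($\beta \in (10^{-3}, 10)$ per
hour; $t_2 = t_1 + \Delta$ with $\Delta \ge 0.1$ h so the ordering is
structural), started from raw half-maximum crossings and $\beta_0 = 4 /
(\text{25--75\% rise time})$. A fit is never accepted if it is worse than
its own initialization, and failures are flagged (`status`), not
silently returned. Series whose maximum count stays below the onset
threshold carry no event information and are flagged `no_signal`.

Onset is the threshold crossing of the *fitted* curve on its rising
flank — the model smooths counting noise — at 300 points by default, the
lowest threshold that robustly times onset; the package verifies that
cohort timing statistics move by well under 1.5 h for any threshold
between 300 and 600 points (`threshold_robustness()`). Onset is not read
from the fitted $t_1$: for EBs harvested before peak, $t_1$ (and the
plateau height) is poorly constrained, while a 300-point crossing is
not. Peak time is found numerically on
$[t_1 - 5/\beta_1,\; t_2 + 5/\beta_2]$; for $\beta_1 = \beta_2$ it
equals $(t_1 + t_2)/2$ exactly, which the tests assert.

`dev_age(onset, harvest)` is simply `harvest - onset`; negative values
(pre-onset harvest) are flagged rather than rejected, and undetected
onsets are an error distinct from negative ages.

## Point-cloud filtering and radius

Segmentation yields 3D point positions with intensities. Two filters
clean them, mirroring standard practice:

* `neighbor_filter()` removes points with fewer than 5 neighbors within
  40 µm (Euclidean). It is a *single pass* over the input cloud — counts
  are not recomputed as points drop out — so re-applying it can remove
  more points; the tests document this. For large frames the counts are
  computed on a 40 µm grid (27-cell neighborhoods), which is exact and
  near-linear; a brute-force $O(n^2)$ oracle checks it.
* `bbox_filter()` keeps points inside a closed axis-aligned box (points
  on a face are retained), removing plate/agar clutter far from the EB.

EB radius is the radius of the **minimal enclosing circle** of the 2D
(xy) projection of outline points — the operational meaning of a
circumscribed circle measured on a single projected image. The
implementation is the incremental Welzl construction, deterministic
given point order and verified against an $O(n^3)$ pair/triple oracle.
Volume occupancy is `count / radius^3`, a dimensionless proxy for the
reporter-positive fraction of the EB.

## qPCR normalization

Single-EB CT matrices (genes × EBs, 30 amplification cycles, failed
reactions as `NA` — never as the cycle ceiling) are normalized in two
steps:

1. **Housekeeping selection.** `genorm_stability()` computes the geNorm
   M value (mean SD of pairwise CT differences; the pair returned by the
   iterative scheme that repeatedly drops the least stable candidate)
   and `normfinder_stability()` a model-based measure combining
   inter-group bias and intra-group variance,
   $\rho_i = \text{mean}_g \sqrt{d_{ig}^2 + \sigma_{ig}^2}$, computed
   directly on candidate CT values. We deliberately omit the per-sample
   gene-centering step of the original NormFinder publication: with only
   a handful of candidates the centering couples every candidate's
   residuals to the others, and a perfectly stable (constant-CT)
   candidate would no longer score zero. On CT values directly, a
   constant candidate scores exactly 0 and a single-group design reduces
   to the within-group variance ranking — both properties the tests pin
   down. `select_normalizers()` returns the top pair **only when both
   methods agree on it as a set**; otherwise it raises a condition
   carrying both rankings, because silently picking one method would
   hide a real data-quality problem.
2. **−ΔΔCT.** $\Delta CT = CT_{gene} - \mathrm{mean}(CT_{hk1},
   CT_{hk2})$ (arithmetic mean of the two normalizer CTs = geometric
   mean of their expression), then $-\Delta\Delta CT = -(\Delta CT -
   \mathrm{median}_{\,control}\,\Delta CT)$ per gene. Reference-group
   medians are exactly zero by construction; one unit is one cycle, i.e.
   a two-fold expression change, and `fold_range()` is
   $2^{\max - \min}$. Adding a constant to all CTs of an EB (loading /
   cell-number effects) cancels exactly. EBs missing both normalizers
   are dropped with a message; with one normalizer missing the other is
   used alone.

Missing cells are imputed only where a complete matrix is required
(clustering, PCA) by `impute_nn()` — each missing value is copied from
the nearest EB under the RMS distance over co-observed genes. Trend
analyses use observed values only, so imputation can never create a
trend. Gene clustering uses distance $1 - r$ (Pearson) with average
linkage.

## Trends along the clock

`variance_explained()` is the $R^2$ (×100) of a simple linear regression
of a gene's −ΔΔCT on DevA (or on harvest time, for comparison). We use
the linear fit rather than a smoother-based estimator because it is
reproducible, affine-invariant in the response, and monotone in trend
strength; the kernel smoother is for display. Constant responses return
0 by convention (no variance to explain). `local_linear_trend()` fits a
Gaussian-kernel weighted line at each grid point (default bandwidth 25%
of the DevA range — a standard rule of thumb; the data are too sparse
per gene for cross-validation to be stable). Local linear smoothing
reproduces straight-line data exactly, and grid points with negligible
kernel mass are masked instead of extrapolated.

## Perturbation analysis and Wnt3-dependency modes

Group shifts are per-gene median differences against the control group
with an advisory Wilcoxon rank-sum flag (Benjamini–Hochberg across
genes at 0.05); the flags do not feed the mode classifier. PCA runs on
the imputed, gene-centered EB × gene matrix with percent explained
variance per component.

CHIR (a GSK3β inhibitor) activates canonical Wnt signaling *downstream*
of the Wnt3 ligand while also lowering Wnt3 transcript levels, so it
dissociates canonical-pathway targets from Wnt3 expression. For each
gene correlated with Wnt3 on control EBs
(|r| ≥ `r_min`, default 0.5), `classify_dependency_modes()` compares
the gene's behavior under CHIR with the control trend line of gene vs
Wnt3:

| mode | expression moved? | relative to trend |
|---|---|---|
| `decoupled_parallel` | no (all CHIR groups) | — |
| `indirect_long_term_only` | long treatment only | — |
| `canonical_regulation` | yes, incl. a short pulse | off-trend |
| `trend_continuation` | yes, incl. a short pulse | on-trend |

"Moved" means |shift_z| > k (group median minus control median, in
control SDs; default k = 2); "off-trend" means |residual_z| > k (median
trend residual in control residual SDs). The rules are ordered this way
because a decoupled gene is *also* off-trend — Wnt3 moved and the gene
did not — so asking "did the gene itself move?" must come first;
off-trend vs on-trend then separates direct canonical targets (which
move against the trend, like Lmo2 and Brachyury under CHIR) from genes
that slide along it (like Otx2, consistent with a non-canonical route or
simply expedited progression). The control trend line is the
**standardized major axis** (slope $\mathrm{sign}(r)\,s_y/s_w$), not an
ordinary regression of gene on Wnt3: both axes are noisy −ΔΔCT
measurements, and OLS attenuation would systematically push
trend-following genes off the line. All classifier statistics are
invariant to gene-wise affine rescaling. With no short-pulse groups in
the data the long-only mode is unresolvable and the classifier says so
rather than guessing.

## The synthetic cohort generator

No raw data accompany the study, so every stage is validated on
synthetic cohorts whose latent truth is known. The generator's defaults
*are* the study conditions:

| quantity | default | origin |
|---|---|---|
| onset time | 83.3 ± 3.7 h | within-experiment distribution |
| onset-to-peak | 12.8 ± 2.2 h | same cohort |
| EB radius | 113 ± 19 µm, truncated to 81–176 | pre-onset measurement at 60 h |
| amplitude | ~3000 points, capped at $3\times10^{-3} R^3$ | typical peak counts; size cap below ~100 µm |
| frames | every 1.5 h, 60–120 h | 1–2 h imaging interval |
| counting noise | Poisson (variance = mean) | counts of segmented objects |
| perturbed onset | control 70 h; CHIR-long / Bmp4 50 h | perturbation experiment |

Rather than drawing $t_1, t_2$ directly, `gen_cohort()` draws the
*observable* events — onset and onset-to-peak — and inverts the event
map (`solve_impulse_times()`) so the simulated distributions are exactly
the designed ones. The rise and decline rates are not reported
quantities; defaults $\beta_1 = 0.7$, $\beta_2 = 0.35$ per hour are
constrained jointly by the onset-to-peak interval and by the requirement
that onset timing be robust to thresholds 300–600 (the 300→600 crossing
lag on a single curve is $\ln\!\big(600(A-300)/300(A-600)\big)/\beta_1$,
which must stay well under 1.5 h at the simulated amplitudes). Onset
times, onset-to-peak intervals and radii are drawn independently — the
study's own conclusion about size independence — and the amplitude cap
$A = \min(A_{free}, 3\times10^{-3}R^3)$ reproduces the weak
amplitude–size correlation restricted to EBs below ~100 µm. The
within-experiment correlation between onset and onset-to-peak is not
reported; the generator treats them as independent.

Point clouds place the reporter-positive points on a contiguous angular
cap of the EB shell centered on a fixed onset locus; the covered shell
fraction is $N(t)/A$, so the cap grows from a single locus and recedes
toward it, covering the full shell when $N = A$. GFP points carry 2 µm
radial jitter (cell-sized segmentation objects); the outline shells used
for radius estimation carry 1 µm (optical edge localization) — this
matters because a circumscribed circle tracks the outermost jittered
point, and would otherwise acquire a bias of about two jitter SDs.
Clutter is a sparse uniform component outside 1.1 R (removed by the
close-neighbor filter) plus a small far cluster (removed by the
bounding box), exercising both filters.

Expression panels are emitted as CT values by inverting the −ΔΔCT
transform: each EB gets a loading offset (cell-number proxy) shared by
all its genes and tracked by two designed housekeeping genes ("Rock2",
"Ywhaz"), and each gene's signal is
`intercept + slope · DevA + shift(group) + noise`. With all noise at
zero, normalization returns the designed signal exactly (centered on the
control median) — a round-trip identity the tests assert. The
dependency-mode panels use genes with |slope| = 0.3 −ΔΔCT/h against
Wnt3's −0.2, DevA spread U(8, 20) h, 30 control EBs and 10 per CHIR
group, and per-mode shifts of at least three control SDs; under those
conditions mode recovery exceeds 90% over 20 seeds. Thirty control EBs
(not the 10 minimum) are used because the standardized-major-axis slope
estimate from a small control group is the dominant source of
classification error.

### What the generator does not emulate

Voxel-level imaging (PSF, depth attenuation, segmentation itself),
intensity calibration to cell numbers, hanging-drop culture variability,
amplification efficiency differences between assays, and any
gene-regulatory network structure: genes are conditionally independent
given DevA and group. Passing tests therefore demonstrate that the
*analysis* recovers what it claims from data with the assumed
statistical structure — not that real EBs satisfy those assumptions.

## Numerical choices and degenerate inputs

* Onset root-finding brackets the rising flank between a far-left point
  and the numeric peak (tolerance $10^{-9}$ h); onset is `NA` when the
  peak never reaches the threshold.
* The Welzl circle uses a $10^{-7}$ relative containment tolerance;
  collinear triples fall back to the widest pair.
* `variance_explained()` clips to [0, 100]; constant covariates are an
  error, constant responses return 0 with a message.
* Ties in `sort_by_devA()` keep input order (stable sort); EBs without
  a clock are appended and flagged, never interleaved.
* Problem sizes in the test-suite recovery checks — 50-EB cohorts for
  timing and radius, 78 EBs for clock informativeness, 30 per
  perturbation arm, 20 seeds for mode recovery — are the cohort sizes of
  the emulated experiments.

## Known limitations

The impulse form is one of several five-parameter pulse shapes; if the
true generating curve were, e.g., a normalized sum form, half-peak
semantics of $t_1, t_2$ would need re-checking. The NormFinder-style
measure is a deliberate simplification (above). Mode classification
assumes shifts large relative to control variability; genes with weak
responses gate into `not_correlated` or `decoupled_parallel` rather than
receiving a low-confidence mode label. DevA requires a detected onset:
EBs harvested long before onset cannot be placed on the clock at all.
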