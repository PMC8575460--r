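---
title: "somatomap: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somatomap: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

# Scope

somatomap analyses finger somatotopy in the primary somatosensory (S1) hand
area: phase-encoded (travelling-wave) winner-take-all finger maps with FDR
thresholding and group probability maps; split-half map consistency via the
Dice overlap coefficient; a blocked-design GLM with percent-signal-change
(PSC) extraction; crossnobis representational similarity analysis (RSA) with
separability, typicality and MDS; and the accompanying statistics
(Crawford–Howell single-case tests, bootstrap intervals, Benjamini–Hochberg
FDR, rank-based group tests, seeded permutation tests). Because no real
dataset ships with the package, every stage is driven and validated by a
synthetic BOLD generator with known somatotopic ground truth.

This vignette records the models, the tunable parameters with their defaults
and rationale, what the generator does and does not emulate, the numerical
conventions, and the design choices made where the design was genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# The synthetic world

## Designs

`design_spec()` encodes two acquisition protocols at TR 2 s:

* **Travelling wave**: the five fingers are cued in a fixed cycle, 10 s per
  finger, 50 s per cycle, 7 cycles per run; two forward (thumb → little) and
  two backward runs of 182 volumes (364 s) each.
* **Blocked**: 8 s blocks of six conditions (five fingers + rest), each
  repeated 5 times per run in a seeded counterbalanced order distinct per
  run; four runs of 127 volumes (254 s).

The cycle structure accounts for 350 s and the blocks for 240 s; the
remaining 14 s of each run is modelled as an *initial* rest baseline. Whether
those seconds were leading rest, trailing rest or dummy scans is not
determinable from the protocol figures alone; leading rest is the assumption,
exposed as `baseline_pad_seconds`.

## Ground truth and deterioration

`ground_truth_map()` lays a contiguous hand-area slab on a 3-D lattice
(default 20 × 20 × 10 voxels) with a monotone thumb→little preferred-finger
gradient along one axis, a disjoint CSF block with zero response, and silent
background. Each hand voxel responds to finger $f$ with Gaussian tuning
$g_v(f) = \exp\{-(f - p_v)^2 / 2w_v^2\}$ around its preferred finger $p_v$.

Two deliberate departures from a textbook homogeneous map:

* **Cortical magnification** (`magnification = TRUE`, default): tuning width
  grows and response gain falls from thumb to little finger (0.7–1.3 × the
  base width 0.8 fingers; 1.2–0.8 × the base gain 1 % signal). A homogeneous
  map makes the template inter-finger distance structure depend only on
  $|i-j|$, producing near-tied representational distances whose ranks are
  unstable under any measurement noise; the magnified map has ten
  well-separated canonical distances, as real hand representations do. Widths
  and gains are properties of the cortical site (fixed at map creation), so
  later reorganisation does not change a voxel's net responsiveness.
* **Mean-normalised profiles**: every tuned voxel's response profile is
  rescaled so its mean over the five fingers equals a fixed constant. This
  makes overall (all-fingers-vs-rest) activity *exactly* invariant under
  deterioration — the dissociation the pipeline must reproduce (net activity
  preserved, somatotopy degraded) holds by construction rather than
  approximately.

Deterioration $\delta \in [0,1]$ acts through two mechanisms:

* **Mixing**: the profile is mixed toward its finger-mean with weight
  $\delta$, so between-finger pattern variance shrinks as $(1-\delta)^2$ and
  vanishes at $\delta = 1$ (the congenital one-hander limit: no tuned
  voxels, uniform responses, preserved net activity).
* **Scatter**: each voxel's preferred finger is jittered by a rounded
  Gaussian with SD $3\delta$ fingers (clipped to 1–5), reorganising the map
  itself.

For SCI subjects $\delta = \mathrm{years\ since\ SCI}/35$ (clipped), so the
deterioration-with-time effect is recoverable ground truth; motor and sensory
scores decline with $\delta$ plus Gaussian noise, while tissue bridges and
cord area are independent of it (their correlations should come out null).
The scatter SD and the magnification profile were calibrated once so that the
stated recovery targets hold on default cohorts — the years-vs-typicality
rank correlation is detected (two-sided $p<0.05$) in $\ge 90\%$ of cohort
seeds at the study's group sizes — and were not revisited afterwards.

## Noise

Default noise is i.i.d. Gaussian with SD 1 % signal per volume, a realistic
thermal + physiological figure for 2 mm voxels at TR 2 s against a 1 % peak
response; AR(1) temporal correlation is available (`ar1`). The generator does
**not** emulate head motion, physiological cycles, distortion, registration
error or cortical surface geometry. A green recovery test therefore
establishes that the estimators are correct and calibrated for
additive-noise somatotopic data — not that the pipeline is robust to
real-world artefacts, which the out-of-scope preprocessing of a real study
would have to remove first.

# Travelling-wave analysis

A reference response (gamma HRF convolved with the 10 s-on/40 s-off boxcar,
tiled over the 7 cycles) is shifted by one TR at a time across the 50 s
cycle, giving 25 standardised models; each voxel's time course is Pearson-
correlated with each model at zero offset (the lag lives in the bank) and
Fisher r-to-z transformed. Correlations are clamped at $|r| \le 1-10^{-7}$ so
noiseless data keep finite z; constant time courses get z = 0.

**Lag → finger assignment.** Each finger owns five consecutive *cyclic* lags
centred on its cue-onset lag. Centring is not cosmetic: the reference model
already carries the HRF delay, so a voxel's correlation profile peaks exactly
at its cue lag and falls off symmetrically. An assignment that starts each
group at the onset lag would spill half of every finger's correlation mass
into the cyclically previous group and bias forward-only and backward-only
maps in opposite directions; with centred groups, single-direction maps agree
voxel-for-voxel on noiseless data (the package's direction-equivalence test).

**Backward lag reversal.** Time-reversal maps an ON window starting at lag
$k$ onto one starting at $\mathrm{cycle} - \mathrm{window} - k$, so backward
lag vectors are remapped by $(25 - 5 - k) \bmod 25$ — plain index reversal
plus a block-width correction — before averaging with forward runs in the
lag-specificity map. Plain reversal without the correction leaves a constant
10 s phase error.

**Thresholding.** The winner's Fisher z is converted to a two-sided p-value
under the nominal null $z \sim N(0, 1/(n_{\mathrm{eff}}-3))$ with
$n_{\mathrm{eff}}$ = volumes per run, then Benjamini–Hochberg-corrected
across in-mask voxels (q = 0.05 default). Temporal autocorrelation makes
$n_{\mathrm{eff}}$ nominal; it is configurable. Because the thresholded
statistic is a winner (a maximum over five), this conversion is conservative
for the null voxels the FDR is meant to control, which the CSF
false-positive test confirms. The same standardised statistic underlies the
"minimal Z > 2" threshold used for split-half masks. Winner ties break
deterministically to the lowest finger index and are flagged.

# Split-half Dice analysis

Half 1 is the finger map from the first forward + first backward run, half 2
from the second of each; both halves run through the identical pipeline. For
every cross-half finger pair $(i, j)$ the Dice overlap
$2|A \cap B| / (|A| + |B|)$ is computed on the thresholded winner masks
within the S1 ROI and classified by $|i-j|$ (0 same, 1 neighbour, ≥ 2
non-neighbour; no wraparound). Pairs where both masks are empty are undefined
(NA) and excluded from category means. Dice is computed volumetrically on the
lattice; the surface-based computation of a real study is a documented
deviation, immaterial for synthetic grids.

# Blocked-design GLM

Design matrices contain the five finger regressors (double-gamma HRF
convolved boxcars, unit peak per run), their temporal derivatives (boxcar
convolved with the analytic HRF derivative), a discrete-cosine high-pass
basis up to the 100 s cut-off (90 s would be the travelling-wave value), and
an intercept. High-pass filtering by nuisance columns is the same projection
as pre-filtering with simpler provenance. Fitting is per-run OLS:
prewhitening against local autocorrelation is deliberately omitted (betas
stay unbiased; variance estimates are nominal), with a single-pass
Cochrane–Orcutt AR(1) refit behind `ar1_correct`. Run-level contrasts are
averaged across runs with equal weights — the fixed-effects combination
appropriate for equal-length balanced runs.

PSC scales the all-movement-vs-rest contrast by the voxel's baseline (the
intercept beta) — plain mean-signal scaling, not a regressor-height
convention; with unit-peak regressors on both the generating and analysis
side, a simulated 1 % amplitude reads out as PSC ≈ 1.

# Crossnobis RSA

Residual voxel covariances are pooled over runs, shrunk toward their
diagonal with weight λ (default 0.1; λ = 1 gives univariate per-voxel
scaling, also reachable via `univariate = TRUE`), and inverted via a
symmetric eigendecomposition square root. Condition patterns are prewhitened
and the cross-validated squared Mahalanobis distance computed over all six
unordered pairs of the four runs:
$$d_{ij} = \frac{2}{R(R-1)\,P} \sum_{r<s}
  (u_{i,r}-u_{j,r})^\top (u_{i,s}-u_{j,s}).$$
Cross-validation makes the estimator unbiased: zero expectation when the
true patterns agree (individual estimates may be negative), positive when
they differ. Separability is the mean of the ten unique RDM values; a CSF
control ROI re-runs the full analysis where no finger information exists.

**Typicality** is the Spearman correlation between a subject's ten distances
and a canonical RDM's, Fisher r-to-z transformed for inference (raw rho kept
for display). The normative 7T canonical of a real study is not available,
so the default canonical is *synthetic*: the generator's noise-free
control-template RDM (`canonical_rdm()`); `read_rdm_csv()` loads a
user-supplied 5 × 5 table instead.

**MDS**: classical scaling of the (possibly non-Euclidean) crossnobis matrix
via the double-centred Gram matrix, truncating negative eigenvalues and
flagging configurations whose truncated mass exceeds 10 %. Per-subject 2-D
embeddings are aligned by orthogonal Procrustes (rotation/reflection, no
scaling) to an iterated group mean (generalised Procrustes, 10 iterations or
$10^{-8}$ convergence); group means and between-subject SEs are computed
only after alignment.

# Statistics

* **Crawford–Howell**: $t = (x-\bar c)/(s_c\sqrt{(n+1)/n})$, df $n-1$,
  two-sided; converges to the z-test as $n \to \infty$.
* **Bootstrap means**: 10,000 with-replacement replicates by default. The
  interval is the *expanded* percentile interval (quantile levels widened by
  the $t$-versus-normal ratio): the plain percentile interval measurably
  undercovers at the group sizes involved (n ≈ 15–20), while the expanded
  interval restores 93–97 % empirical coverage; `type = "percentile"` gives
  the uncorrected interval.
* **BH-FDR**: literal step-up with monotone adjusted p-values, tested
  exhaustively against the definition for m ≤ 8.
* **Group tests**: Mann–Whitney / paired Wilcoxon for two groups,
  Kruskal–Wallis for three; all two-tailed. The trimmed-means robust mixed
  ANOVA of the motivating literature is *not* reimplemented — a seeded
  permutation test of the group × category interaction
  (`permutation_group_test`, label permutation across subjects) covers the
  same contrast and is the documented substitute. Bayes factors are out of
  scope.
* **Covariate correlations**: Spearman, two-sided, uncorrected (exploratory,
  by design), computed on Fisher-z typicality.
* `stepwise_forward()` is a thin, explicitly exploratory forward-selection
  utility.

# Determinism and I/O

A single pipeline seed fans out to per-subject, per-run child seeds through
a counter-based scheme (`derive_seed`), so any subset of the cohort is
reproducible in isolation; all helpers restore the caller's RNG state.
Re-running `run_pipeline()` with one config + seed reproduces every output
byte-for-byte on one machine, and the run manifest stores an MD5 hash per
output file (`verify_manifest()` detects tampering). Volumes can be
exchanged as single-file little-endian NIfTI-1 (`write_nifti` /
`read_nifti`, float32/int16, validated against an independent neuroimaging
reader); tables are CSV and configs JSON.

# Known limitations

* The noise model is additive Gaussian (optionally AR(1)); no motion,
  physiology, or spatial noise correlations, and no surface geometry.
* FDR p-values use a nominal effective sample size; inference on real,
  autocorrelated data would need FILM-like prewhitening, which is out of
  scope.
* The canonical RDM is synthetic unless the user supplies one; typicality
  values are therefore comparable within a cohort, not across studies.
* Group sizes below ~3 per group degrade the statistical battery gracefully
  (tests are skipped with warnings) but meaningfully.
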