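---
title: "Measuring free water in white matter: models, masks and statistics"
author: "freewater package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring free water in white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freewater)
```

## The measurement problem

Extracellular free water (FW) in cerebral white matter — water diffusing
isotropically at roughly the rate of bulk water at body temperature — rises
with neuroinflammation, oedema and partial-volume contamination from CSF.
A whole-brain FW summary computed from an ordinary clinical single-shell DWI
acquisition (here: 41 directions at b = 1000 s/mm², one b = 0) is attractive
because it needs no tractography, atlases or multi-shell protocols. Getting a
*meaningful* number out of it requires three things, and this package
implements all three:

1. a per-voxel **bi-tensor fit** separating the FW fraction `f` from the
   tissue tensor;
2. a **partial-volume-safe white-matter mask** so that ventricular and sulcal
   CSF does not masquerade as tissue FW, with white-matter hyperintensities
   (WMH) and their penumbra excluded on top;
3. **cohort statistics** (log-scale ANOVA, Tukey–Kramer contrasts, ANCOVA,
   voxelwise z-score cluster maps) on the resulting per-subject metrics.

Everything is testable without clinical data through a synthetic phantom and
cohort generator with exact ground truth.

## The bi-tensor signal model

For gradient `k` with b-value `b_k` and direction `g_k`, the model is

$$ S_k = S_0\left[(1-f)\,e^{-b_k\, g_k^{\top} D\, g_k} + f\,e^{-b_k d_w}\right], $$

with `f` the free-water volume fraction, `D` the (symmetric
positive-definite) tissue tensor and `d_w = 3.0e-3` mm²/s the diffusivity of
free water at body temperature — a literature constant, exposed in
`fw_fit_config()` but rarely worth changing.

### Why constraints are not optional

With a single shell, the data contain essentially one attenuation profile per
direction, and an unconstrained bi-tensor model is *not identifiable*: a
faster, more isotropic tissue tensor can mimic the free-water compartment
exactly at one b-value. In noise this is not a theoretical nicety — an
unconstrained least-squares fit collapses to `f = 0` in most voxels because
the tensor's six degrees of freedom absorb the water signal. Three
constraints restore a usable problem:

* **Eigenvalue bounds** on the tissue tensor, `[0.1e-3, 2.5e-3]` mm²/s. The
  upper bound is strictly below `d_w`, which is what makes `f = 1`
  distinguishable from fast tissue.
* **A tissue mean-diffusivity (MD) prior**, `md_range = c(0.6e-3, 0.9e-3)`
  mm²/s — the healthy-white-matter band. The fit adds a *dead-zone* penalty
  `md_prior_weight * (b̄ · dist(MD, md_range))²`: zero while the profiled
  tissue MD stays inside the band, quadratic outside. The dead-zone form
  matters: a ridge toward a single prior value also works against the
  collapse but biases noise-free recovery by the prior–truth mismatch,
  whereas the dead zone leaves exact data unharmed. With the prior inactive
  (`md_prior_weight = 0`) the collapse behaviour returns; the default weight
  0.5 is far from any sensitivity edge (2× either way changes little).
* **Optional spatial smoothness** of the `f` field (below).

### How the fit is computed

The fit is a variable projection over `f`. Given a candidate `f`, the implied
tissue attenuation `(S/S_0 - f e^{-b d_w})/(1-f)` is clamped entrywise into
the band allowed by the eigenvalue bounds and fit by the standard log-linear
tensor regression — one shared 6×6 solve, so sweeping `f` over a grid for
every voxel at once is pure matrix algebra. `f` is then chosen per voxel to
minimise the signal-domain sum of squares (plus the MD penalty), refined by
parabolic interpolation between grid points, and the tensor is re-fit at the
selected `f` with eigenvalues clipped into bounds by eigen-decomposition.
`S_0` is fixed at the mean of the b = 0 volumes rather than optimised — with
any b = 0 measurement present this is the standard estimator, and it removes
one degeneracy direction.

The default grid has 51 points (`f_grid_n`); the parabolic refinement brings
noise-free recovery to ~2e-3 absolute error. For cohort simulations where
per-voxel precision matters less than throughput, 26 points lose nothing at
the group level and halve the cost.

When `lambda_reg > 0` (default 0.1) the per-voxel objectives are coupled by
the penalty `lambda_reg * Σ ||∇f||²` over the 6-neighbourhood graph of the
mask, implementing spatial coherence of the FW field. Because the per-voxel
objective is cached on the `f` grid, the coupled problem is optimised by
iterated conditional modes: each sweep re-selects every voxel's grid value
given its neighbours, for at most `max_iter` (default 10) sweeps or until the
total objective decreases by less than `tol`. The objective is computed on
s0-normalised signal, so `lambda_reg` is scale-free with respect to signal
amplitude. On the SNR-30 slab phantom, `lambda_reg = 0.1` roughly halves the
voxelwise RMSE relative to `lambda_reg = 0` (the acceptance script recomputes
both numbers).

Voxels that cannot be fit (non-positive b = 0 signal, non-finite values)
carry `NA` everywhere downstream — never 0, which would bias the metrics low.

Remaining honesty notes: with *isotropic* tissue (GM-like), one b-value
cannot separate `f` from the tissue diffusivity even noise-free; the prior
resolves the degeneracy by assumption, so FW values in GM/CSF-like tissue are
prior-driven, not measured. All metrics in this package are taken over
white-matter masks, where the tensor is anisotropic and the fit is genuinely
informative. Under Rician noise the voxelwise estimates remain noisy
(RMSE ≈ 0.04–0.09 at SNR 30 depending on smoothing); subject-level summaries
average over thousands of voxels and are far more stable, and systematic
components of the error are common to all subjects and cancel in group
contrasts.

## The safe white-matter mask

On a shared voxel grid (registration is upstream and a hard precondition; the
package refuses mismatched grids rather than resampling), the mask is

$$ WM_{safe} = \big((WM - (GM \oplus R^1)) - (CSF \oplus R^1)\big) \cap (BM \ominus R^{15}), $$

i.e. white matter with a one-voxel guard band against GM and CSF, restricted
to a deeply eroded brain mask. Choices the notation leaves open, and how this
package resolves them:

* **Structuring element**: the discrete Euclidean ball (`‖v‖₂ ≤ n`), not a
  cube — the faithful reading of "radius"; a cube is available
  (`se_type = "cube"`) for sensitivity checks. The radius-1 ball has 7
  offsets, the radius-2 ball 33.
* **WMH penumbra**: "dilation of 2 voxels" is one radius-2 ball dilation, not
  two iterated radius-1 dilations (these differ on a discrete grid).
* **Border rule**: erosion treats outside-the-grid as background, so the
  brain mask recedes from the field of view edge too — the conservative
  choice for partial-volume safety. Dilation ignores out-of-bounds
  neighbours.
* **Radii are voxel units** of the working grid. The defaults (1, 15, 2)
  assume the 1 mm isotropic up-sampled diffusion space; on stylized test
  phantoms the brain-erosion radius is scaled with the geometry (a 15-voxel
  erosion of a 20-voxel phantom brain leaves nothing).
* Tissue masks are hard labels; probabilistic maps must be thresholded
  upstream.

Internally, dilation and erosion are computed by FFT convolution of the mask
with the structuring element (zero-padded, so the border rules above hold
exactly); counts are integers, so rounding removes FFT noise and the result
is bit-exact against brute-force neighbourhood scans — which the test suite
asserts on 100 random masks. No installed 3-D binary morphology was
available, so this is implemented in-package.

Two lesion-mask conventions: the **WMHs metric row uses the undilated lesion
mask** (FW inside the lesions themselves), while the subtraction from
`WM_safe` uses the **dilated** mask (lesion + penumbra excluded from
normal-appearing WM).

## The two metrics

Over a mask `m`, with missing voxels removed first:

* `rFW_m` — the fraction of mask voxels with FW **strictly** greater than
  0.1. A voxel at exactly 0.1 does not count. The threshold is a config
  value; it was chosen empirically for the clinical data this design targets
  and may need adjustment on other datasets, so `rfw_threshold_sweep()`
  evaluates a grid (rFW is non-increasing in the threshold, which the tests
  assert). rFW is deliberately volume-relative, to be robust against
  ventricular expansion and global atrophy.
* `muFW_m` — the plain arithmetic mean of FW over the mask, *including*
  voxels below the rFW threshold.

Each subject yields four records: `WM`, `WM_safe`, `WMHs`,
`WM_safe_minus_WMHs`, each carrying the undilated WMH volume in mm³.

## Cohort statistics

Metrics are analysed on the **natural-log** scale (the log base only rescales
printed differences; natural log is stated prominently because reported
group differences are log-scale numbers). Per metric: one-way ANOVA for a
group main effect, then all pairwise **Tukey–Kramer** contrasts — the
unequal-`n` form, since the target cohorts are unbalanced — with
`diff = mean_i - mean_j` in level order (NC−MCI, NC−AD, MCI−AD),
`se = sqrt(MSW (1/n_i + 1/n_j)/2)` and p-values from the studentized range
distribution. For two groups this reduces to the pooled t-test, which the
tests verify, along with a hand-computed worked example (F = 3 on
{1,2,3},{2,3,4},{3,4,5}) and a type-I error simulation at the clinical group
sizes 81/103/42 (the observed rate must stay in [0.03, 0.07]).

The ANCOVA fits `log(metric) ~ group + age + gender` by least squares with NC
as the reference level and reports partial F-tests per covariate plus
covariate-adjusted NC−patient contrasts; in this additive model the adjusted
contrast *is* the group coefficient, i.e. the comparison at equal age and
gender. Rank deficiency (e.g. a constant covariate) is an error naming the
culprit, not a silent drop. Implementation rides on `stats::aov`/`lm`/
`ptukey`; the test suite cross-checks against `TukeyHSD` and `emmeans` as
independent routes. No multiplicity correction is applied across metric rows,
matching the design this package implements; the rows are strongly
correlated summaries of one FW field, and readers should treat the stars
accordingly.

## z-score cluster maps

Given spatially aligned FW volumes: the reference (control) group defines a
per-voxel mean and sample SD (n−1); each patient is z-scored against it;
z-volumes are averaged within patient group; the average is thresholded at
**z ≥ 2 inclusive** (positive tail only by default — elevated FW is the
direction of interest; `two_tailed = TRUE` for |z|); connected components are
labeled (26-connectivity by default, 6/18 configurable) and components under
**10 voxels** discarded. Voxels where the reference SD is zero or any subject
is missing are invalid and can never survive. The component labeling is a BFS
flood fill, tested against an independent label-propagation oracle.

## The synthetic generator

`make_phantom()` builds a stylized head: nested ellipsoids for brain, a
cortical GM shell, WM interior and ventricular CSF; WMH lesions carved from
deep WM; an axially symmetric WM tensor (eigenvalues 1.5/0.4/0.4 ×10⁻³
mm²/s) whose principal direction varies smoothly across the volume; DWI
generated voxelwise from the forward bi-tensor model and degraded with
**Rician** noise (`sqrt((S+n₁)² + n₂²)`), the correct magnitude-MRI noise
model. The default geometry is 64³ at 1 mm so that the clinical 15-voxel
brain erosion leaves a usable safe-WM shell; tests run smaller grids with the
erosion radius scaled proportionally.

The ground-truth FW field is `f = 0.15` baseline in WM **plus a smooth random
texture** (`f_texture_sd = 0.08`, a box-smoothed Gaussian field), a rise of
up to +0.25 over the 3 voxels nearest CSF/GM (emulating partial-volume
contamination — this is what makes `WM` and `WM_safe` genuinely different),
`f = 1` in CSF and 0.6 inside lesions. The texture deserves a word: real WM
FW is continuously heterogeneous, and without it rFW (a strict threshold
count at 0.1) would be a step function of a subject's baseline — whole groups
at exactly 0 or 1, which is both unrealistic and statistically degenerate.

`make_cohort()`/`run_synthetic_cohort()` add the study structure: group
offsets on the WM baseline (defaults 0 / +0.02 / +0.04 for NC / MCI / AD),
per-subject Gaussian jitter on the offset (SD 0.005 — keeps within-group
variance realistic without drowning the between-group signal), group-wise age
and gender distributions matching the clinical cohort this design targets
(81/103/42 subjects, ages ≈ 78–79, the observed sex ratios) and WMH counts
increasing along the disease continuum (every subject gets ≥ 1 lesion so
lesion volume stays positive for log-scale analysis). The ground-truth metric
table is computed from the true field with the same metric code used on fits,
so pipeline output is comparable voxel-for-voxel.

What the generator does **not** emulate: anatomy, crossing fibres (the
bi-tensor model itself assumes a single fibre population; most real WM voxels
contain more), motion/eddy/multi-site artefacts, and registration error.
Passing tests therefore demonstrate algorithmic correctness and statistical
behaviour under the stated model, not robustness to real-scanner physics.

## Problem sizes and validation choices

The validation suite uses: a 40×40×44 slab phantom (11 f-levels) for
recovery; 100 random 12³ masks for morphology oracle equivalence; a full-size
64³ phantom for the Eq-above postconditions at the clinical radii; 1000 null
cohorts at sizes 81/103/42 for type-I error; and 20 seeded repeats of a
60-subject cohort on 16³ phantoms (offsets 0/0.03/0.06, coarse 26-point fit
grid, brain erosion radius 3) for end-to-end direction recovery. At that
miniature geometry nearly every safe-WM voxel lies within partial-volume
reach, so the *fitted* rFW saturates at 1 and carries no group information —
the direction-recovery check is therefore evaluated on the μFW rows (with and
without WMH removal). On the full-size geometry rFW is informative; the
saturation is a property of the reduced test geometry, not of the measure.

## Known limitations

* Single-shell FW is prior-dependent by construction; absolute FW levels
  inherit the MD prior band, and only *relative* (between-group,
  between-mask) comparisons should be interpreted.
* The z-score cluster procedure makes no multiplicity correction and is a
  visualization aid, not inference; permutation or TFCE-style approaches
  would be the upgrade path.
* The pipeline consumes co-registered inputs; it neither registers nor
  resamples, and refuses grids that disagree (1e-4 mm affine tolerance).
* `muFW` includes sub-threshold voxels by design (the plain mean); whether a
  thresholded mean would separate groups better is deliberately not explored
  — tuning the threshold to the groups would fit the cohort, not the biology.
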