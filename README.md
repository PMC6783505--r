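# freewater

Whole-brain free-water (FW) measurement from single-shell diffusion MRI, for
studies that need a simple, tractography-free white-matter summary — e.g.
separating cognitively normal, MCI and Alzheimer's-disease groups on
clinical-grade DWI (41 directions at b = 1000 s/mm²).

## What it computes

Per voxel, the constrained bi-tensor model

```
S_k = S0 [ (1 - f) exp(-b_k gᵀ D g) + f exp(-b_k d_w) ],   d_w = 3.0e-3 mm²/s
```

is fit by variable projection over the FW fraction `f`, with bounded tissue
eigenvalues, a dead-zone prior on the tissue mean diffusivity (single-shell
FW is not identifiable without one), and optional spatial smoothing of the
`f` field. Per subject, FW is summarised inside a partial-volume-safe WM
mask built by 3-D binary morphology,

```
WM_safe = ((WM - (GM ⊕ R1)) - (CSF ⊕ R1)) ∩ (BM ⊖ R15)
```

with white-matter hyperintensities (WMH) and their 2-voxel dilated penumbra
removed on top, giving two measures over four masks:

* `rFW` — fraction of mask voxels with FW strictly above 0.1;
* `muFW` — mean FW over the mask,

plus the WMH volume. Per cohort: natural-log-scale one-way ANOVA,
Tukey–Kramer pairwise contrasts (unequal group sizes), ANCOVA adjusting for
age and gender, and voxelwise z-score maps thresholded at z ≥ 2 with
clusters under 10 voxels discarded. A synthetic phantom/cohort generator
with exact ground truth makes the whole pipeline testable offline.

## Worked example

Fit a noisy slab phantom with known FW levels and check the recovery:

```r
library(freewater)
ph  <- make_slab_phantom(shape = c(20, 20, 22),
                         f_levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         rician_sigma = 100 / 30, seed = 7)   # SNR 30
fit <- fit_freewater(ph$dwi, ph$mask)
fit
#> Free-water bi-tensor fit
#>   8800 voxels in mask, 0 unfittable
#>   f: median 0.488, IQR [0.252, 0.734]
#>   spatial regularization: lambda = 0.1
cbind(true_f = c(0.1, 0.3, 0.5, 0.7, 0.9),
      mean_fitted = sapply(1:5, function(lv)
        round(mean(as.vector(fit$f_map)[ph$slab == lv]), 3)))
#>      true_f mean_fitted
#> [1,]    0.1       0.123
#> [2,]    0.3       0.278
#> [3,]    0.5       0.482
#> [4,]    0.7       0.690
#> [5,]    0.9       0.894
```

Each slab's mean fitted FW lands within ~0.02 of its ground truth at
clinical noise levels. End-to-end on a synthetic three-group cohort
(16³ phantoms, WM FW offsets 0 / +0.03 / +0.06 for NC / MCI / AD):

```r
pspec <- phantom_spec(shape = c(16, 16, 16), n_wmh = 1,
                      wmh_radius_range = c(1, 1), seed = 1)
cspec <- cohort_spec(n_per_group = c(NC = 10, MCI = 10, AD = 10),
                     f_offsets = c(NC = 0, MCI = 0.03, AD = 0.06), seed = 2)
cfg <- pipeline_config(fit = fw_fit_config(f_grid_n = 26), r_brain = 3)
res <- run_synthetic_cohort(pspec, cspec, cfg)
run_cohort(res$metrics, res$demographics, cfg)$report
#> Cohort report (log scale): 9 metric(s)
#>                   metric        F         NC_MCI           NC_AD          MCI_AD
#>                  muFW_WM 34.88*** -0.06 (0.01)** -0.15 (0.01)*** -0.09 (0.01)***
#>             muFW_WM_safe 40.86*** -0.06 (0.01)** -0.15 (0.01)*** -0.08 (0.01)***
#>  muFW_WM_safe_minus_WMHs 26.99***  -0.06 (0.01)* -0.14 (0.01)*** -0.08 (0.01)***
#>               WMH_volume    5.21*   -0.22 (0.18)   -0.78 (0.18)*   -0.56 (0.18)
#>  ...
```

The constructed NC < MCI < AD ordering comes back as negative log-scale
NC−patient differences with the expected significance, and survives removal
of the WMH lesions and their penumbra from the mask. (At this miniature test
geometry the rFW rows saturate and carry no signal; see the methods
vignette.) On real data the entry points are `run_subject()` — NIfTI DWI +
bval/bvec + tissue masks in, FW maps and a metrics CSV out — and
`run_cohort()` on the pooled metrics plus a demographics table. A thin CLI
over the same functions ships in `inst/cli/fw_pipeline.R` with verbs
`qa | fit | metrics | cohort | zmap | simulate`.

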