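#' Evenly distributed gradient scheme
#'
#' Builds a single-shell gradient table with `n_b0` unweighted volumes
#' followed by `n_dirs` directions spread over the sphere by the golden-angle
#' (Fibonacci) spiral, which is deterministic and close to uniform. The
#' defaults mirror the clinical acquisition this pipeline targets: 41
#' directions at b = 1000 s/mm^2 plus one b = 0.
#'
#' @param n_dirs number of diffusion directions.
#' @param bval shell b-value (s/mm^2).
#' @param n_b0 number of b = 0 volumes.
#' @return a [gradient_table()].
#' @export
make_gradient_scheme <- function(n_dirs = 41, bval = 1000, n_b0 = 1) {
  i <- seq_len(n_dirs)
  z <- 1 - (2 * i - 1) / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  gradient_table(c(rep(0, n_b0), rep(bval, n_dirs)),
                 rbind(matrix(0, n_b0, 3), dirs))
}

#' Rician noise for magnitude MR signal
#'
#' Magnitude images of complex Gaussian noise follow the Rician
#' distribution: `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2` independent
#' zero-mean Gaussians of standard deviation `sigma`. The result is always
#' non-negative, and a zero signal becomes Rayleigh noise with mean
#' `sigma * sqrt(pi/2)`.
#'
#' @param signal non-negative numeric vector or array.
#' @param sigma noise standard deviation (same units as `signal`); 0 returns
#'   the input unchanged.
#' @param seed optional integer seed for a deterministic draw.
#' @return noisy signal with the shape of the input.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be non-negative")
  if (sigma == 0) return(signal)
  with_seed(seed, {
    n <- length(signal)
    out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}

#' Specification of a synthetic head phantom
#'
#' Describes a stylized head as nested ellipsoids on a voxel grid: a brain
#' envelope, a cortical GM shell, a WM interior, and ventricular CSF, with a
#' known ground-truth free-water field. The geometry is deliberately
#' non-anatomical: the pipeline's correctness claims are mask-algebraic and
#' statistical, not anatomical. The ground-truth FW field has a baseline in
#' WM, a smooth rise toward CSF/GM borders (emulating partial-volume
#' contamination), f = 1 in CSF, and elevated values inside the WMH lesions
#' carved from WM.
#'
#' @param shape grid shape (voxels); the default 64^3 at 1 mm mirrors the
#'   up-sampled 1 mm isotropic working space, where the default brain-mask
#'   erosion radius of 15 voxels leaves a usable safe-WM shell.
#' @param voxel_size voxel size in mm.
#' @param brain_radius_frac brain ellipsoid semi-axes as a fraction of the
#'   grid half-extent.
#' @param gm_shell_frac inner boundary of the GM shell as a fraction of the
#'   brain radius.
#' @param vent_radius_frac ventricular CSF semi-axes as a fraction of the
#'   grid half-extent.
#' @param f_wm baseline ground-truth FW fraction in WM.
#' @param f_texture_sd SD of the smooth spatial variation of the WM FW field
#'   around its baseline. Real white matter shows continuous voxelwise FW
#'   heterogeneity; without it the relative-FW measure would be a step
#'   function of the baseline. Implemented as a box-smoothed Gaussian random
#'   field, standardised within WM.
#' @param f_gm ground-truth FW fraction in the GM shell.
#' @param f_gradient_width,f_gradient_amp width (voxels) and amplitude of the
#'   near-CSF/GM FW rise inside WM.
#' @param n_wmh number of WMH lesions carved from WM.
#' @param wmh_radius_range integer range of lesion radii (voxels).
#' @param f_wmh ground-truth FW fraction inside lesions.
#' @param wm_eigs tissue-tensor eigenvalues in WM (mm^2/s), axially symmetric
#'   about a principal direction that varies smoothly across the volume.
#' @param d_gm,d_csf isotropic tissue diffusivities for GM and CSF (mm^2/s).
#' @param s0 b = 0 signal level.
#' @param rician_sigma Rician noise SD in signal units; the default gives
#'   SNR = 30 at b = 0, a typical clinical DWI level.
#' @param n_dirs,bval,n_b0 gradient scheme, see [make_gradient_scheme()].
#' @param seed integer seed driving every random element of the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = c(1, 1, 1),
                         brain_radius_frac = 0.9, gm_shell_frac = 0.85,
                         vent_radius_frac = 0.3,
                         f_wm = 0.15, f_texture_sd = 0.08, f_gm = 0.3,
                         f_gradient_width = 3, f_gradient_amp = 0.25,
                         n_wmh = 3, wmh_radius_range = c(1, 2), f_wmh = 0.6,
                         wm_eigs = c(1.5e-3, 0.4e-3, 0.4e-3),
                         d_gm = 0.8e-3, d_csf = 3.0e-3,
                         s0 = 100, rician_sigma = s0 / 30,
                         n_dirs = 41, bval = 1000, n_b0 = 1,
                         seed = 1L) {
  fvals <- c(f_wm, f_gm, f_wmh, f_gm + f_gradient_amp)
  if (any(fvals < 0 | fvals > 1))
    stop("all ground-truth FW fractions must lie in [0, 1]")
  if (!(vent_radius_frac < gm_shell_frac * brain_radius_frac))
    stop("ventricles must fit inside the WM interior")
  if (length(wm_eigs) != 3L || any(wm_eigs <= 0))
    stop("'wm_eigs' must be 3 positive eigenvalues")
  structure(list(
    shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
    brain_radius_frac = brain_radius_frac, gm_shell_frac = gm_shell_frac,
    vent_radius_frac = vent_radius_frac, f_wm = f_wm,
    f_texture_sd = f_texture_sd, f_gm = f_gm,
    f_gradient_width = f_gradient_width, f_gradient_amp = f_gradient_amp,
    n_wmh = as.integer(n_wmh), wmh_radius_range = as.integer(wmh_radius_range),
    f_wmh = f_wmh, wm_eigs = wm_eigs, d_gm = d_gm, d_csf = d_csf,
    s0 = s0, rician_sigma = rician_sigma, n_dirs = as.integer(n_dirs),
    bval = bval, n_b0 = as.integer(n_b0), seed = as.integer(seed)),
    class = "phantom_spec")
}

# Internal: 3^3 box smoothing of a numeric array by FFT convolution
# (zero-padded borders), applied `passes` times.
.smooth3 <- function(a, passes = 1L) {
  dims <- dim(a)
  pd <- vapply(dims + 2L * passes, function(n) stats::nextn(n, c(2, 3, 5)), 0)
  K <- array(0, pd)
  kidx <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %%
    matrix(pd, 27L, 3L, byrow = TRUE) + 1L
  K[kidx] <- 1 / 27
  fK <- stats::fft(K)
  for (p in seq_len(passes)) {
    A <- array(0, pd)
    A[seq_len(dims[1L]), seq_len(dims[2L]), seq_len(dims[3L])] <- a
    a <- Re(stats::fft(stats::fft(A) * fK, inverse = TRUE))[
      seq_len(dims[1L]), seq_len(dims[2L]), seq_len(dims[3L])] / prod(pd)
  }
  a
}

# Internal: normalized ellipsoid coordinate rho for every voxel; rho <= 1 is
# inside an ellipsoid with the given semi-axes (voxels) about the grid centre.
.ellipsoid_rho <- function(shape, semi_axes) {
  ctr <- (shape + 1) / 2
  x <- (seq_len(shape[1L]) - ctr[1L]) / semi_axes[1L]
  y <- (seq_len(shape[2L]) - ctr[2L]) / semi_axes[2L]
  z <- (seq_len(shape[3L]) - ctr[3L]) / semi_axes[3L]
  sqrt(outer(outer(x^2, y^2, "+"), z^2, "+"))
}

#' Generate a synthetic phantom
#'
#' Builds the tissue masks, the ground-truth FW field and the Rician-noised
#' single-shell DWI series described by a [phantom_spec()]. The DWI signal is
#' generated voxelwise from the forward bi-tensor model
#' ([predict_fw_signal()]) using the ground-truth fraction and the
#' region-dependent tissue tensor. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `fw_phantom`: a list with `tissues`
#'   ([tissue_maps()]), `true_f` ([scalar_volume()], `NA` outside the brain),
#'   `dwi` ([dwi_series()]) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- as.integer(spec$shape)
    grid <- image_grid(shape, spec$voxel_size)
    half <- shape / 2
    rho_b <- .ellipsoid_rho(shape, spec$brain_radius_frac * half)
    rho_v <- .ellipsoid_rho(shape, spec$vent_radius_frac * half)
    brain <- rho_b <= 1
    csf <- rho_v <= 1
    gm <- brain & rho_b > spec$gm_shell_frac & !csf
    wm <- brain & !gm & !csf
    if (!any(wm)) stop("phantom regions do not fit the grid: no WM voxels")
    mk <- function(v) binary_mask(v, grid)

    # ground-truth FW field: WM baseline + smooth texture, rising toward the
    # CSF/GM border, f = 1 in CSF
    f <- array(NA_real_, shape)
    f[wm] <- spec$f_wm
    if (spec$f_texture_sd > 0) {
      tex <- .smooth3(array(stats::rnorm(prod(shape)), shape), passes = 2L)
      tex <- tex / stats::sd(tex[wm])
      f[wm] <- f[wm] + spec$f_texture_sd * tex[wm]
    }
    f[gm] <- spec$f_gm
    f[csf] <- 1
    width <- as.integer(spec$f_gradient_width)
    if (width > 0L && spec$f_gradient_amp > 0) {
      border <- csf | gm
      se1 <- make_ball(1)
      prev <- mk(border)
      for (d in seq_len(width)) {
        cur <- dilate(prev, se1)
        ring <- cur & !prev & wm
        f[ring] <- f[ring] + spec$f_gradient_amp * (width - d + 1) / width
        prev <- cur
      }
    }
    f[wm] <- pmin(pmax(f[wm], 0.01), 0.995)

    # WMH lesions carved from WM, away from the CSF/GM border
    wmh <- array(FALSE, shape)
    if (spec$n_wmh > 0L) {
      rmax <- max(spec$wmh_radius_range)
      interior <- wm & !dilate(mk(csf | gm), make_ball(rmax + 1))
      cand <- which(interior)
      if (length(cand) >= spec$n_wmh) {
        ctrs <- cand[sample.int(length(cand), spec$n_wmh)]
        for (cl in ctrs) {
          r <- sample(seq.int(spec$wmh_radius_range[1L],
                              spec$wmh_radius_range[2L]), 1L)
          pos <- arrayInd(cl, shape)
          offs <- make_ball(r)$offsets
          vox <- sweep(offs, 2L, as.integer(pos), "+")
          ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
            vox[, 2] >= 1 & vox[, 2] <= shape[2] &
            vox[, 3] >= 1 & vox[, 3] <= shape[3]
          vox <- vox[ok, , drop = FALSE]
          lin <- vox[, 1] + (vox[, 2] - 1L) * shape[1L] +
            (vox[, 3] - 1L) * shape[1L] * shape[2L]
          lin <- lin[wm[lin]]
          wmh[lin] <- TRUE
        }
        f[wmh] <- spec$f_wmh
      } else {
        warning("not enough interior WM to place WMH lesions; none placed")
      }
    }

    # per-voxel tissue tensors inside the brain
    idx <- which(brain)
    pos <- arrayInd(idx, shape)
    theta <- pi * pos[, 3L] / shape[3L]          # smoothly varying principal axis
    phi <- pi * pos[, 2L] / shape[2L]
    dir <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    l1 <- spec$wm_eigs[1L]; l23 <- mean(spec$wm_eigs[2:3])
    D6 <- cbind(l23 + (l1 - l23) * dir[, 1L]^2,
                (l1 - l23) * dir[, 1L] * dir[, 2L],
                (l1 - l23) * dir[, 1L] * dir[, 3L],
                l23 + (l1 - l23) * dir[, 2L]^2,
                (l1 - l23) * dir[, 2L] * dir[, 3L],
                l23 + (l1 - l23) * dir[, 3L]^2)
    iso <- function(d) cbind(d, 0, 0, d, 0, d)
    in_gm <- gm[idx]; in_csf <- csf[idx]
    D6[in_gm, ] <- matrix(iso(spec$d_gm), sum(in_gm), 6L, byrow = TRUE)
    D6[in_csf, ] <- matrix(iso(spec$d_csf), sum(in_csf), 6L, byrow = TRUE)

    gtab <- make_gradient_scheme(spec$n_dirs, spec$bval, spec$n_b0)
    Q <- .tensor_design(gtab)
    aw <- exp(-gtab$bvals * 3.0e-3)
    att_t <- exp(-tcrossprod(D6, Q))
    fv <- f[idx]
    sig <- spec$s0 * ((1 - fv) * att_t +
                        fv * matrix(aw, length(idx), length(gtab), byrow = TRUE))
    signal <- array(0, c(shape, length(gtab)))
    for (k in seq_len(length(gtab))) signal[, , , k][idx] <- sig[, k]
    if (spec$rician_sigma > 0)
      signal <- add_rician_noise(signal, spec$rician_sigma)

    structure(list(
      tissues = tissue_maps(mk(wm), mk(gm), mk(csf), mk(brain), mk(wmh)),
      true_f = scalar_volume(f, grid, units = "fraction"),
      dwi = dwi_series(signal, grid, gtab),
      spec = spec
    ), class = "fw_phantom")
  })
}

#' @export
print.fw_phantom <- function(x, ...) {
  cat("<fw_phantom>\n")
  print(x$tissues)
  print(x$dwi)
  invisible(x)
}

#' Slab phantom for fit validation
#'
#' A simpler phantom than [make_phantom()]: the grid is divided into slabs
#' along the third axis, one per requested ground-truth FW level, with one
#' fixed anisotropic tissue tensor everywhere. This isolates the parameter
#' recovery of the bi-tensor fit from any geometry effects, which is exactly
#' what a recovery benchmark wants.
#'
#' @param shape grid shape.
#' @param f_levels ground-truth FW fractions, one per slab.
#' @param eigs tissue-tensor eigenvalues (mm^2/s); principal axis along x.
#' @param s0 b = 0 signal level.
#' @param rician_sigma noise SD (0 for noise-free).
#' @param gtab gradient scheme; defaults to [make_gradient_scheme()].
#' @param seed seed for the noise draw.
#' @return list with `dwi` ([dwi_series()]), `true_f` ([scalar_volume()]),
#'   `mask` (all-true [binary_mask()]) and `slab` (integer array of slab
#'   indices).
#' @export
make_slab_phantom <- function(shape = c(40, 40, 44),
                              f_levels = seq(0, 1, by = 0.1),
                              eigs = c(1.5e-3, 0.4e-3, 0.4e-3),
                              s0 = 100, rician_sigma = 0,
                              gtab = make_gradient_scheme(), seed = 1L) {
  shape <- as.integer(shape)
  nl <- length(f_levels)
  if (shape[3L] < nl) stop("third axis too short for the requested slabs")
  grid <- image_grid(shape)
  slab_of_z <- pmin(ceiling(seq_len(shape[3L]) / (shape[3L] / nl)), nl)
  slab <- array(rep(slab_of_z, each = shape[1L] * shape[2L]), shape)
  f <- array(f_levels[slab], shape)
  D6 <- c(eigs[1L], 0, 0, eigs[2L], 0, eigs[3L])
  att_t <- exp(-as.vector(.tensor_design(gtab) %*% D6))
  aw <- exp(-gtab$bvals * 3.0e-3)
  fv <- as.vector(f)
  sig <- s0 * (outer(1 - fv, att_t) + outer(fv, aw))
  signal <- array(sig, c(shape, length(gtab)))
  if (rician_sigma > 0)
    signal <- add_rician_noise(signal, rician_sigma, seed = seed)
  list(dwi = dwi_series(signal, grid, gtab),
       true_f = scalar_volume(f, grid, units = "fraction"),
       mask = binary_mask(array(TRUE, shape), grid),
       slab = slab)
}

#' Specification of a synthetic cohort
#'
#' Statistical structure of a three-group study: group sizes, additive
#' group offsets on the WM baseline FW (the effect of interest, ordered
#' NC < MCI < AD), per-subject jitter on that offset, and group-dependent
#' demographics. Defaults mirror the clinical cohort this pipeline was
#' designed around: 81 NC / 103 MCI / 42 AD, ages near 79, the observed
#' male/female ratios, and WMH burden increasing along the disease continuum.
#'
#' @param n_per_group named integer vector of subjects per group.
#' @param f_offsets named additive offsets applied to the phantom's baseline
#'   WM free-water fraction per group.
#' @param offset_jitter_sd SD of the per-subject Gaussian jitter on the
#'   offset (keeps within-group variance realistic without drowning the
#'   between-group effect).
#' @param age_mean,age_sd per-group age distribution parameters (years).
#' @param p_male per-group probability of male gender.
#' @param wmh_rate per-group Poisson rate for the number of WMH lesions
#'   beyond the first (every subject gets at least one lesion so lesion
#'   volume stays positive for log-scale analysis).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(NC = 81, MCI = 103, AD = 42),
                        f_offsets = c(NC = 0, MCI = 0.02, AD = 0.04),
                        offset_jitter_sd = 0.005,
                        age_mean = c(NC = 78.46, MCI = 79.0, AD = 79.38),
                        age_sd = c(NC = 6.11, MCI = 7.62, AD = 7.78),
                        p_male = c(NC = 38 / 81, MCI = 69 / 103, AD = 25 / 42),
                        wmh_rate = c(NC = 1, MCI = 2, AD = 3),
                        seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("'n_per_group' must be a named vector")
  if (any(n_per_group < 2)) stop("every group needs at least 2 subjects")
  for (arg in list(f_offsets, age_mean, age_sd, p_male, wmh_rate))
    if (!all(groups %in% names(arg)))
      stop("all per-group parameters must be named for every group")
  structure(list(groups = groups,
                 n_per_group = n_per_group, f_offsets = f_offsets,
                 offset_jitter_sd = offset_jitter_sd,
                 age_mean = age_mean, age_sd = age_sd, p_male = p_male,
                 wmh_rate = wmh_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Internal: deterministic per-subject plan (ids, demographics, per-subject
# baseline f and sub-seeds) for a cohort.
.cohort_plan <- function(pspec, cspec) {
  with_seed(cspec$seed, {
    rows <- list()
    for (g in cspec$groups) {
      n <- cspec$n_per_group[[g]]
      for (i in seq_len(n)) {
        off <- cspec$f_offsets[[g]] + stats::rnorm(1, 0, cspec$offset_jitter_sd)
        f_wm <- min(max(pspec$f_wm + off, 0), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%03d", g, i), group = g,
          age = round(stats::rnorm(1, cspec$age_mean[[g]], cspec$age_sd[[g]]), 1),
          gender = if (stats::runif(1) < cspec$p_male[[g]]) "M" else "F",
          f_wm = f_wm,
          n_wmh = 1L + stats::rpois(1, cspec$wmh_rate[[g]]),
          seed = sample.int(.Machine$integer.max - 1L, 1L),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Internal: phantom spec for one planned subject.
.subject_spec <- function(pspec, plan_row) {
  sp <- pspec
  sp$f_wm <- plan_row$f_wm
  sp$n_wmh <- plan_row$n_wmh
  sp$seed <- plan_row$seed
  sp
}

#' Generate a synthetic cohort with known ground truth
#'
#' One phantom per subject, with the group offset (plus subject jitter)
#' applied to the baseline WM free-water fraction and a group-dependent WMH
#' lesion count. The ground-truth metric table is computed from the true FW
#' field (not from any fit) with exactly the metric functions used on fitted
#' data, so pipeline output can be compared against it voxel-for-voxel.
#'
#' @param pspec a [phantom_spec()]; per-subject fields (`f_wm`, `n_wmh`,
#'   `seed`) are overridden by the cohort plan.
#' @param cspec a [cohort_spec()].
#' @param dir optional output directory; when given, each subject's DWI,
#'   gradient files and masks are written as a NIfTI/bval/bvec bundle indexed
#'   by a `manifest.json`, together with `demographics.csv` and
#'   `ground_truth.csv`.
#' @param keep `"all"` keeps every subject's phantom in memory (only
#'   advisable for small grids), `"truth"` (default) keeps just the
#'   demographics and ground-truth tables.
#' @param r_small,r_brain,wmh_dilation,threshold mask radii and rFW threshold
#'   used for the ground-truth metric table.
#' @return object of class `fw_cohort`: `demographics`, `truth` (ground-truth
#'   metric records), `plan`, and (if kept) `subjects`.
#' @export
make_cohort <- function(pspec, cspec, dir = NULL, keep = c("truth", "all"),
                        r_small = 1, r_brain = 15, wmh_dilation = 2,
                        threshold = 0.1) {
  stopifnot(inherits(pspec, "phantom_spec"), inherits(cspec, "cohort_spec"))
  keep <- match.arg(keep)
  plan <- .cohort_plan(pspec, cspec)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  subjects <- if (keep == "all") vector("list", nrow(plan)) else NULL
  manifest <- list()
  for (i in seq_len(nrow(plan))) {
    ph <- make_phantom(.subject_spec(pspec, plan[i, ]))
    wm_safe <- build_wm_safe(ph$tissues, r_small = r_small, r_brain = r_brain)
    wmh_exp <- expand_wmh(ph$tissues$wmh, radius = wmh_dilation)
    truth[[i]] <- subject_metrics(ph$true_f, ph$tissues, wm_safe, wmh_exp,
                                  threshold = threshold,
                                  subject_id = plan$subject_id[i])
    if (!is.null(dir)) {
      sd <- file.path(dir, plan$subject_id[i])
      dir.create(sd, showWarnings = FALSE)
      write_dwi(ph$dwi, file.path(sd, "dwi.nii.gz"),
                file.path(sd, "dwi.bval"), file.path(sd, "dwi.bvec"))
      for (nm in c("wm", "gm", "csf", "brain", "wmh"))
        write_volume(ph$tissues[[nm]], file.path(sd, paste0(nm, ".nii.gz")))
      write_volume(ph$true_f, file.path(sd, "true_f.nii.gz"))
      manifest[[plan$subject_id[i]]] <- list(
        dir = plan$subject_id[i], group = plan$group[i],
        files = c("dwi.nii.gz", "dwi.bval", "dwi.bvec", "wm.nii.gz",
                  "gm.nii.gz", "csf.nii.gz", "brain.nii.gz", "wmh.nii.gz",
                  "true_f.nii.gz"))
    }
    if (keep == "all") subjects[[i]] <- ph
  }
  truth <- do.call(rbind, truth)
  demographics <- plan[, c("subject_id", "group", "age", "gender")]
  if (!is.null(dir)) {
    utils::write.csv(demographics, file.path(dir, "demographics.csv"),
                     row.names = FALSE)
    write_metrics_csv(truth, file.path(dir, "ground_truth.csv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(demographics = demographics, truth = truth, plan = plan,
                 subjects = subjects, pspec = pspec, cspec = cspec),
            class = "fw_cohort")
}

#' @export
print.fw_cohort <- function(x, ...) {
  cat("<fw_cohort>\n")
  print(table(x$demographics$group))
  invisible(x)
}
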