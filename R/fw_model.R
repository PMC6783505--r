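#' Configuration of the bi-tensor free-water fit
#'
#' Bundles every tunable of the constrained single-shell fit. The model writes
#' the signal at gradient k as
#' \deqn{S_k = S_0 [ (1-f) e^{-b_k g_k' D g_k} + f e^{-b_k d_w} ]}
#' where `f` is the free-water fraction, `D` the tissue diffusion tensor and
#' `d_w` the diffusivity of free water. Single-shell data cannot identify all
#' of this without constraints, so the fit bounds the tissue eigenvalues,
#' bounds `f`, and (optionally) smooths the `f` field spatially.
#'
#' @param d_water isotropic free-water diffusivity, mm^2/s. Default 3.0e-3,
#'   the accepted value for water at body temperature.
#' @param eig_min,eig_max tissue-tensor eigenvalue bounds, mm^2/s. Must
#'   satisfy `0 < eig_min < eig_max < d_water`, which is what makes `f`
#'   identifiable at the free-water end of the range.
#' @param f_bounds allowed interval for the free-water fraction, inside [0,1].
#' @param max_iter outer iterations of the fit/smooth alternation when
#'   `lambda_reg > 0`.
#' @param tol convergence tolerance: stop when the total objective decreases
#'   by less than this between outer iterations.
#' @param lambda_reg weight of the spatial penalty `lambda_reg * sum ||grad f||^2`
#'   over the mask (6-neighbourhood differences). 0 disables smoothing. The
#'   objective is computed on s0-normalised signal, so the weight is
#'   scale-free with respect to signal amplitude.
#' @param f_grid_n number of grid points spanning `f_bounds` in the
#'   variable-projection search over `f` (parabolic refinement sharpens the
#'   final estimate below the grid spacing).
#' @param md_range plausible range for the tissue compartment's mean
#'   diffusivity (mm^2/s), default `c(0.6e-3, 0.9e-3)`, the literature band
#'   for healthy white matter. Without a tissue prior the single-shell
#'   bi-tensor model is not identifiable in noise: the tissue tensor can
#'   absorb the free-water signal entirely and the fit collapses to f = 0.
#'   The prior is a dead-zone penalty
#'   `md_prior_weight * (b_mean * dist(MD, md_range))^2` added to the
#'   objective used to select f — zero while the profiled tissue MD stays in
#'   the band, so noise-free recovery is not distorted, quadratic outside it.
#' @param md_prior_weight weight of the MD dead-zone penalty on the
#'   s0-normalised objective (dimensionless; the `b_mean * MD` scaling makes
#'   the penalised quantity order 1). 0 disables the prior.
#' @param d_tissue_prior tissue diffusivity prior (mm^2/s) used only by the
#'   initial estimate of `f`.
#' @param f_init_clip clip window applied to the initial `f` estimate, keeping
#'   the start away from the degenerate boundaries.
#' @param seed integer seed recorded for any randomized element of the fit
#'   (the default fitter is deterministic; the seed is stored so downstream
#'   pipelines have a single reproducibility knob).
#' @return object of class `fw_fit_config`.
#' @export
fw_fit_config <- function(d_water = 3.0e-3,
                          eig_min = 0.1e-3, eig_max = 2.5e-3,
                          f_bounds = c(0, 1),
                          max_iter = 10L, tol = 1e-6,
                          lambda_reg = 0.1,
                          f_grid_n = 51L,
                          md_range = c(0.6e-3, 0.9e-3),
                          md_prior_weight = 0.5,
                          d_tissue_prior = 0.6e-3,
                          f_init_clip = c(0.05, 0.95),
                          seed = 1L) {
  if (!(eig_min > 0 && eig_min < eig_max))
    stop("need 0 < eig_min < eig_max")
  if (!(d_water > eig_max))
    stop("'d_water' must exceed 'eig_max' (free water diffuses faster than tissue)")
  if (length(f_bounds) != 2L || f_bounds[1] < 0 || f_bounds[2] > 1 ||
      f_bounds[1] >= f_bounds[2])
    stop("'f_bounds' must be an interval inside [0, 1]")
  if (lambda_reg < 0) stop("'lambda_reg' must be >= 0")
  if (md_prior_weight < 0) stop("'md_prior_weight' must be >= 0")
  if (length(md_range) != 2L || md_range[1] >= md_range[2])
    stop("'md_range' must be an increasing interval")
  if (md_prior_weight > 0 &&
      !(md_range[1] > eig_min && md_range[2] < eig_max))
    stop("'md_range' must lie inside the eigenvalue bounds")
  if (f_grid_n < 5L) stop("'f_grid_n' must be at least 5")
  structure(list(d_water = d_water, eig_min = eig_min, eig_max = eig_max,
                 f_bounds = as.numeric(f_bounds),
                 max_iter = as.integer(max_iter), tol = tol,
                 lambda_reg = lambda_reg, f_grid_n = as.integer(f_grid_n),
                 md_range = as.numeric(md_range),
                 md_prior_weight = md_prior_weight,
                 d_tissue_prior = d_tissue_prior,
                 f_init_clip = as.numeric(f_init_clip),
                 seed = as.integer(seed)),
            class = "fw_fit_config")
}

#' @export
print.fw_fit_config <- function(x, ...) {
  cat(sprintf(paste0("<fw_fit_config> d_water %g mm^2/s; eigenvalues [%g, %g];",
                     " f in [%g, %g]; lambda_reg %g; grid %d; max_iter %d\n"),
              x$d_water, x$eig_min, x$eig_max, x$f_bounds[1], x$f_bounds[2],
              x$lambda_reg, x$f_grid_n, x$max_iter))
  invisible(x)
}

# Internal: m x 6 design matrix mapping the unique tensor components
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) to b * g' D g per gradient.
.tensor_design <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
        g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2) * b
}

#' Forward bi-tensor signal prediction
#'
#' Evaluates the two-compartment model for one voxel: an anisotropic tissue
#' tensor weighted `1 - f` plus an isotropic free-water compartment of
#' diffusivity `d_water` weighted `f`.
#'
#' @param f free-water fraction in [0, 1].
#' @param tensor length-6 tissue tensor, order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz),
#'   mm^2/s.
#' @param s0 signal at b = 0 (must be positive).
#' @param gtab a [gradient_table()].
#' @param d_water free-water diffusivity, mm^2/s.
#' @return numeric vector of predicted signal, one entry per gradient; equals
#'   `s0` exactly wherever b = 0.
#' @export
#' @examples
#' gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
#' predict_fw_signal(1, rep(0, 6), 100, gt) # 100, 100*exp(-3)
predict_fw_signal <- function(f, tensor, s0, gtab, d_water = 3.0e-3) {
  if (!is.finite(f) || f < 0 || f > 1)
    stop("'f' must lie in [0, 1]")
  if (length(tensor) != 6L) stop("'tensor' must have 6 components")
  if (!is.finite(s0) || s0 <= 0) stop("'s0' must be positive")
  q <- .tensor_design(gtab)
  atten_tissue <- exp(-as.vector(q %*% tensor))
  atten_water <- exp(-gtab$bvals * d_water)
  s0 * ((1 - f) * atten_tissue + f * atten_water)
}

# Internal: clip the eigenvalues of 6-component tensors (rows of D6) into
# [eig_min, eig_max]; returns the clipped rows. Symmetric 3x3 eigen per voxel.
.clip_tensor_eigs <- function(D6, eig_min, eig_max) {
  n <- nrow(D6)
  out <- D6
  for (i in seq_len(n)) {
    d <- D6[i, ]
    if (any(!is.finite(d))) {
      out[i, ] <- c(eig_min, 0, 0, eig_min, 0, eig_min)
      next
    }
    M <- matrix(c(d[1], d[2], d[3],
                  d[2], d[4], d[5],
                  d[3], d[5], d[6]), 3, 3)
    e <- eigen(M, symmetric = TRUE)
    if (all(e$values >= eig_min - 1e-12) && all(e$values <= eig_max + 1e-12)) {
      ev <- pmin(pmax(e$values, eig_min), eig_max)
      if (identical(ev, e$values)) next
    }
    ev <- pmin(pmax(e$values, eig_min), eig_max)
    Mc <- e$vectors %*% (ev * t(e$vectors))
    out[i, ] <- c(Mc[1, 1], Mc[1, 2], Mc[1, 3], Mc[2, 2], Mc[2, 3], Mc[3, 3])
  }
  out
}

#' Initial estimate for the bi-tensor fit of one voxel
#'
#' `s0` is the mean of the b = 0 signals. The initial fraction `f0` places the
#' voxel's geometric-mean attenuation on the log scale between a tissue prior
#' `exp(-b * d_tissue_prior)` and the free-water value `exp(-b * d_water)`,
#' then clips to the configured window (default [0.05, 0.95]) to keep the
#' optimizer off the degenerate boundaries. The initial tensor is a standard
#' log-linear fit of the signal after removing the `f0` water fraction, with
#' eigenvalues clipped to the configured bounds.
#'
#' @param dwi_voxel numeric signal vector for one voxel (one entry per
#'   gradient).
#' @param gtab a [gradient_table()]; needs at least one b = 0 entry and at
#'   least 6 nonzero-b entries.
#' @param config a [fw_fit_config()].
#' @return list with `f0`, `tensor0` (length 6), `s0`, and `fittable`
#'   (`FALSE` when `s0 <= 0` or the signal is unusable).
#' @export
init_fw_estimate <- function(dwi_voxel, gtab, config = fw_fit_config()) {
  b0 <- is_b0(gtab)
  if (sum(b0) < 1L) stop("gradient table has no b = 0 entry")
  if (sum(!b0) < 6L) stop("need at least 6 nonzero-b measurements")
  s0 <- mean(dwi_voxel[b0])
  if (!is.finite(s0) || s0 <= 0 || any(!is.finite(dwi_voxel)))
    return(list(f0 = NA_real_, tensor0 = rep(NA_real_, 6), s0 = s0,
                fittable = FALSE))
  b_nz <- gtab$bvals[!b0]
  A <- pmax(dwi_voxel[!b0] / s0, 1e-8)
  logA <- mean(log(A))                      # geometric mean, log domain
  b_bar <- mean(b_nz)
  log_tis <- -b_bar * config$d_tissue_prior
  log_wat <- -b_bar * config$d_water
  f0 <- (logA - log_tis) / (log_wat - log_tis)
  f0 <- min(max(f0, config$f_init_clip[1]), config$f_init_clip[2])
  aw <- exp(-b_nz * config$d_water)
  At <- (A - f0 * aw) / (1 - f0)
  At <- pmin(pmax(At, exp(-b_nz * config$eig_max)), exp(-b_nz * config$eig_min))
  Q <- .tensor_design(gtab)[!b0, , drop = FALSE]
  d <- -solve(crossprod(Q), crossprod(Q, log(At)))
  tensor0 <- .clip_tensor_eigs(matrix(d, 1L), config$eig_min, config$eig_max)[1L, ]
  list(f0 = f0, tensor0 = tensor0, s0 = s0, fittable = TRUE)
}

# Internal fitting engine shared by fit_fw_voxel and fit_freewater.
#
# S:       nvox x ngrad signal matrix (already restricted to mask voxels)
# gtab:    gradient table
# config:  fw_fit_config
# nb:      optional neighbour structure (list(idx = nvox x 6 matrix of row
#          indices into S, 0 = none)) enabling the spatial penalty
#
# Strategy: variable projection. For each candidate f on a grid, the tissue
# attenuation (A - f*aw)/(1-f) is clamped entrywise into the attenuation band
# implied by the eigenvalue bounds and fitted by an ordinary log-linear tensor
# regression (one shared projector, so the whole grid sweep is matrix
# algebra). f is chosen per voxel to minimise the signal-domain SSE, plus,
# when lambda_reg > 0, an ICM pass over the cached SSE grid implementing the
# smoothness penalty. A final parabolic refinement interpolates between grid
# points, and the tensor is re-fit at the selected f with eigenvalue clipping.
.fw_fit_engine <- function(S, gtab, config, nb = NULL) {
  b0 <- is_b0(gtab)
  if (sum(b0) < 1L) stop("gradient table has no b = 0 entry")
  if (sum(!b0) < 6L) stop("need at least 6 nonzero-b measurements")
  nvox <- nrow(S)
  m <- sum(!b0)
  b_nz <- gtab$bvals[!b0]
  aw <- exp(-b_nz * config$d_water)
  at_lo <- exp(-b_nz * config$eig_max)
  at_hi <- exp(-b_nz * config$eig_min)
  Q <- .tensor_design(gtab)[!b0, , drop = FALSE]
  b_bar <- mean(b_nz)
  w_md <- config$md_prior_weight
  md_lo <- config$md_range[1]
  md_hi <- config$md_range[2]
  Mi <- chol2inv(chol(crossprod(Q)))        # OLS normal-equation inverse

  s0 <- rowMeans(S[, b0, drop = FALSE])
  ok <- is.finite(s0) & s0 > 0 & rowSums(!is.finite(S)) == 0L
  res <- list(f = rep(NA_real_, nvox),
              tensor = matrix(NA_real_, nvox, 6L),
              s0 = s0,
              converged = rep(FALSE, nvox),
              n_iter = rep(0L, nvox),
              sse = rep(NA_real_, nvox))
  if (!any(ok)) return(res)

  A <- S[ok, !b0, drop = FALSE] / s0[ok]
  nf <- config$f_grid_n
  f_grid <- seq(config$f_bounds[1], config$f_bounds[2], length.out = nf)
  h <- f_grid[2] - f_grid[1]
  n_ok <- nrow(A)

  aw_row <- matrix(aw, n_ok, m, byrow = TRUE)
  lo_row <- matrix(at_lo, n_ok, m, byrow = TRUE)
  hi_row <- matrix(at_hi, n_ok, m, byrow = TRUE)

  tensor_at <- function(At) {
    # log-linear tensor fit, one shared 6x6 solve for all voxels
    -(log(At) %*% Q) %*% Mi
  }
  md_penalty <- function(Dc) {
    # dead-zone prior: free inside the plausible tissue-MD band
    md <- (Dc[, 1] + Dc[, 4] + Dc[, 6]) / 3
    w_md * (b_bar * pmax(0, pmax(md_lo - md, md - md_hi)))^2
  }
  sse_at <- function(fv) {
    # fv: scalar or length-n_ok vector of candidate fractions
    if (length(fv) == 1L) fv <- rep(fv, n_ok)
    one <- fv >= 1 - 1e-9
    At <- (A - fv * aw_row) / pmax(1 - fv, 1e-9)
    At <- pmin(pmax(At, lo_row), hi_row)
    Dc <- tensor_at(At)                     # n_ok x 6 tensors
    predT <- exp(-tcrossprod(Dc, Q))
    predA <- (1 - fv) * predT + fv * aw_row
    out <- rowSums((A - predA)^2) + md_penalty(Dc)
    if (any(one))   # pure water: no tissue compartment, no tissue penalty
      out[one] <- rowSums((A[one, , drop = FALSE] -
                             matrix(aw, sum(one), m, byrow = TRUE))^2)
    out
  }

  SSE <- matrix(0, n_ok, nf)
  for (j in seq_len(nf)) SSE[, j] <- sse_at(f_grid[j])

  lam <- config$lambda_reg
  if (lam > 0 && !is.null(nb) && n_ok > 1L) {
    map <- integer(nvox); map[ok] <- seq_len(n_ok)   # S-row -> A-row
    nb_idx <- nb$idx
    # translate neighbour rows to A-rows, dropping unfittable neighbours
    nb_ok <- matrix(0L, n_ok, ncol(nb_idx))
    rows <- which(ok)
    for (k in seq_len(ncol(nb_idx))) {
      v <- nb_idx[rows, k]
      v[v > 0L & !ok[pmax(v, 1L)]] <- 0L
      nb_ok[, k] <- ifelse(v > 0L, map[pmax(v, 1L)], 0L)
    }
    nb_cnt <- rowSums(nb_ok > 0L)
    j_cur <- max.col(-SSE, ties.method = "first")
    f_cur <- f_grid[j_cur]
    obj_prev <- Inf
    it_done <- 0L
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      nb_sum <- numeric(n_ok)
      for (k in seq_len(ncol(nb_ok))) {
        idx <- nb_ok[, k]
        has <- idx > 0L
        nb_sum[has] <- nb_sum[has] + f_cur[idx[has]]
      }
      tot <- SSE + lam * (outer(nb_cnt, f_grid^2) - 2 * outer(nb_sum, f_grid))
      j_cur <- max.col(-tot, ties.method = "first")
      f_cur <- f_grid[j_cur]
      # global objective: data term + each neighbour pair once
      pair_pen <- 0
      for (k in seq_len(ncol(nb_ok))) {
        idx <- nb_ok[, k]
        has <- idx > 0L
        pair_pen <- pair_pen + sum((f_cur[has] - f_cur[idx[has]])^2)
      }
      obj <- sum(SSE[cbind(seq_len(n_ok), j_cur)]) + lam * pair_pen / 2
      it_done <- it
      if (obj_prev - obj < config$tol) { converged <- TRUE; break }
      obj_prev <- obj
    }
    # refine on the penalised objective
    f_hat <- .parabolic_refine(tot, j_cur, f_grid, h)
    res$converged[ok] <- converged
    res$n_iter[ok] <- it_done
  } else {
    j_cur <- max.col(-SSE, ties.method = "first")
    f_hat <- .parabolic_refine(SSE, j_cur, f_grid, h)
    res$converged[ok] <- TRUE
    res$n_iter[ok] <- 1L
  }

  # final tensor at the refined f, eigenvalues clipped into bounds
  one <- f_hat >= 1 - 1e-6
  At <- (A - f_hat * aw_row) / pmax(1 - f_hat, 1e-9)
  At <- pmin(pmax(At, lo_row), hi_row)
  Dc <- tensor_at(At)
  if (any(one))   # no tissue compartment left: report the minimal isotropic tensor
    Dc[one, ] <- matrix(c(config$eig_min, 0, 0, config$eig_min, 0, config$eig_min),
                        sum(one), 6L, byrow = TRUE)
  Dc <- .clip_tensor_eigs(Dc, config$eig_min, config$eig_max)
  predT <- exp(-tcrossprod(Dc, Q))
  predA <- (1 - f_hat) * predT + f_hat * aw_row
  if (any(one)) predA[one, ] <- matrix(aw, sum(one), m, byrow = TRUE)

  res$f[ok] <- f_hat
  res$tensor[ok, ] <- Dc
  res$sse[ok] <- rowSums((A - predA)^2)
  res
}

# Internal: vertex of the parabola through the best grid point and its two
# neighbours; falls back to the grid point at the edges or when the curvature
# is not positive. Result clamped to one grid step around the minimum.
.parabolic_refine <- function(OBJ, j, f_grid, h) {
  n <- nrow(OBJ)
  f_hat <- f_grid[j]
  interior <- j > 1L & j < length(f_grid)
  if (any(interior)) {
    i <- which(interior)
    y0 <- OBJ[cbind(i, j[i] - 1L)]
    y1 <- OBJ[cbind(i, j[i])]
    y2 <- OBJ[cbind(i, j[i] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(denom > 1e-300, 0.5 * h * (y0 - y2) / denom, 0)
    shift <- pmin(pmax(shift, -h), h)
    f_hat[i] <- f_grid[j[i]] + shift
  }
  pmin(pmax(f_hat, f_grid[1]), f_grid[length(f_grid)])
}

#' Fit the bi-tensor model to a single voxel
#'
#' @param dwi_voxel numeric signal vector, one entry per gradient.
#' @param gtab a [gradient_table()].
#' @param config a [fw_fit_config()]; the spatial penalty does not apply to a
#'   single voxel.
#' @return list with `f`, `tensor` (length 6), `s0`, `converged`, `n_iter`.
#'   Unfittable voxels (non-positive `s0`, all-zero or non-finite signal)
#'   return `f = NA`.
#' @export
fit_fw_voxel <- function(dwi_voxel, gtab, config = fw_fit_config()) {
  fit <- .fw_fit_engine(matrix(dwi_voxel, nrow = 1L), gtab, config)
  list(f = fit$f[1L], tensor = fit$tensor[1L, ], s0 = fit$s0[1L],
       converged = fit$converged[1L], n_iter = fit$n_iter[1L])
}
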