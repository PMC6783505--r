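# Internal: 6-neighbourhood structure over a logical mask array.
# Returns list(idx = nvox x 6 matrix of row indices into which(mask), 0 = no
# neighbour inside the mask/grid).
.mask_neighbours <- function(mask, dims) {
  lin <- which(mask)
  nvox <- length(lin)
  rowmap <- integer(prod(dims))
  rowmap[lin] <- seq_len(nvox)
  pos <- arrayInd(lin, dims)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  idx <- matrix(0L, nvox, 6L)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (k in 1:6) {
    np <- pos + matrix(offs[k, ], nvox, 3L, byrow = TRUE)
    inside <- np[, 1] >= 1L & np[, 1] <= dims[1L] &
      np[, 2] >= 1L & np[, 2] <= dims[2L] &
      np[, 3] >= 1L & np[, 3] <= dims[3L]
    nlin <- 1L + (np[, 1] - 1L) * strides[1L] + (np[, 2] - 1L) * strides[2L] +
      (np[, 3] - 1L) * strides[3L]
    idx[inside, k] <- rowmap[nlin[inside]]
  }
  list(idx = idx)
}

#' Fit the free-water bi-tensor model over a volume
#'
#' The central fitting function of the package. Every voxel inside `mask` is
#' fit with the constrained single-shell bi-tensor model (see
#' [fw_fit_config()] for the model and its constraints); when
#' `config$lambda_reg > 0` the per-voxel fits alternate with a spatial
#' smoothing step penalising `lambda_reg * sum ||grad f||^2` over the mask.
#' Voxels outside the mask, and unfittable voxels inside it (non-positive
#' b = 0 signal, non-finite values), carry `NA` in the resulting maps so they
#' propagate as missing rather than biasing metrics toward zero.
#'
#' @param dwi a [dwi_series()].
#' @param mask a [binary_mask()] on the DWI grid, or `NULL` to fit every
#'   voxel.
#' @param config a [fw_fit_config()].
#' @param keep_data keep the input series inside the returned object (needed
#'   by [residuals.freewater_fit()]).
#' @return an object of class `freewater_fit` with components `f_map`
#'   ([scalar_volume()], the free-water map), `tensor_map` (4-D array, 6
#'   tensor components per voxel), `s0_map`, `converged` and `n_iter` arrays,
#'   plus the mask, gradient table and configuration used.
#' @seealso [fit_fw_voxel()] for a single voxel, [write_freewater()] to save
#'   the maps as NIfTI-1.
#' @export
fit_freewater <- function(dwi, mask = NULL, config = fw_fit_config(),
                          keep_data = TRUE) {
  stopifnot(inherits(dwi, "dwi_series"))
  grid <- dwi$grid
  if (is.null(mask)) {
    mask <- binary_mask(array(TRUE, grid$shape), grid)
  } else {
    stopifnot(inherits(mask, "binary_mask"))
    assert_same_grid(dwi = dwi, mask = mask)
  }
  if (!any(mask)) stop("empty mask: nothing to fit")
  dims <- grid$shape
  lin <- which(mask)
  ngrad <- length(dwi$gtab)
  S <- matrix(dwi$signal, prod(dims), ngrad)[lin, , drop = FALSE]
  nb <- if (config$lambda_reg > 0) .mask_neighbours(mask, dims) else NULL
  fit <- with_seed(config$seed, .fw_fit_engine(S, dwi$gtab, config, nb = nb))

  fill <- function(vals, default = NA_real_) {
    a <- array(default, dims)
    a[lin] <- vals
    a
  }
  tensor_map <- array(NA_real_, c(dims, 6L))
  for (k in 1:6) tensor_map[, , , k][lin] <- fit$tensor[, k]

  structure(list(
    f_map = scalar_volume(fill(fit$f), grid, units = "fraction"),
    tensor_map = tensor_map,
    s0_map = scalar_volume(fill(fit$s0), grid, units = "signal"),
    converged = fill(as.numeric(fit$converged)) > 0,
    n_iter = fill(as.numeric(fit$n_iter), 0),
    sse = scalar_volume(fill(fit$sse), grid, units = "normalised SSE"),
    mask = mask,
    gtab = dwi$gtab,
    config = config,
    data = if (keep_data) dwi else NULL,
    call = match.call()
  ), class = "freewater_fit")
}

#' @export
print.freewater_fit <- function(x, ...) {
  n_mask <- sum(x$mask)
  f <- as.vector(x$f_map)[which(x$mask)]
  n_missing <- sum(is.na(f))
  cat("Free-water bi-tensor fit\n")
  cat(sprintf("  %d voxels in mask, %d unfittable\n", n_mask, n_missing))
  if (any(!is.na(f)))
    cat(sprintf("  f: median %.3f, IQR [%.3f, %.3f]\n",
                stats::median(f, na.rm = TRUE),
                stats::quantile(f, 0.25, na.rm = TRUE),
                stats::quantile(f, 0.75, na.rm = TRUE)))
  cat(sprintf("  spatial regularization: lambda = %g\n", x$config$lambda_reg))
  invisible(x)
}

#' @export
summary.freewater_fit <- function(object, ...) {
  idx <- which(object$mask)
  f <- as.vector(object$f_map)[idx]
  out <- list(
    n_mask = length(idx),
    n_missing = sum(is.na(f)),
    f_quantiles = stats::quantile(f, c(0, .05, .25, .5, .75, .95, 1),
                                  na.rm = TRUE),
    mean_f = mean(f, na.rm = TRUE),
    prop_converged = mean(object$converged[idx], na.rm = TRUE),
    mean_sse = mean(as.vector(object$sse)[idx], na.rm = TRUE),
    config = object$config
  )
  class(out) <- "summary.freewater_fit"
  out
}

#' @export
print.summary.freewater_fit <- function(x, ...) {
  cat("Free-water bi-tensor fit\n")
  cat(sprintf("  voxels: %d in mask (%d unfittable)\n", x$n_mask, x$n_missing))
  cat(sprintf("  mean f: %.4f\n", x$mean_f))
  cat("  f quantiles:\n")
  print(round(x$f_quantiles, 4))
  cat(sprintf("  converged: %.1f%%; mean normalised SSE: %.4g\n",
              100 * x$prop_converged, x$mean_sse))
  print(x$config)
  invisible(x)
}

#' @export
coef.freewater_fit <- function(object, ...) {
  idx <- which(object$mask)
  tens <- sapply(1:6, function(k) object$tensor_map[, , , k][idx])
  out <- cbind(f = as.vector(object$f_map)[idx],
               matrix(tens, ncol = 6,
                      dimnames = list(NULL, c("Dxx", "Dxy", "Dxz",
                                              "Dyy", "Dyz", "Dzz"))),
               s0 = as.vector(object$s0_map)[idx])
  rownames(out) <- idx
  out
}

#' Predicted DWI signal from a fitted free-water model
#'
#' @param object a `freewater_fit`.
#' @param gtab optional [gradient_table()] to predict on (defaults to the one
#'   used for fitting).
#' @param ... unused.
#' @return a [dwi_series()] of model-predicted signal; `NA` outside the mask
#'   and at unfittable voxels.
#' @export
predict.freewater_fit <- function(object, gtab = NULL, ...) {
  if (is.null(gtab)) gtab <- object$gtab
  grid <- as_image_grid(object$f_map)
  dims <- grid$shape
  idx <- which(object$mask & !is.na(object$f_map))
  q <- .tensor_design(gtab)
  aw <- exp(-gtab$bvals * object$config$d_water)
  tens <- sapply(1:6, function(k) object$tensor_map[, , , k][idx])
  f <- as.vector(object$f_map)[idx]
  s0 <- as.vector(object$s0_map)[idx]
  predT <- exp(-tcrossprod(matrix(tens, ncol = 6), q))
  pred <- s0 * ((1 - f) * predT + f * matrix(aw, length(idx), length(gtab$bvals),
                                             byrow = TRUE))
  out <- array(NA_real_, c(dims, length(gtab)))
  for (k in seq_len(length(gtab))) out[, , , k][idx] <- pred[, k]
  out[out < 0] <- 0
  structure(list(signal = out, grid = grid, gtab = gtab),
            class = "dwi_series")
}

#' @export
fitted.freewater_fit <- function(object, ...) predict(object)

#' Residuals of a fitted free-water model
#'
#' Observed minus model-predicted signal; requires the fit to have been run
#' with `keep_data = TRUE`.
#'
#' @param object a `freewater_fit`.
#' @param ... unused.
#' @return 4-D array of residuals (`NA` outside the fitted voxels).
#' @export
residuals.freewater_fit <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was run with keep_data = FALSE; residuals unavailable")
  object$data$signal - predict(object)$signal
}

#' Simulate DWI series from a fitted free-water model
#'
#' Draws Rician-noise replicates of the model-predicted signal, which is the
#' noise model of magnitude MR images.
#'
#' @param object a `freewater_fit`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param sigma Rician noise level in signal units; defaults to the RMS
#'   residual of the fit when data was kept, else 1.
#' @param ... unused.
#' @return list of [dwi_series()] objects of length `nsim`.
#' @export
simulate.freewater_fit <- function(object, nsim = 1, seed = NULL,
                                   sigma = NULL, ...) {
  pred <- predict(object)
  if (is.null(sigma)) {
    sigma <- if (!is.null(object$data))
      stats::sd(residuals(object), na.rm = TRUE) else 1
  }
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    s <- pred$signal
    okv <- !is.na(s)
    s[okv] <- add_rician_noise(s[okv], sigma)
    structure(list(signal = s, grid = pred$grid, gtab = pred$gtab),
              class = "dwi_series")
  }))
}

#' Plot a slice of the fitted free-water map
#'
#' @param x a `freewater_fit`.
#' @param slice axial (third-axis) slice index; defaults to the middle slice.
#' @param ... passed to [graphics::image()].
#' @export
plot.freewater_fit <- function(x, slice = NULL, ...) {
  dims <- as_image_grid(x$f_map)$shape
  if (is.null(slice)) slice <- ceiling(dims[3L] / 2)
  f <- unclass(x$f_map)[, , slice]
  graphics::image(seq_len(dims[1L]), seq_len(dims[2L]), f,
                  zlim = c(0, 1), asp = 1, xlab = "x (voxel)",
                  ylab = "y (voxel)",
                  main = sprintf("free-water fraction, slice z = %d", slice),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write the maps of a free-water fit as NIfTI-1
#'
#' Writes `<prefix>_fw.nii.gz` (FW fraction), `<prefix>_s0.nii.gz`,
#' `<prefix>_tensor.nii.gz` (4-D, 6 components) and
#' `<prefix>_converged.nii.gz` (byte volume).
#'
#' @param fit a `freewater_fit`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, named character vector of the written paths.
#' @export
write_freewater <- function(fit, dir, prefix = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- as_image_grid(fit$f_map)
  paths <- c(fw = file.path(dir, paste0(prefix, "_fw.nii.gz")),
             s0 = file.path(dir, paste0(prefix, "_s0.nii.gz")),
             tensor = file.path(dir, paste0(prefix, "_tensor.nii.gz")),
             converged = file.path(dir, paste0(prefix, "_converged.nii.gz")))
  write_volume(fit$f_map, paths["fw"])
  write_volume(fit$s0_map, paths["s0"])
  timg <- RNifti::asNifti(fit$tensor_map)
  RNifti::pixdim(timg) <- c(grid$voxel_size, 1)
  RNifti::qform(timg) <- structure(grid$affine, code = 2L)
  RNifti::sform(timg) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(timg, paths["tensor"], datatype = "float")
  conv <- binary_mask(array(fit$converged & !is.na(fit$converged), grid$shape),
                      grid)
  write_volume(conv, paths["converged"])
  invisible(paths)
}
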