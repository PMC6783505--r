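#' Discrete 3-D structuring element
#'
#' Builds the structuring element `R^n` used by the safe-WM mask equation: by
#' default the discrete Euclidean ball, i.e. all integer offsets `v` with
#' `||v||_2 <= radius`. A cube (Chebyshev ball) is available for sensitivity
#' checks, since "radius" is most faithfully read as Euclidean.
#'
#' @param radius non-negative integer radius in voxels.
#' @param type `"ball"` (Euclidean, default) or `"cube"` (Chebyshev).
#' @return object of class `struct_elem` with fields `radius`, `type` and
#'   `offsets` (k x 3 integer matrix containing the origin and symmetric
#'   under negation).
#' @export
#' @examples
#' nrow(make_ball(1)$offsets) # 7: origin + 6 face neighbours
#' nrow(make_ball(2)$offsets) # 33
make_ball <- function(radius, type = c("ball", "cube")) {
  type <- match.arg(type)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L) stop("'radius' must be a non-negative integer")
  r <- seq.int(-radius, radius)
  offs <- as.matrix(expand.grid(x = r, y = r, z = r))
  if (type == "ball")
    offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  dimnames(offs) <- NULL
  structure(list(radius = radius, type = type, offsets = offs),
            class = "struct_elem")
}

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf("<struct_elem> %s, radius %d, %d offsets\n",
              x$type, x$radius, nrow(x$offsets)))
  invisible(x)
}

# Internal: for each voxel x, the number of offsets v with mask[x + v] true.
# Computed by FFT convolution on a zero-padded grid, so voxels outside the
# field of view count as background. Counts are integers; FFT round-off is
# orders of magnitude below 0.5, so round() restores exactness.
.se_counts <- function(mask, se) {
  dims <- dim(mask)
  offs <- se$offsets
  mx <- apply(abs(offs), 2L, max)
  pd <- vapply(dims + 2L * mx, function(n) stats::nextn(n, c(2, 3, 5)), 0)
  A <- array(0, pd)
  A[seq_len(dims[1L]), seq_len(dims[2L]), seq_len(dims[3L])] <- mask
  K <- array(0, pd)
  kidx <- (-offs) %% matrix(pd, nrow(offs), 3L, byrow = TRUE) + 1L
  K[kidx] <- 1
  C <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(pd)
  round(C[seq_len(dims[1L]), seq_len(dims[2L]), seq_len(dims[3L])])
}

#' Binary dilation
#'
#' A voxel of the result is true iff any offset-shifted voxel of the input is
#' true; neighbours outside the grid are ignored.
#'
#' @param mask a [binary_mask()].
#' @param se a [make_ball()] structuring element.
#' @return the dilated [binary_mask()].
#' @export
dilate <- function(mask, se) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_elem"))
  binary_mask(.se_counts(mask, se) > 0, as_image_grid(mask))
}

#' Binary erosion
#'
#' A voxel of the result is true iff every offset-shifted position is true;
#' positions outside the grid count as background, so the mask recedes from
#' the field-of-view border as well as from its own surface. This is the
#' conservative rule for partial-volume safety.
#'
#' @inheritParams dilate
#' @return the eroded [binary_mask()].
#' @export
erode <- function(mask, se) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_elem"))
  binary_mask(.se_counts(mask, se) >= nrow(se$offsets), as_image_grid(mask))
}

#' Bundle the per-subject tissue masks
#'
#' Collects the binary WM, GM, CSF and brain masks (plus the possibly empty
#' WMH lesion mask) on one shared grid. WM/GM/CSF are hard segmentation
#' labels; overlap between them indicates an upstream segmentation problem and
#' is reported as a warning with the voxel count, not an error.
#'
#' @param wm,gm,csf,brain [binary_mask()] objects on one grid.
#' @param wmh optional WMH lesion [binary_mask()]; defaults to empty.
#' @return object of class `tissue_maps`.
#' @export
tissue_maps <- function(wm, gm, csf, brain, wmh = NULL) {
  if (is.null(wmh))
    wmh <- binary_mask(array(FALSE, as_image_grid(wm)$shape), as_image_grid(wm))
  assert_same_grid(wm = wm, gm = gm, csf = csf, brain = brain, wmh = wmh)
  n_overlap <- sum((wm & gm) | (wm & csf) | (gm & csf))
  if (n_overlap > 0L)
    warning(sprintf("WM/GM/CSF masks overlap at %d voxel(s)", n_overlap))
  structure(list(wm = wm, gm = gm, csf = csf, brain = brain, wmh = wmh),
            class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat("<tissue_maps>\n")
  for (nm in c("wm", "gm", "csf", "brain", "wmh"))
    cat(sprintf("  %-5s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Build the partial-volume-safe white-matter mask
#'
#' Implements
#' \deqn{WM_{safe} = ((WM - (GM \oplus R^{r_{small}})) - (CSF \oplus R^{r_{small}}))
#'   \cap (BM \ominus R^{r_{brain}})}
#' with set subtraction `A - B = A AND NOT B`: white matter with a one-voxel
#' guard band against GM and CSF partial-volume contamination, restricted to
#' the deeply eroded brain mask. Radii are in voxel units of the working grid
#' (the defaults assume the 1 mm isotropic up-sampled diffusion space).
#' The three defining exclusions are re-asserted on the result before it is
#' returned.
#'
#' @param tissues a [tissue_maps()].
#' @param r_small dilation radius for the GM and CSF guard bands (voxels).
#' @param r_brain erosion radius for the brain mask (voxels).
#' @param se_type structuring-element shape, see [make_ball()].
#' @return the safe-WM [binary_mask()] (always a subset of `tissues$wm`).
#' @export
build_wm_safe <- function(tissues, r_small = 1, r_brain = 15,
                          se_type = c("ball", "cube")) {
  stopifnot(inherits(tissues, "tissue_maps"))
  se_type <- match.arg(se_type)
  grid <- as_image_grid(tissues$wm)
  if (!any(tissues$wm)) {
    warning("WM mask is empty; safe-WM mask is empty")
    return(binary_mask(array(FALSE, grid$shape), grid))
  }
  se_s <- make_ball(r_small, se_type)
  se_b <- make_ball(r_brain, se_type)
  gm_d <- dilate(tissues$gm, se_s)
  csf_d <- dilate(tissues$csf, se_s)
  bm_e <- erode(tissues$brain, se_b)
  res <- tissues$wm & !gm_d & !csf_d & bm_e
  stopifnot(!any(res & gm_d), !any(res & csf_d), !any(res & !bm_e))
  binary_mask(res, grid)
}

#' Expand the WMH lesion mask to cover its penumbra
#'
#' Dilates the WMH mask by a ball of the given radius (default 2 voxels) so
#' that both partial-volume contamination at the lesion border and the lesion
#' penumbra are excluded from the normal-appearing-WM measurement. Read as a
#' single radius-`radius` dilation, not iterated unit dilations (the two
#' differ on the discrete grid).
#'
#' @param wmh the lesion [binary_mask()].
#' @param radius dilation radius in voxels.
#' @param se_type structuring-element shape, see [make_ball()].
#' @return the dilated [binary_mask()].
#' @export
expand_wmh <- function(wmh, radius = 2, se_type = c("ball", "cube")) {
  stopifnot(inherits(wmh, "binary_mask"))
  if (!any(wmh)) return(wmh)
  dilate(wmh, make_ball(radius, match.arg(se_type)))
}

#' Mask subtraction
#'
#' `a AND NOT b`, the set subtraction used to remove the expanded WMH mask
#' from the safe-WM mask.
#'
#' @param a,b [binary_mask()] objects on one grid.
#' @return a [binary_mask()].
#' @export
mask_subtract <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  assert_same_grid(a = a, b = b)
  binary_mask(a & !b, as_image_grid(a))
}
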