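#' Define a 3-D voxel grid
#'
#' An `image_grid` records the geometry shared by every volume of one subject:
#' the array shape in voxels, the voxel size in millimetres, and the 4x4
#' voxel-to-world affine. All mask algebra and metric extraction in this
#' package happens in voxel space on a single shared grid; co-registration of
#' the inputs onto that grid is an upstream precondition, not something this
#' package performs.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param affine optional 4x4 voxel-to-world matrix (mm). Defaults to a scaled
#'   identity built from `voxel_size`. Voxel indices are 0-based in this map.
#' @return An object of class `image_grid`.
#' @export
#' @examples
#' g <- image_grid(c(10, 10, 10), c(1.3, 1.3, 2.7))
#' voxel_volume(g) # 4.563 mm^3
image_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive lengths (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
      stop("'affine' must be a finite 4x4 matrix")
    if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
      stop("affine rotation/scaling block is singular")
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size, digits = 4), collapse = "x")))
  invisible(x)
}

#' Voxel volume of a grid in cubic millimetres
#'
#' @param grid an [image_grid()] (or any object carrying one).
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) {
  grid <- as_image_grid(grid)
  prod(grid$voxel_size)
}

#' @rdname image_grid
#' @param x object to coerce or test.
#' @export
is_image_grid <- function(x) inherits(x, "image_grid")

#' Extract the grid carried by a volume, mask or DWI series
#'
#' @param x an `image_grid`, `scalar_volume`, `binary_mask` or `dwi_series`.
#' @return the underlying `image_grid`.
#' @export
as_image_grid <- function(x) {
  if (is_image_grid(x)) return(x)
  g <- attr(x, "grid", exact = TRUE)
  if (is_image_grid(g)) return(g)
  if (is.list(x) && is_image_grid(x$grid)) return(x$grid)
  stop("cannot extract an image_grid from object of class ",
       paste(class(x), collapse = "/"))
}

#' Construct a scalar volume on a grid
#'
#' A `scalar_volume` is a 3-D numeric array with an attached [image_grid()].
#' Missing voxels (e.g. unfittable free-water voxels) are `NA`; they propagate
#' as missing and are excluded from metrics rather than treated as zero.
#'
#' @param values numeric array (or vector) with `prod(grid$shape)` entries.
#' @param grid an [image_grid()].
#' @param units free-text unit label.
#' @return object of class `scalar_volume` (a 3-D array with attributes).
#' @export
scalar_volume <- function(values, grid, units = "") {
  grid <- as_image_grid(grid)
  values <- as.numeric(values)
  if (length(values) != prod(grid$shape))
    stop(sprintf("value count (%d) does not match grid shape (%s)",
                 length(values), paste(grid$shape, collapse = "x")))
  structure(array(values, dim = grid$shape),
            grid = grid, units = units, class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  g <- as_image_grid(x)
  v <- as.vector(x)
  cat(sprintf("<scalar_volume> %s voxels%s; %d NA; range [%g, %g]\n",
              paste(g$shape, collapse = "x"),
              if (nzchar(attr(x, "units"))) paste0(" (", attr(x, "units"), ")") else "",
              sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Construct a binary mask on a grid
#'
#' @param values logical (or 0/1 numeric) array with `prod(grid$shape)` entries.
#' @param grid an [image_grid()].
#' @return object of class `binary_mask` (a 3-D logical array with attributes).
#' @export
binary_mask <- function(values, grid) {
  grid <- as_image_grid(grid)
  if (is.numeric(values)) {
    bad <- !(values %in% c(0, 1)) & !is.na(values)
    if (any(bad)) stop("numeric mask values must all be 0 or 1")
  }
  values <- as.logical(values)
  values[is.na(values)] <- FALSE
  if (length(values) != prod(grid$shape))
    stop("mask value count does not match grid shape")
  structure(array(values, dim = grid$shape),
            grid = grid, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  g <- as_image_grid(x)
  cat(sprintf("<binary_mask> %s voxels; %d true (%.1f mm^3)\n",
              paste(g$shape, collapse = "x"), sum(x), mask_volume_mm3(x)))
  invisible(x)
}

#' Assert that several volumes share one voxel grid
#'
#' Shapes must match exactly and affines agree within `tol` per entry;
#' otherwise an error names the first offending pair. Used as the guard in
#' every multi-volume operation, since the package performs no resampling.
#'
#' @param ... two or more grids, volumes or masks.
#' @param tol absolute tolerance on affine entries (mm).
#' @return invisibly `TRUE` on success.
#' @export
assert_same_grid <- function(..., tol = 1e-4) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1L]]) && !is_image_grid(objs[[1L]]) &&
      is.null(attr(objs[[1L]], "grid", exact = TRUE)) && is.null(objs[[1L]]$grid))
    objs <- objs[[1L]]
  if (length(objs) < 2L) stop("need at least two grids to compare")
  nms <- names(objs)
  if (is.null(nms)) nms <- rep("", length(objs))
  nms <- ifelse(nzchar(nms), nms, paste0("volume ", seq_along(objs)))
  grids <- lapply(objs, as_image_grid)
  ref <- grids[[1L]]
  for (i in seq_along(grids)[-1L]) {
    g <- grids[[i]]
    if (!identical(ref$shape, g$shape))
      stop(sprintf("grid shape mismatch: %s is %s but %s is %s",
                   nms[1L], paste(ref$shape, collapse = "x"),
                   nms[i], paste(g$shape, collapse = "x")))
    d <- abs(ref$affine - g$affine)
    if (any(d > tol)) {
      w <- which(d == max(d), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "grid affine mismatch between %s and %s: entry [%d,%d] differs by %g mm",
        nms[1L], nms[i], w[1L], w[2L], max(d)))
    }
  }
  invisible(TRUE)
}

# Internal: seed-scoped RNG so generators are deterministic without
# clobbering the caller's random state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
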