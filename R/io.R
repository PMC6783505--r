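#' Read a 3-D NIfTI-1 volume
#'
#' Reads a scalar volume or binary mask, populating the grid (shape, voxel
#' size, voxel-to-world affine) from the NIfTI header. `NaN` voxels are
#' converted to `NA` and reported with a count, so that missing data is
#' explicit rather than silently numeric.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_mask if `TRUE`, require all stored values to be 0 or 1 and return
#'   a [binary_mask()]; otherwise return a [scalar_volume()].
#' @param units unit label attached to a scalar volume.
#' @return a [scalar_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, as_mask = FALSE, units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4L] == 1L) {
    d <- d[1:3]
    arr <- array(arr, dim = d)
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume but '%s' has %d dimensions",
                 path, length(d)))
  grid <- .grid_from_nifti(img, d)
  n_nan <- sum(is.nan(arr))
  if (n_nan > 0L) {
    warning(sprintf("'%s' contains %d NaN voxel%s; stored as NA",
                    path, n_nan, if (n_nan == 1L) "" else "s"))
    arr[is.nan(arr)] <- NA_real_
  }
  if (as_mask) {
    vals <- arr[!is.na(arr)]
    if (!all(vals %in% c(0, 1)))
      stop(sprintf("'%s' requested as a mask but contains values other than 0/1",
                   path))
    binary_mask(arr, grid)
  } else {
    scalar_volume(arr, grid, units = units)
  }
}

# Internal: ImageGrid from an RNifti image header.
.grid_from_nifti <- function(img, shape) {
  aff <- structure(RNifti::xform(img), class = NULL)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- sqrt(colSums(aff[1:3, 1:3]^2))
  image_grid(shape, abs(pd[1:3]), affine = aff)
}

#' Write a volume or mask as NIfTI-1
#'
#' Scalar volumes are stored as float32 (`NA` becomes `NaN`); binary masks as
#' uint8 0/1. The grid's affine is written to both sform and qform.
#'
#' @param x a [scalar_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  grid <- as_image_grid(x)
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x), dim = grid$shape)
    dtype <- "uint8"
  } else {
    arr <- array(as.numeric(x), dim = grid$shape)
    arr[is.na(arr)] <- NaN
    dtype <- "float"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Construct a diffusion gradient table
#'
#' @param bvals numeric vector of non-negative b-values (s/mm^2).
#' @param bvecs n x 3 matrix of gradient directions; rows with b > 0 must be
#'   unit vectors (within `1e-3`), rows with b = 0 may be zero.
#' @param b0_threshold b-values below this (s/mm^2) count as b = 0; scanners
#'   commonly report small nonzero values for unweighted volumes.
#' @return object of class `gradient_table` with fields `bvals`, `bvecs`,
#'   `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("'bvecs' must have 3 columns (x, y, z)")
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("gradient table length mismatch: %d b-values but %d b-vectors",
                 length(bvals), nrow(bvecs)))
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  if (any(!is.finite(bvecs))) stop("b-vectors must be finite")
  nz <- bvals >= b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(nz & abs(nrm - 1) > 1e-3))
    stop("b-vectors at b > 0 must be unit length (within 1e-3)")
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  b0 <- x$bvals < x$b0_threshold
  cat(sprintf("<gradient_table> %d entries: %d b=0, %d diffusion-weighted (b ~ %g)\n",
              length(x$bvals), sum(b0), sum(!b0),
              if (any(!b0)) mean(x$bvals[!b0]) else NA_real_))
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Indices of b = 0 entries in a gradient table
#' @param gtab a [gradient_table()].
#' @return logical vector, `TRUE` where b is below the table's b0 threshold.
#' @export
is_b0 <- function(gtab) gtab$bvals < gtab$b0_threshold

#' Read an FSL-style bval/bvec pair
#'
#' The bval file is one whitespace-separated row of numbers; the bvec file has
#' three rows (x, y, z components). Vectors at b > 0 whose norm is within 1e-2
#' of 1 are renormalised to exactly unit length; larger deviations are an
#' error, since they indicate a corrupted table rather than rounding.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @param b0_threshold passed to [gradient_table()].
#' @return a [gradient_table()].
#' @export
read_gradients <- function(bval_path, bvec_path, b0_threshold = 50) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bvals <- .parse_numeric_rows(bval_path, "bval")
  if (length(bvals) == 0L) stop("empty bval file: ", bval_path)
  if (is.list(bvals)) stop("bval file must contain a single row: ", bval_path)
  bv <- .parse_numeric_rows(bvec_path, "bvec", expect_rows = 3L)
  bvecs <- t(do.call(rbind, bv))
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("gradient table length mismatch: %d b-values but %d b-vectors",
                 length(bvals), nrow(bvecs)))
  nz <- bvals >= b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- nz & abs(nrm - 1) > 1e-2 + 1e-9
  if (any(bad))
    stop(sprintf("%d b-vector(s) at b > 0 deviate from unit norm by more than 1e-2",
                 sum(bad)))
  fix <- nz & nrm > 0
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  gradient_table(bvals, bvecs, b0_threshold = b0_threshold)
}

# Internal: parse whitespace-separated numeric rows; errors on non-numeric
# tokens. Returns a vector for one row, a list of vectors otherwise.
.parse_numeric_rows <- function(path, what, expect_rows = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric token '%s' in %s file %s",
                   toks[which(is.na(vals))[1L]], what, path))
    vals
  })
  if (!is.null(expect_rows) && length(rows) != expect_rows)
    stop(sprintf("%s file %s must have %d rows, found %d",
                 what, path, expect_rows, length(rows)))
  if (!is.null(expect_rows)) {
    n <- lengths(rows)
    if (length(unique(n)) != 1L)
      stop(sprintf("%s file %s has rows of unequal length", what, path))
    return(rows)
  }
  if (length(rows) == 1L) rows[[1L]] else rows
}

#' Write a gradient table as FSL bval/bvec text files
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @return invisibly `NULL`.
#' @export
write_gradients <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Gradient-shell quality assurance
#'
#' Checks that a DWI acquisition is single-shell with enough diffusion
#' directions: all nonzero b-values must lie within `b_tolerance` of their
#' mean, and the number of nonzero-b directions must be at least
#' `min_directions`. b = 0 entries are ignored for the shell test. The
#' defaults encode the acquisition this pipeline expects: 41 directions on one
#' shell at b = 1000 s/mm^2.
#'
#' @param gtab a [gradient_table()].
#' @param b_tolerance allowed deviation of nonzero b-values from their mean
#'   (s/mm^2).
#' @param min_directions minimum number of nonzero-b directions.
#' @return a list of class `shell_qa` with `pass`, `messages`, `n_directions`,
#'   `n_b0`, `b_mean`.
#' @export
check_single_shell <- function(gtab, b_tolerance = 50, min_directions = 41) {
  if (length(gtab) == 0L) stop("empty gradient table")
  nz <- !is_b0(gtab)
  msgs <- character(0)
  b_mean <- if (any(nz)) mean(gtab$bvals[nz]) else NA_real_
  if (any(nz) && any(abs(gtab$bvals[nz] - b_mean) > b_tolerance))
    msgs <- c(msgs, sprintf(
      "multiple shells: nonzero b-values span [%g, %g], beyond +/-%g of mean %g",
      min(gtab$bvals[nz]), max(gtab$bvals[nz]), b_tolerance, b_mean))
  if (sum(nz) < min_directions)
    msgs <- c(msgs, sprintf("too few directions: %d nonzero-b directions, need >= %d",
                            sum(nz), min_directions))
  structure(list(pass = length(msgs) == 0L, messages = msgs,
                 n_directions = sum(nz), n_b0 = sum(!nz), b_mean = b_mean),
            class = "shell_qa")
}

#' @export
print.shell_qa <- function(x, ...) {
  cat(sprintf("<shell_qa> %s: %d directions, %d b=0, mean b %g\n",
              if (x$pass) "PASS" else "FAIL", x$n_directions, x$n_b0, x$b_mean))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Construct a 4-D diffusion-weighted series
#'
#' @param signal 4-D non-negative array; the fourth dimension indexes
#'   gradients and must equal the gradient-table length.
#' @param grid an [image_grid()] for the first three dimensions.
#' @param gtab a [gradient_table()].
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(signal, grid, gtab) {
  grid <- as_image_grid(grid)
  d <- dim(signal)
  if (length(d) != 4L) stop("'signal' must be a 4-D array")
  signal <- array(as.numeric(signal), d)   # drop any foreign attributes
  if (!identical(as.integer(d[1:3]), grid$shape))
    stop("signal spatial dimensions do not match the grid")
  if (d[4L] != length(gtab))
    stop(sprintf("number of 3-D volumes (%d) does not equal gradient-table length (%d)",
                 d[4L], length(gtab)))
  if (any(signal < 0, na.rm = TRUE)) stop("DWI signal must be non-negative")
  structure(list(signal = signal, grid = grid, gtab = gtab),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> %s voxels x %d gradients\n",
              paste(x$grid$shape, collapse = "x"), length(x$gtab)))
  print(x$gtab)
  invisible(x)
}

#' Read a DWI series (NIfTI + bval/bvec)
#'
#' @param dwi_path 4-D NIfTI-1 file.
#' @param bval_path,bvec_path FSL gradient files.
#' @return a [dwi_series()].
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path) {
  if (!file.exists(dwi_path)) stop("file not found: ", dwi_path)
  img <- RNifti::readNifti(dwi_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-D DWI series but '%s' has %d dimensions",
                 dwi_path, length(dim(arr))))
  grid <- .grid_from_nifti(img, dim(arr)[1:3])
  gtab <- read_gradients(bval_path, bvec_path)
  dwi_series(arr, grid, gtab)
}

#' Write a DWI series as NIfTI + bval/bvec
#'
#' @param dwi a [dwi_series()].
#' @param dwi_path,bval_path,bvec_path output paths.
#' @return invisibly `dwi_path`.
#' @export
write_dwi <- function(dwi, dwi_path, bval_path, bvec_path) {
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$grid$voxel_size, 1)
  RNifti::qform(img) <- structure(dwi$grid$affine, code = 2L)
  RNifti::sform(img) <- structure(dwi$grid$affine, code = 2L)
  RNifti::writeNifti(img, dwi_path, datatype = "float")
  write_gradients(dwi$gtab, bval_path, bvec_path)
  invisible(dwi_path)
}
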