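#' Voxelwise reference distribution of a group
#'
#' Per-voxel mean and sample standard deviation (n - 1 divisor) of a group's
#' FW volumes, used as the reference against which individual subjects are
#' z-scored. A voxel is `valid` only when every subject has a value there and
#' the SD is strictly positive.
#'
#' @param fw_volumes list of at least two [scalar_volume()] objects on one
#'   grid.
#' @return object of class `group_reference` with `mean`, `sd`
#'   ([scalar_volume()]), `n`, `valid` ([binary_mask()]).
#' @export
group_reference <- function(fw_volumes) {
  if (length(fw_volumes) < 2L)
    stop("need at least two volumes to form a reference")
  do.call(assert_same_grid, fw_volumes)
  grid <- as_image_grid(fw_volumes[[1L]])
  X <- vapply(fw_volumes, as.vector, numeric(prod(grid$shape)))
  n <- ncol(X)
  full <- rowSums(is.na(X)) == 0L
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  mu[!full] <- NA_real_
  sdv[!full] <- NA_real_
  structure(list(mean = scalar_volume(mu, grid),
                 sd = scalar_volume(sdv, grid),
                 n = n,
                 valid = binary_mask(full & !is.na(sdv) & sdv > 0, grid)),
            class = "group_reference")
}

#' @export
print.group_reference <- function(x, ...) {
  cat(sprintf("<group_reference> n = %d subjects, %d valid voxels\n",
              x$n, sum(x$valid)))
  invisible(x)
}

#' z-score a subject against a group reference
#'
#' `(x - mean) / sd` inside the reference's valid voxels; `NA` elsewhere and
#' wherever the subject itself is missing.
#'
#' @param fw the subject's FW [scalar_volume()].
#' @param ref a [group_reference()].
#' @return a [scalar_volume()] of z-scores.
#' @export
subject_zscore <- function(fw, ref) {
  stopifnot(inherits(ref, "group_reference"))
  assert_same_grid(fw = fw, ref = ref$mean)
  z <- (as.vector(fw) - as.vector(ref$mean)) / as.vector(ref$sd)
  z[!as.vector(ref$valid)] <- NA_real_
  scalar_volume(z, as_image_grid(fw), units = "z")
}

#' Average z-score volumes
#'
#' Voxelwise mean over a list of z-score volumes; a voxel is valid in the
#' output only when it is valid (non-missing) in every input.
#'
#' @param z_volumes non-empty list of [scalar_volume()] objects on one grid.
#' @return a [scalar_volume()].
#' @export
mean_zscore <- function(z_volumes) {
  if (length(z_volumes) < 1L) stop("empty list of z-score volumes")
  if (length(z_volumes) > 1L) do.call(assert_same_grid, z_volumes)
  grid <- as_image_grid(z_volumes[[1L]])
  X <- vapply(z_volumes, as.vector, numeric(prod(grid$shape)))
  X <- matrix(X, ncol = length(z_volumes))
  out <- rowMeans(X)               # NA wherever any input is NA
  scalar_volume(out, grid, units = "z")
}

# Internal: neighbour offsets for 6/18/26 connectivity.
.conn_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1L,
                 "18" = rowSums(abs(g)) <= 2L,
                 "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Breadth-first flood fill under the requested neighbourhood rule. Labels
#' are renumbered contiguously from 1, largest component first (ties broken
#' by first voxel in array order).
#'
#' @param mask a [binary_mask()] (or plain logical 3-D array).
#' @param connectivity 6, 18 or 26 (default).
#' @return list with `labels` (integer 3-D array, 0 = background) and `sizes`
#'   (integer vector named by label).
#' @export
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- .conn_offsets(as.integer(connectivity))
  lab <- array(0L, dims)
  m <- as.logical(mask)
  seeds <- which(m)
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      pos <- arrayInd(frontier, dims)
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        np1 <- pos[, 1L] + offs[k, 1L]
        np2 <- pos[, 2L] + offs[k, 2L]
        np3 <- pos[, 3L] + offs[k, 3L]
        inside <- np1 >= 1L & np1 <= dims[1L] & np2 >= 1L & np2 <= dims[2L] &
          np3 >= 1L & np3 <= dims[3L]
        if (!any(inside)) next
        nlin <- np1[inside] + (np2[inside] - 1L) * dims[1L] +
          (np3[inside] - 1L) * dims[1L] * dims[2L]
        nlin <- nlin[m[nlin] & lab[nlin] == 0L]
        if (length(nlin)) {
          lab[nlin] <- cur
          nxt <- c(nxt, nlin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  if (cur == 0L) return(list(labels = lab, sizes = integer(0)))
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  ord <- order(-sizes, vapply(seq_len(cur), function(l) which(lab == l)[1L], 0L))
  remap <- integer(cur)
  remap[ord] <- seq_len(cur)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  list(labels = lab, sizes = stats::setNames(sizes[ord], seq_len(cur)))
}

#' Threshold a z-score volume and keep large clusters
#'
#' Binarises the average z-score volume at `z >= z_min` (inclusive; by
#' default only the positive tail, the direction of elevated FW in patients),
#' labels connected components under the chosen neighbourhood, and discards
#' components smaller than `min_size` voxels.
#'
#' @param z a [scalar_volume()] of (averaged) z-scores; `NA` voxels never
#'   survive the threshold.
#' @param z_min inclusive z threshold (default 2).
#' @param min_size minimum surviving cluster size in voxels (default 10).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param two_tailed threshold on `|z|` instead of `z`.
#' @return object of class `cluster_map`: `labels` (integer array, 0 =
#'   background, labels contiguous from 1), `sizes` (named integer vector),
#'   `grid`, and the thresholding parameters.
#' @export
threshold_clusters <- function(z, z_min = 2, min_size = 10,
                               connectivity = 26, two_tailed = FALSE) {
  stopifnot(inherits(z, "scalar_volume"))
  grid <- as_image_grid(z)
  zv <- unclass(z)
  attributes(zv) <- list(dim = grid$shape)
  bin <- if (two_tailed) abs(zv) >= z_min else zv >= z_min
  bin[is.na(bin)] <- FALSE
  cc <- label_components(bin, connectivity)
  keep <- as.integer(names(cc$sizes))[cc$sizes >= min_size]
  lab <- cc$labels
  lab[!(lab %in% keep)] <- 0L
  # renumber surviving clusters contiguously, preserving size order
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[sort(keep)] <- rank(sort(keep))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    sizes <- stats::setNames(cc$sizes[as.character(sort(keep))],
                             seq_along(keep))
  } else {
    sizes <- integer(0)
  }
  structure(list(labels = lab, sizes = sizes, grid = grid, z_min = z_min,
                 min_size = min_size, connectivity = connectivity,
                 two_tailed = two_tailed),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d cluster(s) >= %d voxels at z >= %g; %d voxels total\n",
              length(x$sizes), x$min_size, x$z_min, sum(x$labels > 0L)))
  invisible(x)
}

#' Tabulate a cluster map
#'
#' @param cm a [threshold_clusters()] result.
#' @return data frame with `label`, `size` and the 0-based voxel centroid
#'   (`cx`, `cy`, `cz`).
#' @export
cluster_table <- function(cm) {
  stopifnot(inherits(cm, "cluster_map"))
  if (!length(cm$sizes))
    return(data.frame(label = integer(0), size = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0)))
  rows <- lapply(as.integer(names(cm$sizes)), function(l) {
    pos <- arrayInd(which(cm$labels == l), dim(cm$labels)) - 1L
    data.frame(label = l, size = unname(cm$sizes[as.character(l)]),
               cx = mean(pos[, 1L]), cy = mean(pos[, 2L]), cz = mean(pos[, 3L]))
  })
  do.call(rbind, rows)
}

#' Write a cluster map as NIfTI label volume + CSV table
#'
#' @param cm a [threshold_clusters()] result.
#' @param nii_path output NIfTI-1 path for the integer label volume.
#' @param csv_path output CSV path for [cluster_table()].
#' @return invisibly `NULL`.
#' @export
write_cluster_map <- function(cm, nii_path, csv_path = NULL) {
  stopifnot(inherits(cm, "cluster_map"))
  img <- RNifti::asNifti(cm$labels)
  RNifti::pixdim(img) <- cm$grid$voxel_size
  RNifti::qform(img) <- structure(cm$grid$affine, code = 2L)
  RNifti::sform(img) <- structure(cm$grid$affine, code = 2L)
  RNifti::writeNifti(img, nii_path, datatype = "int16")
  if (!is.null(csv_path))
    utils::write.csv(cluster_table(cm), csv_path, row.names = FALSE)
  invisible(NULL)
}
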