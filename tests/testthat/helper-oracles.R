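# Independent brute-force oracles used to check the production morphology and
# cluster code. These deliberately share no code with the package internals:
# plain voxel/offset double loops and iterative label propagation.

bf_dilate <- function(mask, offsets) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    for (k in seq_len(nrow(offsets))) {
      p <- c(x, y, z) + offsets[k, ]
      if (all(p >= 1) && all(p <= dims) && mask[p[1], p[2], p[3]]) {
        out[x, y, z] <- TRUE
        break
      }
    }
  }
  out
}

bf_erode <- function(mask, offsets) {
  dims <- dim(mask)
  out <- array(TRUE, dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    for (k in seq_len(nrow(offsets))) {
      p <- c(x, y, z) + offsets[k, ]
      if (!(all(p >= 1) && all(p <= dims)) || !mask[p[1], p[2], p[3]]) {
        out[x, y, z] <- FALSE
        break
      }
    }
  }
  out
}

# Connected components by iterative minimum-label propagation (a different
# algorithm from the package's BFS flood fill): start with unique labels and
# repeatedly replace each voxel's label by the minimum over its in-mask
# neighbourhood until nothing changes.
bf_label <- function(mask, offsets) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    idx <- which(mask)
    pos <- arrayInd(idx, dims)
    for (k in seq_len(nrow(offsets))) {
      np <- pos + matrix(offsets[k, ], nrow(pos), 3, byrow = TRUE)
      ok <- np[, 1] >= 1 & np[, 1] <= dims[1] & np[, 2] >= 1 & np[, 2] <= dims[2] &
        np[, 3] >= 1 & np[, 3] <= dims[3]
      nlin <- np[ok, 1] + (np[ok, 2] - 1L) * dims[1] +
        (np[ok, 3] - 1L) * dims[1] * dims[2]
      src <- idx[ok]
      nb_ok <- mask[nlin]
      better <- nb_ok & lab[nlin] < lab[src]
      if (any(better)) {
        lab[src[better]] <- lab[nlin[better]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# Random binary mask on an n^3 grid.
random_mask <- function(n, p = 0.5, grid = image_grid(rep(n, 3))) {
  binary_mask(array(stats::runif(n^3) < p, rep(n, 3)), grid)
}

# Partition check: same components up to label renumbering.
same_partition <- function(a, b) {
  fa <- as.vector(a)[as.vector(a) > 0 | as.vector(b) > 0]
  fb <- as.vector(b)[as.vector(a) > 0 | as.vector(b) > 0]
  all(fa > 0) && all(fb > 0) &&
    !is.na(suppressWarnings({
      tab <- table(fa, fb)
      all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    })) && {
      tab <- table(fa, fb)
      all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    }
}

# Small gradient scheme for fast fit tests.
small_gtab <- function(n_dirs = 20) make_gradient_scheme(n_dirs = n_dirs)

# Default WM-like tensor used across fit tests.
wm_tensor <- c(1.5e-3, 0, 0, 0.4e-3, 0, 0.4e-3)
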