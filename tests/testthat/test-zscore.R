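vol_of <- function(vals, shape = c(4, 4, 4)) {
  scalar_volume(array(vals, shape), image_grid(shape))
}

test_that("group reference computes per-voxel mean and sample SD", {
  v <- lapply(c(1, 2, 3), vol_of)
  ref <- group_reference(v)
  expect_equal(as.vector(ref$mean), rep(2, 64))
  expect_equal(as.vector(ref$sd), rep(1, 64))  # n-1 divisor
  expect_identical(ref$n, 3L)
  # two identical volumes: sd 0 everywhere, valid empty
  ref2 <- group_reference(lapply(c(5, 5), vol_of))
  expect_true(all(as.vector(ref2$sd) == 0))
  expect_identical(sum(ref2$valid), 0L)
  # a missing voxel in one volume drops out of valid
  vv <- lapply(c(1, 2, 3), vol_of)
  vv[[2]][1, 1, 1] <- NA
  vv[[2]] <- scalar_volume(vv[[2]], image_grid(c(4, 4, 4)))
  ref3 <- group_reference(vv)
  expect_false(ref3$valid[1, 1, 1])
  expect_identical(sum(ref3$valid), 63L)
  expect_error(group_reference(v[1]), "two volumes")
})

test_that("subject z-scores match the elementwise definition", {
  set.seed(51)
  vols <- lapply(1:4, function(i) vol_of(rnorm(64, 10, 2)))
  ref <- group_reference(vols)
  x <- vol_of(rnorm(64, 10, 2))
  z <- subject_zscore(x, ref)
  oracle <- (as.vector(x) - as.vector(ref$mean)) / as.vector(ref$sd)
  expect_equal(as.vector(z), oracle, tolerance = 1e-12)
  # x equal to the mean gives all-zero z inside valid
  z0 <- subject_zscore(ref$mean, ref)
  expect_true(all(abs(as.vector(z0)[as.vector(ref$valid)]) < 1e-12))
  # x = mean + 2 sd gives exactly 2
  x2 <- scalar_volume(as.vector(ref$mean) + 2 * as.vector(ref$sd),
                      image_grid(c(4, 4, 4)))
  expect_equal(as.vector(subject_zscore(x2, ref))[1], 2, tolerance = 1e-12)
})

test_that("z-scores of group members against their own reference sum to zero", {
  set.seed(52)
  vols <- lapply(1:6, function(i) vol_of(rnorm(64, 5, 1)))
  ref <- group_reference(vols)
  zsum <- Reduce(`+`, lapply(vols, function(v)
    as.vector(subject_zscore(v, ref))))
  expect_lt(max(abs(zsum[as.vector(ref$valid)])), 1e-8)
})

test_that("z-volume averaging keeps only voxels valid everywhere", {
  z1 <- vol_of(1); z2 <- vol_of(-1)
  expect_equal(as.vector(mean_zscore(list(z1, z2))), rep(0, 64))
  expect_equal(as.vector(mean_zscore(list(z1))), rep(1, 64))
  z3 <- z1; z3[2, 2, 2] <- NA
  z3 <- scalar_volume(z3, image_grid(c(4, 4, 4)))
  zb <- mean_zscore(list(z1, z3))
  expect_true(is.na(zb[2, 2, 2]))
  set.seed(53)
  zs <- lapply(1:3, function(i) vol_of(rnorm(64)))
  oracle <- rowMeans(vapply(zs, as.vector, numeric(64)))
  expect_equal(as.vector(mean_zscore(zs)), oracle, tolerance = 1e-12)
  expect_error(mean_zscore(list()), "empty")
})

test_that("cluster thresholding keeps exactly the >= 10-voxel components", {
  shape <- c(12, 40, 5)
  z <- array(0, shape)
  # three disjoint line components of sizes 9, 10, 11
  z[1:9, 1, 1] <- 3
  z[1:10, 10, 1] <- 3
  z[1:11, 20, 1] <- 3
  cm <- threshold_clusters(scalar_volume(z, image_grid(shape)),
                           z_min = 2, min_size = 10)
  expect_identical(length(cm$sizes), 2L)
  expect_identical(sort(unname(cm$sizes)), c(10L, 11L))
  expect_identical(sum(cm$labels > 0), 21L)
  # all-subthreshold field gives an empty map
  cm0 <- threshold_clusters(vol_of(1), z_min = 2, min_size = 10)
  expect_identical(length(cm0$sizes), 0L)
  # z exactly at the threshold is kept (inclusive)
  z2 <- array(0, shape); z2[1:12, 30, 2] <- 2
  cm2 <- threshold_clusters(scalar_volume(z2, image_grid(shape)), z_min = 2,
                            min_size = 10)
  expect_identical(sum(cm2$labels > 0), 12L)
})

test_that("component labels agree with the propagation oracle", {
  set.seed(54)
  for (conn in c(6L, 26L)) {
    offs <- freewater:::.conn_offsets(conn)
    for (i in 1:5) {
      m <- array(runif(10^3) < 0.35, c(10, 10, 10))
      lab <- label_components(m, connectivity = conn)$labels
      oracle <- bf_label(m, offs)
      expect_true(same_partition(lab, oracle))
    }
  }
})

test_that("raising the threshold or minimum size never adds voxels", {
  set.seed(55)
  z <- vol_of(rnorm(64, 1.5, 1))
  v1 <- sum(threshold_clusters(z, z_min = 1.5, min_size = 2)$labels > 0)
  v2 <- sum(threshold_clusters(z, z_min = 2.0, min_size = 2)$labels > 0)
  v3 <- sum(threshold_clusters(z, z_min = 1.5, min_size = 5)$labels > 0)
  expect_lte(v2, v1)
  expect_lte(v3, v1)
})

test_that("null groups rarely produce surviving clusters", {
  set.seed(56)
  hits <- 0L
  for (rep in 1:5) {
    vols <- lapply(1:20, function(i) vol_of(rnorm(512, 0.15, 0.03), c(8, 8, 8)))
    ref <- group_reference(vols[1:10])
    zbar <- mean_zscore(lapply(vols[11:20], subject_zscore, ref = ref))
    cm <- threshold_clusters(zbar, z_min = 2, min_size = 10)
    hits <- hits + sum(cm$labels > 0)
  }
  expect_identical(hits, 0L)
})

test_that("cluster tables and NIfTI output round-trip", {
  shape <- c(12, 12, 5)
  z <- array(0, shape); z[2:12, 2, 1] <- 4; z[1:10, 8, 3] <- 4
  cm <- threshold_clusters(scalar_volume(z, image_grid(shape)), 2, 10)
  tab <- cluster_table(cm)
  expect_identical(nrow(tab), 2L)
  expect_identical(sort(tab$size), c(10L, 11L))
  # centroid of the first line: x spans 0-based 1..11 -> 6
  expect_equal(tab$cx[tab$size == 11], 6)
  np <- tempfile(fileext = ".nii.gz"); cp <- tempfile(fileext = ".csv")
  write_cluster_map(cm, np, cp)
  lab2 <- as.array(RNifti::readNifti(np))
  expect_identical(as.integer(lab2), as.integer(cm$labels))
  expect_identical(nrow(utils::read.csv(cp)), 2L)
})
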