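test_that("structuring elements enumerate the discrete ball", {
  expect_identical(nrow(make_ball(0)$offsets), 1L)
  expect_identical(nrow(make_ball(1)$offsets), 7L)   # origin + 6 faces
  expect_identical(nrow(make_ball(2)$offsets), 33L)  # brute-force count
  # symmetric under negation and contains the origin
  se <- make_ball(3)
  o <- se$offsets
  expect_true(any(rowSums(abs(o)) == 0))
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(o), key(-o))
  expect_identical(nrow(make_ball(1, "cube")$offsets), 27L)
  expect_error(make_ball(-1), "non-negative")
})

test_that("dilation and erosion match hand-derivable cases", {
  g <- image_grid(c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  m <- binary_mask(m, g)
  expect_identical(sum(dilate(m, make_ball(1))), 7L)
  expect_identical(sum(dilate(m, make_ball(2))), 33L)
  expect_identical(sum(erode(m, make_ball(1))), 0L)
  empty <- binary_mask(array(FALSE, c(5, 5, 5)), g)
  expect_identical(sum(dilate(empty, make_ball(2))), 0L)
  g10 <- image_grid(c(10, 10, 10))
  full <- binary_mask(array(TRUE, c(10, 10, 10)), g10)
  expect_identical(sum(erode(full, make_ball(1))), 512L) # 8^3 interior
})

test_that("morphology matches the brute-force oracle on random masks", {
  set.seed(101)
  for (r in 1:2) {
    se <- make_ball(r)
    for (i in 1:10) {
      m <- random_mask(12, p = runif(1, 0.2, 0.8))
      expect_identical(as.vector(dilate(m, se)),
                       as.vector(bf_dilate(m, se$offsets)))
      expect_identical(as.vector(erode(m, se)),
                       as.vector(bf_erode(m, se$offsets)))
    }
  }
})

test_that("erosion is the dual of dilation of the complement", {
  set.seed(5)
  g <- image_grid(c(12, 12, 12))
  se <- make_ball(2)
  for (i in 1:5) {
    m <- random_mask(12, p = 0.6, grid = g)
    # duality holds in the infinite-grid sense: pad so the border rule
    # (outside = background for erosion, ignored for dilation) agrees
    pad <- array(FALSE, c(18, 18, 18))
    pad[4:15, 4:15, 4:15] <- m
    gp <- image_grid(c(18, 18, 18))
    mp <- binary_mask(pad, gp)
    er <- erode(mp, se)
    du <- binary_mask(!dilate(binary_mask(!pad, gp), se), gp)
    expect_identical(as.vector(er)[as.vector(pad)], as.vector(du)[as.vector(pad)])
  }
})

test_that("dilation is extensive, erosion anti-extensive, both monotone", {
  set.seed(6)
  se <- make_ball(1)
  a <- random_mask(10, 0.4)
  b <- binary_mask(a | random_mask(10, 0.2), as_image_grid(a)) # a subset of b
  expect_true(all(!a | dilate(a, se)))        # m subset dilate(m)
  expect_true(all(!erode(a, se) | a))         # erode(m) subset m
  expect_true(all(!dilate(a, se) | dilate(b, se)))
  expect_true(all(!erode(a, se) | erode(b, se)))
})

test_that("safe-WM mask equals its defining composition and postconditions", {
  set.seed(7)
  g <- image_grid(c(20, 20, 20))
  wm <- random_mask(20, 0.5, g)
  gm <- binary_mask(!wm & (random_mask(20, 0.3, g) > 0), g)
  csf <- binary_mask(!wm & !gm & (random_mask(20, 0.2, g) > 0), g)
  brain <- binary_mask(wm | gm | csf | random_mask(20, 0.5, g), g)
  tis <- tissue_maps(wm, gm, csf, brain)
  ws <- build_wm_safe(tis, r_small = 1, r_brain = 3)
  # term-by-term oracle composition
  se1 <- make_ball(1); se3 <- make_ball(3)
  expected <- wm & !bf_dilate(gm, se1$offsets) & !bf_dilate(csf, se1$offsets) &
    bf_erode(brain, se3$offsets)
  expect_identical(as.vector(ws), as.vector(expected))
  # the three defining exclusions, restated
  expect_identical(sum(ws & dilate(gm, se1)), 0L)
  expect_identical(sum(ws & dilate(csf, se1)), 0L)
  expect_true(all(!ws | erode(brain, se3)))
  expect_true(all(!ws | wm))                  # result subset of WM
})

test_that("a WM voxel face-adjacent to GM is excluded; deep WM survives", {
  g <- image_grid(c(9, 9, 9))
  wm <- array(TRUE, c(9, 9, 9))
  gm <- array(FALSE, c(9, 9, 9)); gm[1:3, , ] <- TRUE
  wm[gm] <- FALSE
  tis <- tissue_maps(binary_mask(wm, g), binary_mask(gm, g),
                     binary_mask(array(FALSE, c(9, 9, 9)), g),
                     binary_mask(array(TRUE, c(9, 9, 9)), g))
  ws <- build_wm_safe(tis, r_small = 1, r_brain = 2)
  expect_false(ws[4, 5, 5])   # face-adjacent to the GM wall, inside eroded brain
  expect_true(ws[5, 5, 5])    # interior voxel survives all three terms
  # empty WM warns and returns empty
  tis0 <- tissue_maps(binary_mask(array(FALSE, c(9, 9, 9)), g),
                      tis$gm, tis$csf, tis$brain)
  expect_warning(ws0 <- build_wm_safe(tis0), "empty")
  expect_identical(sum(ws0), 0L)
})

test_that("WMH expansion is a single radius-2 ball dilation", {
  g <- image_grid(c(9, 9, 9))
  wmh <- array(FALSE, c(9, 9, 9)); wmh[5, 5, 5] <- TRUE
  wmh <- binary_mask(wmh, g)
  ex <- expand_wmh(wmh)
  expect_identical(sum(ex), 33L)
  expect_identical(sum(expand_wmh(binary_mask(array(FALSE, c(9, 9, 9)), g))), 0L)
  # dilation grows strictly away from borders (no idempotence)
  expect_gt(sum(expand_wmh(ex)), sum(ex))
})

test_that("mask subtraction is elementwise a AND NOT b", {
  set.seed(8)
  a <- random_mask(10, 0.5)
  b <- random_mask(10, 0.5)
  expect_identical(as.vector(mask_subtract(a, b)), as.vector(a) & !as.vector(b))
  expect_identical(sum(mask_subtract(a, a)), 0L)
  empty <- binary_mask(array(FALSE, dim(a)), as_image_grid(a))
  expect_identical(as.vector(mask_subtract(a, empty)), as.vector(a))
  g2 <- image_grid(c(10, 10, 11))
  expect_error(mask_subtract(a, binary_mask(array(FALSE, c(10, 10, 11)), g2)),
               "mismatch")
})

test_that("overlapping tissue labels warn with a count", {
  g <- image_grid(c(4, 4, 4))
  m <- binary_mask(array(TRUE, c(4, 4, 4)), g)
  expect_warning(tissue_maps(m, m, m, m), "overlap at 64")
})
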