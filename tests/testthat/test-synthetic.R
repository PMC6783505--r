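test_that("Rician noise has the right degenerate and asymptotic behaviour", {
  x <- c(0, 1, 5, 10)
  expect_identical(add_rician_noise(x, 0), x)
  expect_error(add_rician_noise(x, -1), "non-negative")
  y <- add_rician_noise(matrix(runif(100), 10), 2, seed = 61)
  expect_true(all(y >= 0))
  expect_identical(dim(y), c(10L, 10L))
  # zero signal becomes Rayleigh with mean sigma * sqrt(pi / 2)
  draws <- add_rician_noise(rep(0, 1e5), 3, seed = 62)
  expect_equal(mean(draws), 3 * sqrt(pi / 2), tolerance = 0.01)
  # deterministic per seed
  expect_identical(add_rician_noise(x, 1, seed = 7),
                   add_rician_noise(x, 1, seed = 7))
})

test_that("phantom regions partition the brain and nest correctly", {
  sp <- phantom_spec(shape = c(24, 24, 24), n_wmh = 2,
                     wmh_radius_range = c(1, 1), seed = 63)
  ph <- make_phantom(sp)
  t <- ph$tissues
  expect_identical(sum(t$wm & t$gm), 0L)
  expect_identical(sum(t$wm & t$csf), 0L)
  expect_identical(sum(t$gm & t$csf), 0L)
  expect_identical(as.vector(t$wm | t$gm | t$csf), as.vector(t$brain))
  expect_true(all(!t$wmh | t$wm))  # lesions carved from WM
  f <- as.vector(ph$true_f)
  expect_true(all(is.na(f[!t$brain])))
  expect_true(all(f[which(t$brain)] >= 0 & f[which(t$brain)] <= 1))
  expect_true(all(f[which(t$csf)] == 1))
})

test_that("phantom generation is deterministic given the seed", {
  sp <- phantom_spec(shape = c(16, 16, 16), n_wmh = 1,
                     wmh_radius_range = c(1, 1), seed = 64)
  a <- make_phantom(sp); b <- make_phantom(sp)
  expect_identical(a$dwi$signal, b$dwi$signal)
  expect_identical(as.vector(a$true_f), as.vector(b$true_f))
  expect_identical(as.vector(a$tissues$wmh), as.vector(b$tissues$wmh))
  sp2 <- phantom_spec(shape = c(16, 16, 16), n_wmh = 1,
                      wmh_radius_range = c(1, 1), seed = 65)
  expect_false(identical(make_phantom(sp2)$dwi$signal, a$dwi$signal))
})

test_that("noise-free phantom DWI equals the forward model voxelwise", {
  sp <- phantom_spec(shape = c(12, 12, 12), rician_sigma = 0, n_wmh = 0,
                     f_texture_sd = 0, f_gradient_amp = 0, seed = 66)
  ph <- make_phantom(sp)
  idx <- which(ph$tissues$wm)[1]
  pos <- arrayInd(idx, dim(ph$tissues$wm))
  sig <- ph$dwi$signal[pos[1], pos[2], pos[3], ]
  expect_equal(sig[1], sp$s0)
  # attenuations bounded by the two compartments
  expect_true(all(sig[-1] <= sp$s0 & sig[-1] >= sp$s0 * exp(-1000 * 3e-3) * 0.99))
})

test_that("no lesions means an empty WMH mask and unchanged safe mask", {
  sp <- phantom_spec(shape = c(16, 16, 16), n_wmh = 0, rician_sigma = 0,
                     seed = 67)
  ph <- make_phantom(sp)
  expect_identical(sum(ph$tissues$wmh), 0L)
  ws <- build_wm_safe(ph$tissues, r_brain = 2)
  expect_identical(as.vector(mask_subtract(ws, expand_wmh(ph$tissues$wmh))),
                   as.vector(ws))
})

small_cohort_args <- function(n = 2, seed = 71) {
  # low-texture phantom so the constructed group offsets dominate the
  # per-subject variability even at these tiny group sizes
  list(pspec = phantom_spec(shape = c(16, 16, 16), n_wmh = 1,
                            wmh_radius_range = c(1, 1), f_texture_sd = 0.02,
                            seed = 1),
       cspec = cohort_spec(n_per_group = c(NC = n, MCI = n, AD = n),
                           f_offsets = c(NC = 0, MCI = 0.04, AD = 0.08),
                           seed = seed))
}

test_that("ground-truth metric table equals the metrics module on true_f", {
  a <- small_cohort_args()
  co <- make_cohort(a$pspec, a$cspec, keep = "all", r_brain = 3)
  for (i in c(1, 4)) {
    ph <- co$subjects[[i]]
    ws <- build_wm_safe(ph$tissues, r_small = 1, r_brain = 3)
    sm <- subject_metrics(ph$true_f, ph$tissues, ws,
                          expand_wmh(ph$tissues$wmh),
                          subject_id = co$plan$subject_id[i])
    got <- co$truth[co$truth$subject_id == co$plan$subject_id[i], ]
    rownames(got) <- rownames(sm) <- NULL
    expect_equal(got, sm)
  }
})

test_that("group offsets order the ground-truth means exactly", {
  a <- small_cohort_args(n = 3)
  co <- make_cohort(a$pspec, a$cspec, r_brain = 3)
  tt <- merge(co$truth[co$truth$mask_name == "WM_safe", ], co$demographics)
  mu <- tapply(tt$muFW, tt$group, mean)
  expect_lt(mu["NC"], mu["MCI"])
  expect_lt(mu["MCI"], mu["AD"])
  # zero offsets and zero jitter: identical group means up to lesion placement
  cs0 <- cohort_spec(n_per_group = c(NC = 2, MCI = 2, AD = 2),
                     f_offsets = c(NC = 0, MCI = 0, AD = 0),
                     offset_jitter_sd = 0, wmh_rate = c(NC = 1, MCI = 1, AD = 1),
                     seed = 5)
  co0 <- make_cohort(a$pspec, cs0, r_brain = 3)
  t0 <- merge(co0$truth[co0$truth$mask_name == "WM_safe", ], co0$demographics)
  mu0 <- tapply(t0$muFW, t0$group, mean)
  expect_lt(diff(range(mu0)), 0.02)
})

test_that("cohort bundles are deterministic and serialize completely", {
  a <- small_cohort_args()
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  co1 <- make_cohort(a$pspec, a$cspec, dir = d1, r_brain = 3)
  co2 <- make_cohort(a$pspec, a$cspec, dir = d2, r_brain = 3)
  expect_equal(co1$truth, co2$truth)
  expect_identical(co1$demographics, co2$demographics)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_length(man, 6L)
  id <- co1$demographics$subject_id[1]
  expect_true(all(file.exists(file.path(d1, id,
                                        c("dwi.nii.gz", "dwi.bval", "dwi.bvec",
                                          "wm.nii.gz", "wmh.nii.gz")))))
  # written DWI matches the regenerated phantom bit-for-bit at float32
  ph <- make_phantom(freewater:::.subject_spec(a$pspec, co1$plan[1, ]))
  dwi2 <- read_dwi(file.path(d1, id, "dwi.nii.gz"),
                   file.path(d1, id, "dwi.bval"), file.path(d1, id, "dwi.bvec"))
  expect_equal(dwi2$signal, ph$dwi$signal, tolerance = 1e-5)
  unlink(c(d1, d2), recursive = TRUE)
})
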