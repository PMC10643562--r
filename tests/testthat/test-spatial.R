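# Misalignment sampling, transform construction, resampling, augmentation
# gating and the pipeline ordering contract.

test_that("sampled parameters respect their bounds and are centered", {
  set.seed(42)
  cfg <- misalignment_config()
  n <- 2e4
  d <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    p <- sample_misalignment(cfg)
    d[i, ] <- c(p$translation_mm, p$rotation_deg, p$squeeze_factor)
  }
  expect_true(all(abs(d[, 1]) <= 10))
  expect_true(all(abs(d[, 2]) <= 10))
  expect_true(all(abs(d[, 3]) <= 6))
  expect_true(all(abs(d[, 4]) <= 15))
  expect_true(all(abs(d[, 5] - 1) <= 0.1))
  # empirical means within 3 standard errors of the uniform-center values
  ses <- apply(d, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(colMeans(d) - c(0, 0, 0, 0, 1)) < 3 * ses + 1e-12))
})

test_that("zero-amplitude config always yields the identity parameters", {
  set.seed(1)
  cfg <- misalignment_config(c(0, 0, 0), 0, 0, probability = 1)
  for (i in 1:20) {
    p <- sample_misalignment(cfg)
    expect_identical(p$translation_mm, c(0, 0, 0))
    expect_identical(p$rotation_deg, 0)
    expect_identical(p$squeeze_factor, 1)
  }
})

test_that("config invariants are enforced at construction", {
  expect_error(misalignment_config(c(-1, 0, 0)), class = "misalignr_invalid_config")
  expect_error(misalignment_config(probability = 1.5), class = "misalignr_invalid_config")
})

test_that("build_transform composes translation, rotation and squeeze correctly", {
  expect_equal(build_transform(misalignment_params(), c(5, 5, 5))$matrix, diag(4))
  # pure translation moves every point by t
  tf <- build_transform(misalignment_params(c(5, 0, 0)), c(13, -2, 7))
  p <- matrix(c(1, 2, 3, -4, 0, 9), 2, 3, byrow = TRUE)
  expect_equal(transform_points(tf, p), p + rep(c(5, 0, 0), each = 2))
  # 90 degree in-plane rotation about c maps c+(r,0,0) to c+(0,r,0)
  cc <- c(10, 20, 5)
  tf90 <- build_transform(misalignment_params(rotation_deg = 90), cc)
  expect_equal(as.numeric(transform_points(tf90, cc + c(3, 0, 0))),
               cc + c(0, 3, 0), tolerance = 1e-12)
  # squeeze scales the dorsal-ventral offset about the center only
  tfs <- build_transform(misalignment_params(squeeze_factor = 0.9), cc)
  expect_equal(as.numeric(transform_points(tfs, cc + c(0, 4, 0))),
               cc + c(0, 3.6, 0), tolerance = 1e-12)
  expect_equal(as.numeric(transform_points(tfs, cc)), cc, tolerance = 1e-12)
})

test_that("resampling: identity is bit-exact, voxel shift is an index shift", {
  sp <- c(1.25, 1.25, 3)
  v <- array(rnorm(48 * 48 * 10), c(48, 48, 10))
  expect_identical(resample_with_transform(v, sp, spatial_transform(), "linear"), v)
  tf <- build_transform(misalignment_params(c(1.25, 0, 0)), c(0, 0, 0))
  sh <- resample_with_transform(v, sp, tf, "nearest", fill_value = -99)
  expect_identical(sh[2:48, , ], v[1:47, , ])
  expect_true(all(sh[1, , ] == -99))
})

test_that("apply-then-invert round trip is accurate on a smooth volume", {
  set.seed(9)
  sp <- c(1.25, 1.25, 3)
  v <- misalignr:::gaussian_smooth(array(rnorm(48 * 48 * 10), c(48, 48, 10)), sp, c(6, 6, 9))
  tf <- build_transform(misalignment_params(c(3, -2, 1.5), 7, 1.05), c(30, 30, 15))
  back <- resample_with_transform(
    resample_with_transform(v, sp, tf, "linear"), sp, invert_transform(tf), "linear")
  interior <- array(FALSE, dim(v)); interior[10:39, 10:39, 3:8] <- TRUE
  expect_lt(max(abs(back - v)[interior]) / diff(range(v)), 0.02)
})

test_that("singular transforms are rejected", {
  m <- diag(4); m[1, 1] <- 0
  expect_error(spatial_transform(m), class = "misalignr_singular_transform")
})

test_that("gating off returns the exam unchanged bit-for-bit", {
  ex <- tiny_exam(seed = 5)
  set.seed(3)
  out <- apply_misalignment_augmentation(ex, misalignment_config(probability = 0))
  expect_identical(out$t2w, ex$t2w)
  expect_identical(out$lesion_mask_t2w, ex$lesion_mask_t2w)
  expect_null(attr(out, "misalignment_applied"))
})

test_that("forced translation displaces T2w and its labels, never the DWI domain", {
  ex <- tiny_exam(seed = 5, noise = 0)
  t <- c(5, -2.5, 3)
  out <- apply_misalignment_augmentation(ex, force_params = misalignment_params(t))
  shift <- misalignr:::mask_centroid_mm(out$lesion_mask_t2w, ex$spacing) -
    misalignr:::mask_centroid_mm(ex$lesion_mask_t2w, ex$spacing)
  expect_true(all(abs(shift - t) <= ex$spacing))
  for (nm in c("dwi_high_b", "adc", "dwi_low_b", "lesion_mask_dwi"))
    expect_identical(out[[nm]], ex[[nm]])
  expect_equal(attr(out, "misalignment_applied")$translation_mm, t)
})

test_that("image and label move together under the sampled transform", {
  ex <- tiny_exam(seed = 8, noise = 0)
  params <- misalignment_params(c(4, 3, 0), 10, 0.95)
  out <- apply_misalignment_augmentation(ex, force_params = params)
  # analytically transformed ideal mask
  ctr <- misalignr:::grid_center_mm(dim(ex$t2w), ex$spacing)
  ideal <- resample_with_transform(ex$lesion_mask_t2w, ex$spacing,
                                   build_transform(params, ctr), "nearest", 0)
  expect_gte(dice(out$lesion_mask_t2w, ideal), 0.9)
})

test_that("inter-domain lesion Dice decreases with translation magnitude", {
  d <- vapply(c(2, 6, 10), function(mag) {
    ex <- generate_phantom(tiny_phantom_config(
      seed = 4, n_lesions = 1, noise = 0,
      misalign = misalignment_params(c(mag, 0, 0))))
    dice(ex$lesion_mask_t2w, ex$lesion_mask_dwi)
  }, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("pipeline ordering contract accepts misalign-first and rejects the reverse", {
  ms <- misalignment_stage(misalignment_config(probability = 0.2))
  gs <- global_stage(identity, name = "global_affine")
  expect_silent(augmentation_pipeline(ms, gs))
  expect_silent(augmentation_pipeline(ms))
  err <- expect_error(augmentation_pipeline(gs, ms), class = "misalignr_pipeline_order")
  expect_match(conditionMessage(err), "misalignment")
  expect_match(conditionMessage(err), "global_affine")
})

test_that("a composed pipeline applies its stages to the exam", {
  ex <- tiny_exam(seed = 5)
  pl <- augmentation_pipeline(
    misalignment_stage(misalignment_config(c(0, 0, 0), 0, 0, probability = 1)),
    global_stage(function(e) { e$t2w <- e$t2w + 1; e }, name = "shift"))
  out <- pl(ex)
  expect_equal(out$t2w, ex$t2w + 1)
})
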