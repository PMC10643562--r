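# Mutual information, both registration methods, and propagation.

test_that("mutual information matches a brute-force joint histogram", {
  set.seed(5)
  a <- array(runif(256), c(8, 8, 4)); b <- array(runif(256), c(8, 8, 4))
  bins <- 8
  ra <- range(a); rb <- range(b)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1, 1), bins)
  J <- matrix(0, bins, bins)
  for (k in seq_along(a)) J[ia[k], ib[k]] <- J[ia[k], ib[k]] + 1
  J <- J / length(a)
  mi_bf <- 0
  for (r in 1:bins) for (cc in 1:bins)
    if (J[r, cc] > 0)
      mi_bf <- mi_bf + J[r, cc] * log(J[r, cc] / (sum(J[r, ]) * sum(J[, cc])))
  expect_equal(mutual_information(a, b, bins), mi_bf, tolerance = 1e-12)
})

test_that("self-information equals the marginal entropy", {
  set.seed(6)
  a <- array(runif(4000), c(20, 20, 10))
  bins <- 16
  ia <- pmin(pmax(floor((a - min(a)) / diff(range(a)) * bins) + 1, 1), bins)
  p <- tabulate(ia, bins) / length(a)
  expect_equal(mutual_information(a, a, bins), -sum(p[p > 0] * log(p[p > 0])),
               tolerance = 1e-12)
})

test_that("independent noise volumes share almost no information", {
  set.seed(7)
  n <- 1e6
  a <- array(runif(n), c(100, 100, 100))
  b <- array(runif(n), c(100, 100, 100))
  expect_lt(mutual_information(a, b, 32), 0.01)
})

test_that("a constant volume yields MI 0 with a warning", {
  a <- array(1, c(4, 4, 2)); b <- array(runif(32), c(4, 4, 2))
  expect_warning(mi <- mutual_information(a, b, 8), "constant")
  expect_equal(mi, 0)
})

test_that("GT-matching on identical masks is the identity within 0.5 mm", {
  ex <- tiny_exam(seed = 11, noise = 0)
  r <- register_gt_matching(
    list(prostate = ex$prostate_mask, lesions = ex$lesion_mask_t2w),
    list(prostate = ex$prostate_mask, lesions = ex$lesion_mask_t2w),
    ex$spacing)
  ctr <- misalignr:::grid_center_mm(dim(ex$t2w), ex$spacing)
  corners <- rbind(ctr, ctr + c(20, 0, 0), ctr + c(0, 20, 10))
  moved <- transform_points(r$transform, corners)
  expect_lt(max(abs(moved - corners)), 0.5)
})

test_that("GT-matching recovers a known pure offset within one voxel", {
  ex <- generate_phantom(tiny_phantom_config(
    seed = 13, noise = 0, misalign = misalignment_params(c(6, 0, 0))))
  r <- register_gt_matching(
    list(prostate = ex$prostate_mask, lesions = ex$lesion_mask_t2w),
    list(prostate = ex$prostate_mask_dwi, lesions = ex$lesion_mask_dwi),
    ex$spacing)
  # composing the recovered correction with the injected truth ~ identity
  comp <- compose_transforms(r$transform, ex$truth_transform)
  ctr <- misalignr:::grid_center_mm(dim(ex$t2w), ex$spacing)
  resid <- abs(transform_points(comp, ctr) - ctr)
  expect_true(all(resid <= ex$spacing))
})

test_that("GT-matching improves lesion overlap under rotation", {
  ex <- generate_phantom(tiny_phantom_config(
    seed = 17, noise = 0, misalign = misalignment_params(rotation_deg = 10)))
  pre <- mean(lesionwise_dice(ex$lesion_mask_t2w, ex$lesion_mask_dwi))
  reg <- register_exam(ex, method = "gt_matching")
  post <- mean(lesionwise_dice(reg$lesion_mask_t2w, reg$lesion_mask_dwi))
  expect_gte(post, pre)
})

test_that("empty prostate masks are rejected", {
  ex <- tiny_exam(seed = 11)
  empty <- array(0L, dim(ex$t2w))
  expect_error(register_gt_matching(list(prostate = empty), list(prostate = empty),
                                    ex$spacing),
               class = "misalignr_empty_mask")
})

test_that("B-spline self-registration stays within 0.5 mm over the gland", {
  ex <- tiny_exam(seed = 21)
  r <- register_bspline(ex$t2w, ex$t2w, ex$spacing)
  idx <- which(ex$prostate_mask > 0, arr.ind = TRUE)
  pts <- list(x = (idx[, 1] - 1) * ex$spacing[1],
              y = (idx[, 2] - 1) * ex$spacing[2],
              z = (idx[, 3] - 1) * ex$spacing[3])
  q <- misalignr:::sample_coords(r$transform, pts)
  disp <- sqrt((q$x - pts$x)^2 + (q$y - pts$y)^2 + (q$z - pts$z)^2)
  expect_lt(stats::quantile(disp, 0.99), 0.5)
})

test_that("B-spline registration improves lesion Dice and mutual information", {
  ex <- generate_phantom(tiny_phantom_config(
    seed = 23, noise = 0.05, misalign = misalignment_params(c(4, 0, 0))))
  pre_dice <- mean(lesionwise_dice(ex$lesion_mask_t2w, ex$lesion_mask_dwi))
  pre_mi <- mutual_information(ex$t2w, ex$dwi_low_b)
  r <- register_exam_bspline(ex)
  out <- propagate(r, images = list(lb = ex$dwi_low_b),
                   masks = list(les = ex$lesion_mask_dwi), spacing = ex$spacing)
  post_dice <- mean(lesionwise_dice(ex$lesion_mask_t2w, out$masks$les))
  expect_gt(post_dice, pre_dice)
  expect_gte(mutual_information(ex$t2w, out$images$lb), pre_mi)
})

test_that("without a low-b DWI the intensity registration falls back to ADC", {
  ex <- tiny_exam(seed = 23)
  ex$dwi_low_b <- NULL
  opts <- reg_options(affine_maxit = c(20, 0, 0), ffd_maxit = 0)
  expect_warning(register_exam_bspline(ex, opts), "falling back")
})

test_that("propagation applies one fitted transform to all siblings", {
  ex <- tiny_exam(seed = 25, noise = 0)
  # identity result: outputs bit-equal
  rid <- misalignr:::registration_result(
    spatial_transform(), 0, "identity", list(dim = dim(ex$t2w), spacing = ex$spacing))
  out <- propagate(rid, images = list(a = ex$adc), masks = list(m = ex$lesion_mask_dwi),
                   spacing = ex$spacing)
  expect_identical(out$images$a, ex$adc)
  expect_identical(out$masks$m, ex$lesion_mask_dwi)
  # known translation: mask centroid moves accordingly
  t <- c(3.75, -2.5, 0)
  rtr <- misalignr:::registration_result(
    build_transform(misalignment_params(t), c(0, 0, 0)), 0, "gt_matching",
    list(dim = dim(ex$t2w), spacing = ex$spacing))
  moved <- propagate(rtr, masks = list(m = ex$lesion_mask_dwi), spacing = ex$spacing)
  shift <- misalignr:::mask_centroid_mm(moved$masks$m, ex$spacing) -
    misalignr:::mask_centroid_mm(ex$lesion_mask_dwi, ex$spacing)
  expect_true(all(abs(shift - t) <= ex$spacing))
  # two images propagated together keep their relative alignment
  pair <- propagate(rtr, images = list(a = ex$dwi_high_b, b = ex$adc),
                    spacing = ex$spacing)
  interior <- pair$masks
  diff_before <- ex$dwi_high_b - ex$adc
  diff_after <- pair$images$a - pair$images$b
  ok <- ex$prostate_mask > 0
  shifted_diff <- propagate(rtr, images = list(d = diff_before), spacing = ex$spacing)$images$d
  expect_lt(max(abs((diff_after - shifted_diff)[ok])), 0.05)
  # volumes from another grid are rejected
  expect_error(propagate(rtr, images = list(x = array(0, c(4, 4, 4))), spacing = ex$spacing),
               class = "misalignr_domain_mismatch")
})

test_that("registration never modifies the fixed T2w-domain data", {
  ex <- generate_phantom(tiny_phantom_config(
    seed = 27, noise = 0, misalign = misalignment_params(c(5, 2, 0), 5)))
  reg <- register_exam(ex, method = "gt_matching")
  expect_identical(reg$t2w, ex$t2w)
  expect_identical(reg$lesion_mask_t2w, ex$lesion_mask_t2w)
  expect_identical(reg$prostate_mask, ex$prostate_mask)
})
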