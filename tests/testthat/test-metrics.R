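# Overlap metrics, the Dice density, patient scoring and the ROC stack.

test_that("dice matches the analytic formula and its conventions", {
  a <- array(0, c(10, 10, 2)); b <- a
  a[1:10, 1:10, 1] <- 1; b[1:10, 1:10, 1] <- 1
  expect_equal(dice(a, b), 1)
  b2 <- array(0, c(10, 10, 2)); b2[1:10, 1:10, 2] <- 1
  expect_equal(dice(a, b2), 0)
  # |A| = |B| = 100, overlap 50
  a3 <- array(0, c(20, 10, 1)); a3[1:10, , 1] <- 1
  b3 <- array(0, c(20, 10, 1)); b3[6:15, , 1] <- 1
  expect_equal(dice(a3, b3), 0.5)
  expect_equal(dice(a * 0, b * 0), 1)  # both empty: no disagreement
  expect_true(abs(dice(a, b2) - dice(b2, a)) < 1e-15)
  expect_error(dice(a, array(0, c(3, 3, 3))), class = "misalignr_shape_mismatch")
})

test_that("lesion-wise Dice pairs lesions greedily and scores orphans 0", {
  lab <- array(0L, c(30, 30, 4))
  lab[3:6, 3:6, 2] <- 1L; lab[12:16, 12:16, 2] <- 2L; lab[22:25, 22:25, 3] <- 3L
  expect_equal(lesionwise_dice(lab, lab), c(1, 1, 1))
  # shift lesion 3 entirely off its partner
  lab2 <- lab; lab2[lab2 == 3L] <- 0L; lab2[22:25, 2:5, 1] <- 3L
  v <- lesionwise_dice(lab, lab2)
  expect_true(0 %in% v)
  expect_equal(sort(v), c(0, 0, 1, 1))
  expect_equal(lesionwise_dice(lab, lab2, drop_orphans = TRUE), c(1, 1))
  expect_warning(out <- lesionwise_dice(array(0L, c(4, 4, 2)), array(0L, c(4, 4, 2))),
                 "no lesions")
  expect_length(out, 0)
})

test_that("partially shifted spheres match the closed-form overlap", {
  # two radius-5 spheres with centers 4 mm apart: lens-intersection volume
  r <- 5; d <- 4
  vint <- 2 * (pi * (r - d / 2)^2 * (3 * r - (r - d / 2)) / 3)
  expected <- vint / (4 / 3 * pi * r^3)
  sp <- c(0.5, 0.5, 0.5)
  dm <- c(48, 48, 48)
  g <- misalignr:::grid_coords_mm(dm, sp)
  ball <- function(cx) array(as.integer((g$x - cx)^2 + (g$y - 12)^2 + (g$z - 12)^2 <= r^2), dm)
  got <- lesionwise_dice(ball(10), ball(14))
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("dice_distribution reports sample statistics and a unit-mass density", {
  d1 <- dice_distribution(0.5)
  expect_equal(d1$mean, 0.5); expect_equal(d1$sd, 0)
  d2 <- dice_distribution(c(0.4, 0.6))
  expect_equal(d2$mean, 0.5)
  expect_equal(d2$sd, sqrt(sum((c(0.4, 0.6) - 0.5)^2) / 1))
  for (vals in list(c(0.2, 0.5, 0.55, 0.8, 0.9, 0.33), runif(40), rep(0.5, 4)))
    expect_lt(abs(trapz(dice_distribution(vals)$density$x,
                        dice_distribution(vals)$density$y) - 1), 1e-3)
  expect_error(dice_distribution(numeric(0)), class = "misalignr_empty_input")
})

test_that("patient score is the permutation-invariant maximum", {
  expect_equal(patient_score(array(0, c(5, 5, 2))), 0)
  m <- array(0, c(5, 5, 2)); m[3, 4, 1] <- 0.73
  expect_equal(patient_score(m), 0.73)
  set.seed(1)
  v <- array(runif(60), c(5, 4, 3))
  p <- array(sample(v), dim(v))
  expect_equal(patient_score(v), patient_score(p))
  expect_error(patient_score(numeric(0)), class = "misalignr_empty_input")
})

test_that("auroc equals the exhaustive pairwise oracle, including ties", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  set.seed(3)
  for (i in 1:100) {
    n <- sample(4:100, 1)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(auroc(s, l), auroc_oracle(s, l), tolerance = 1e-12)
  }
  expect_error(auroc(1:4, rep(1, 4)), class = "misalignr_single_class")
})

test_that("bootstrap CI contains the point estimate and is seed-stable", {
  set.seed(4)
  l <- rep(0:1, each = 30)
  s <- rnorm(60) + l
  ci <- bootstrap_auroc_ci(s, l, B = 400, seed = 11)
  a <- attr(ci, "auroc")
  expect_gte(a, ci[1]); expect_lte(a, ci[2])
  ci2 <- bootstrap_auroc_ci(s, l, B = 400, seed = 11)
  expect_identical(as.numeric(ci), as.numeric(ci2))
})

test_that("the DeLong test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:5) {
    l <- c(rep(0, 25), rep(1, 15))
    sa <- rnorm(40) + l; sb <- rnorm(40) + 0.6 * l
    mine <- delong_test(sa, sb, l)
    ref <- pROC::roc.test(pROC::roc(l, sa, quiet = TRUE, direction = "<"),
                          pROC::roc(l, sb, quiet = TRUE, direction = "<"),
                          method = "delong")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$auroc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  }
})

test_that("identical score vectors yield the degenerate DeLong policy p = 1", {
  l <- rep(0:1, each = 10); s <- rnorm(20) + l
  expect_warning(res <- delong_test(s, s, l), "variance")
  expect_equal(res$p_value, 1)
  expect_equal(res$difference, 0)
})

test_that("DeLong variance is consistent with the bootstrap at n = 200", {
  set.seed(6)
  l <- rep(0:1, each = 100)
  s <- rnorm(200) + 1.19 * l
  # DeLong variance of a single AUROC from the structural components
  comp <- misalignr:::delong_components(s, l)
  v_delong <- stats::var(comp$v10) / sum(l == 1) + stats::var(comp$v01) / sum(l == 0)
  reps <- attr(bootstrap_auroc_ci(s, l, B = 2000, seed = 1), "replicates")
  expect_lt(abs(v_delong / stats::var(reps) - 1), 0.2)
})

test_that("PI-RADS operating points come from the contingency table", {
  op <- pirads_operating_point(c(2, 3, 4, 5, 2, 3), c(0, 0, 1, 1, 0, 1), 4)
  expect_equal(op$sensitivity, 2 / 3)
  expect_equal(op$specificity, 1)
  op1 <- pirads_operating_point(c(2, 3, 4, 5, 2, 3), c(0, 0, 1, 1, 0, 1), 1)
  expect_equal(op1$sensitivity, 1)
  expect_error(pirads_operating_point(c(3, 4), c(1, 1), 3), class = "misalignr_single_class")
})

test_that("configuration tables mark the reference and compare against it", {
  set.seed(7)
  l <- rep(0:1, each = 25)
  sa <- rnorm(50) + l; sb <- rnorm(50) + 0.5 * l
  tab <- evaluate_configurations(list(ref = sa), l, "ref", B = 200, seed = 1)
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$p_vs_reference))
  tab2 <- suppressWarnings(
    evaluate_configurations(list(a = sa, b = sa), l, "a", B = 200, seed = 1))
  expect_equal(tab2$p_vs_reference[tab2$configuration == "b"], 1)
  expect_error(evaluate_configurations(list(a = sa), l, "missing"),
               class = "misalignr_missing_reference")
})
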