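# Evaluation layer: inter-modality lesion overlap (Dice and its density),
# patient-level scoring from a segmentation probability map, AUROC with
# bootstrap confidence intervals, the DeLong test for paired AUROCs, and
# PI-RADS operating points.

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Both masks empty is defined as perfect
#' agreement (Dice 1): there is no disagreement to penalize.
#'
#' @param a,b arrays of identical shape; nonzero means foreground.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    abort("dice: mask shapes differ", "misalignr_shape_mismatch")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Lesion-wise Dice between two lesion label volumes
#'
#' Lesions are paired greedily by maximal voxel overlap; each matched pair
#' contributes its Dice, and any unmatched (orphan) lesion in either volume
#' contributes 0 — an annotation present in only one modality is a complete
#' disagreement. Set `drop_orphans = TRUE` to score matched pairs only.
#'
#' @param labels_a,labels_b integer label volumes on a common grid
#'   (0 background, k > 0 lesion id).
#' @param drop_orphans if `TRUE`, unmatched lesions are omitted instead of
#'   scored 0.
#' @return Numeric vector of per-lesion Dice values (empty, with a warning,
#'   when neither volume contains a lesion).
#' @export
lesionwise_dice <- function(labels_a, labels_b, drop_orphans = FALSE) {
  if (!identical(dim(labels_a), dim(labels_b)))
    abort("lesionwise_dice: label volumes on different grids", "misalignr_shape_mismatch")
  ids_a <- setdiff(sort(unique(as.vector(labels_a))), 0)
  ids_b <- setdiff(sort(unique(as.vector(labels_b))), 0)
  if (!length(ids_a) && !length(ids_b)) {
    warning("no lesions in either label volume")
    return(numeric(0))
  }
  size_a <- vapply(ids_a, function(i) sum(labels_a == i), numeric(1))
  size_b <- vapply(ids_b, function(i) sum(labels_b == i), numeric(1))
  ov <- matrix(0, length(ids_a), length(ids_b))
  if (length(ids_a) && length(ids_b)) {
    both <- labels_a > 0 & labels_b > 0
    if (any(both)) {
      tab <- table(factor(labels_a[both], levels = ids_a),
                   factor(labels_b[both], levels = ids_b))
      ov <- matrix(as.numeric(tab), length(ids_a), length(ids_b))
    }
  }
  vals <- numeric(0)
  free_a <- seq_along(ids_a); free_b <- seq_along(ids_b)
  while (length(free_a) && length(free_b)) {
    sub <- ov[free_a, free_b, drop = FALSE]
    if (max(sub) == 0) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ia <- free_a[w[1]]; ib <- free_b[w[2]]
    vals <- c(vals, 2 * ov[ia, ib] / (size_a[ia] + size_b[ib]))
    free_a <- setdiff(free_a, ia); free_b <- setdiff(free_b, ib)
  }
  if (!drop_orphans) vals <- c(vals, rep(0, length(free_a) + length(free_b)))
  vals
}

#' Summarize a set of Dice values as a distribution
#'
#' Sample mean, sample standard deviation, and a Gaussian-kernel density on
#' \[0, 1\] with boundary reflection at both ends (so the density integrates
#' to one on the unit interval). Bandwidth by Silverman's rule.
#'
#' @param values Dice values, each in \[0, 1\]; must be nonempty.
#' @param n_grid number of density evaluation points.
#' @return An object of class `dice_distribution` with fields `values`,
#'   `mean`, `sd`, and `density` (data frame `x`, `y`).
#' @export
dice_distribution <- function(values, n_grid = 512) {
  if (!length(values)) abort("dice_distribution: empty input", "misalignr_empty_input")
  if (any(values < -1e-9 | values > 1 + 1e-9))
    abort("dice_distribution: values outside [0, 1]", "misalignr_invalid_input")
  values <- pmin(pmax(values, 0), 1)
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  # Silverman bandwidth, floored so a degenerate (zero-spread) sample still
  # yields a density resolvable on the evaluation grid
  h <- max(if (length(values) > 1 && stats::sd(values) > 0) stats::bw.nrd0(values) else 0,
           2 / n_grid)
  x <- seq(0, 1, length.out = n_grid)
  kde <- function(pts) vapply(pts, function(p) mean(stats::dnorm(p, values, h)), numeric(1))
  y <- kde(x) + kde(-x) + kde(2 - x)  # reflect mass leaking past 0 and 1
  structure(list(values = values, mean = m, sd = s,
                 density = data.frame(x = x, y = y)),
            class = "dice_distribution")
}

#' @export
print.dice_distribution <- function(x, ...) {
  cat(sprintf("<dice_distribution> n = %d, Dice = %.2f +/- %.2f\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Patient-level score from a lesion probability map
#'
#' The patient-wise cancer probability is the maximum voxel value of the
#' predicted lesion probability map.
#'
#' @param prob_map array of voxelwise probabilities in \[0, 1\].
#' @return Scalar score.
#' @export
patient_score <- function(prob_map) {
  if (!length(prob_map)) abort("patient_score: empty volume", "misalignr_empty_input")
  if (any(prob_map < -1e-9 | prob_map > 1 + 1e-9, na.rm = TRUE))
    abort("patient_score: probabilities outside [0, 1]", "misalignr_invalid_input")
  max(prob_map, na.rm = TRUE)
}

check_two_classes <- function(labels) {
  if (length(unique(labels[!is.na(labels)])) < 2)
    abort("both classes (0 and 1) must be present", "misalignr_single_class")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs ordered correctly, ties counted 1/2 — i.e.
#' the probability a random positive outscores a random negative.
#'
#' @param scores numeric scores, higher = more suspicious.
#' @param labels 0/1 ground truth.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for AUROC
#'
#' Case resampling over exams; replicates that draw a single class are
#' redrawn. Percentile interval at level `1 - alpha`.
#'
#' @param scores,labels as in [auroc()].
#' @param B number of bootstrap replications (default 1000).
#' @param alpha two-sided miscoverage (default 0.05 for a 95% interval).
#' @param seed optional integer seed for reproducible intervals.
#' @return Length-2 vector `(lo, hi)` with attributes `auroc` (point
#'   estimate) and `replicates`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, B = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(B >= 100)
  check_two_classes(labels)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    reps[b] <- auroc(scores[idx], labels[idx])
  }
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2)))
  structure(ci, auroc = auroc(scores, labels), replicates = reps)
}

# DeLong structural components: V10[i] = mean_j psi(x_i, y_j) over negatives,
# V01[j] = mean_i psi(x_i, y_j) over positives, psi the Mann-Whitney kernel.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUROCs
#'
#' Two-sided test of equal AUROC for two score vectors evaluated on the
#' same exams, using the DeLong structural-component covariance estimator.
#' When the estimated variance of the difference is (numerically) zero —
#' e.g. identical score vectors — the test is uninformative and `p = 1` is
#' returned with a warning.
#'
#' @param scores_a,scores_b paired score vectors on identical exams.
#' @param labels 0/1 ground truth shared by both.
#' @return List with `auroc_a`, `auroc_b`, `difference`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  check_two_classes(labels)
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / n1 + s01 / n0
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auc - cb$auc
  if (!is.finite(v) || v <= .Machine$double.eps * 100) {
    warning("DeLong variance of the AUROC difference is zero; returning p = 1")
    return(list(auroc_a = ca$auc, auroc_b = cb$auc, difference = d,
                z = 0, p_value = 1))
  }
  z <- d / sqrt(v)
  list(auroc_a = ca$auc, auroc_b = cb$auc, difference = d,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Sensitivity and specificity of a PI-RADS operating point
#'
#' Classifies an exam positive when its PI-RADS score is at or above the
#' threshold; thresholds 3 (equivocal risk) and 4 (high risk) are the
#' clinically informative operating points.
#'
#' @param pirads integer scores in 1..5.
#' @param labels 0/1 ground truth.
#' @param threshold classify positive when `pirads >= threshold`.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
pirads_operating_point <- function(pirads, labels, threshold) {
  stopifnot(all(pirads %in% 1:5), length(pirads) == length(labels))
  check_two_classes(labels)
  pred <- pirads >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  list(threshold = threshold,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Compare scoring configurations against a reference
#'
#' For each named score set: AUROC, bootstrap confidence interval, and the
#' DeLong p-value against the reference configuration (omitted for the
#' reference row itself). All score sets must be paired on the same exams.
#'
#' @param score_sets named list of score vectors.
#' @param labels shared 0/1 ground truth.
#' @param reference_name name of the reference configuration.
#' @param B,alpha,seed bootstrap settings, see [bootstrap_auroc_ci()].
#' @return Data frame with one row per configuration: `configuration`,
#'   `auroc`, `ci_lo`, `ci_hi`, `p_vs_reference`, `reference`.
#' @export
evaluate_configurations <- function(score_sets, labels, reference_name,
                                    B = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(is.list(score_sets), length(score_sets) >= 1)
  if (is.null(names(score_sets)) || !reference_name %in% names(score_sets))
    abort(sprintf("reference configuration '%s' missing from score_sets", reference_name),
          "misalignr_missing_reference")
  n <- length(labels)
  for (nm in names(score_sets))
    if (length(score_sets[[nm]]) != n)
      abort(sprintf("score set '%s' is not paired with the labels", nm),
            "misalignr_invalid_input")
  ref <- score_sets[[reference_name]]
  rows <- lapply(names(score_sets), function(nm) {
    ci <- bootstrap_auroc_ci(score_sets[[nm]], labels, B = B, alpha = alpha, seed = seed)
    p <- if (nm == reference_name) NA_real_ else
      suppressWarnings(delong_test(score_sets[[nm]], ref, labels)$p_value)
    data.frame(configuration = nm, auroc = attr(ci, "auroc"),
               ci_lo = ci[1], ci_hi = ci[2], p_vs_reference = p,
               reference = nm == reference_name, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
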