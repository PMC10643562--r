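# Deterministic preprocessing: resampling to a common resolution,
# modality-specific normalization, prostate cropping, and balanced
# class sampling for training loaders.

#' Preprocessing settings
#'
#' @param target_spacing common resolution, mm; default 0.3125 mm in-plane
#'   with the 3 mm slice distance left unchanged.
#' @param crop_margin_mm per-axis margin added around the prostate bounding
#'   box when cropping.
#' @param adc_dataset_stats `(mean, sd)` of ADC intensities pooled across
#'   the training set; required to normalize ADC maps, whose voxel values
#'   are quasi-quantitative and must not be rescaled per patient.
#' @param patch_size recorded network input patch size (x, y, z); carried
#'   in the config for provenance, unused by the preprocessing itself.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(0.3125, 0.3125, 3.0),
                              crop_margin_mm = c(10, 10, 10),
                              adc_dataset_stats = NULL,
                              patch_size = c(320, 256, 20)) {
  stopifnot(length(target_spacing) == 3, length(crop_margin_mm) == 3)
  if (any(target_spacing <= 0)) abort("target_spacing must be positive", "misalignr_invalid_config")
  if (any(crop_margin_mm < 0)) abort("crop_margin_mm must be >= 0", "misalignr_invalid_config")
  if (!is.null(adc_dataset_stats)) stopifnot(length(adc_dataset_stats) == 2,
                                             adc_dataset_stats[2] > 0)
  structure(list(target_spacing = as.numeric(target_spacing),
                 crop_margin_mm = as.numeric(crop_margin_mm),
                 adc_dataset_stats = adc_dataset_stats,
                 patch_size = as.integer(patch_size)),
            class = "preprocess_config")
}

resample_grid <- function(vol, spacing, target_spacing, interpolation, fill) {
  d <- dim(vol)
  nd <- pmax(1L, as.integer(round(d * spacing / target_spacing)))
  if (all(nd == d) && all(spacing == target_spacing)) return(vol)
  ci <- rep((seq_len(nd[1]) - 1) * target_spacing[1] / spacing[1] + 1,
            times = nd[2] * nd[3])
  cj <- rep(rep((seq_len(nd[2]) - 1) * target_spacing[2] / spacing[2] + 1,
                each = nd[1]), times = nd[3])
  ck <- rep((seq_len(nd[3]) - 1) * target_spacing[3] / spacing[3] + 1,
            each = nd[1] * nd[2])
  v <- if (interpolation == "linear") interp_trilinear(vol, ci, cj, ck, fill)
       else interp_nearest(vol, ci, cj, ck, fill)
  array(v, dim = nd)
}

#' Resample an exam to the target spacing
#'
#' All image volumes are linearly resampled to `config$target_spacing`
#' (label volumes with nearest-neighbor interpolation); the physical extent
#' is preserved within one voxel. An exam already at target spacing is
#' returned unchanged.
#'
#' @param exam a [multimodal_exam()].
#' @param config a [preprocess_config()].
#' @return The resampled exam.
#' @export
resample_to_target <- function(exam, config = preprocess_config()) {
  stopifnot(inherits(exam, "multimodal_exam"))
  ts <- config$target_spacing
  if (all(exam$spacing == ts)) return(exam)
  for (nm in c("t2w", "dwi_high_b", "adc", "dwi_low_b")) {
    if (is.null(exam[[nm]])) next
    exam[[nm]] <- resample_grid(exam[[nm]], exam$spacing, ts, "linear", min(exam[[nm]]))
  }
  for (nm in c("lesion_mask_t2w", "lesion_mask_dwi", "prostate_mask", "prostate_mask_dwi")) {
    if (is.null(exam[[nm]])) next
    m <- resample_grid(exam[[nm]], exam$spacing, ts, "nearest", 0)
    exam[[nm]] <- array(as.integer(m), dim = dim(m))
  }
  exam$spacing <- ts
  exam
}

#' Normalize an exam's modalities
#'
#' T2w and the DWI channels are z-scored patient-wise (their intensities
#' are arbitrary units); the ADC map is z-scored with mean/sd pooled across
#' the training dataset (its values map to a physical quantity, so the same
#' ADC value must normalize identically in every exam).
#'
#' @param exam a [multimodal_exam()].
#' @param config a [preprocess_config()] with `adc_dataset_stats` set.
#' @return The normalized exam.
#' @export
normalize_exam <- function(exam, config) {
  stopifnot(inherits(exam, "multimodal_exam"))
  if (is.null(config$adc_dataset_stats))
    abort("adc_dataset_stats must be set to normalize the ADC map",
          "misalignr_invalid_config")
  for (nm in c("t2w", "dwi_high_b", "dwi_low_b")) {
    if (is.null(exam[[nm]])) next
    s <- stats::sd(exam[[nm]])
    if (!is.finite(s) || s == 0)
      abort(sprintf("cannot normalize '%s': per-exam standard deviation is zero", nm),
            "misalignr_degenerate_normalization")
    exam[[nm]] <- (exam[[nm]] - mean(exam[[nm]])) / s
  }
  st <- config$adc_dataset_stats
  exam$adc <- (exam$adc - st[1]) / st[2]
  exam
}

#' Pooled ADC intensity statistics over a set of exams
#'
#' @param exams list of [multimodal_exam()] objects (the training set).
#' @param prostate_only pool over prostate-masked voxels only (default) or
#'   over whole volumes.
#' @return `c(mean, sd)` suitable for [preprocess_config()].
#' @export
adc_dataset_stats <- function(exams, prostate_only = TRUE) {
  vals <- unlist(lapply(exams, function(e) {
    if (prostate_only) e$adc[e$prostate_mask > 0] else as.vector(e$adc)
  }))
  if (!length(vals)) abort("no ADC voxels to pool", "misalignr_empty_input")
  c(mean = mean(vals), sd = stats::sd(vals))
}

#' Crop an exam to the prostate bounding box
#'
#' All volumes are cropped to the prostate-mask bounding box dilated by
#' `config$crop_margin_mm` per axis (clipped to the grid); the gland and
#' every lesion voxel inside it survive the crop.
#'
#' @param exam a [multimodal_exam()].
#' @param config a [preprocess_config()].
#' @return The cropped exam.
#' @export
crop_to_prostate <- function(exam, config = preprocess_config()) {
  stopifnot(inherits(exam, "multimodal_exam"))
  idx <- which(exam$prostate_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty prostate mask", "misalignr_empty_mask")
  mvox <- ceiling(config$crop_margin_mm / exam$spacing)
  lo <- pmax(apply(idx, 2, min) - mvox, 1)
  hi <- pmin(apply(idx, 2, max) + mvox, dim(exam$prostate_mask))
  for (nm in c("t2w", "dwi_high_b", "adc", "dwi_low_b",
               "lesion_mask_t2w", "lesion_mask_dwi",
               "prostate_mask", "prostate_mask_dwi")) {
    if (is.null(exam[[nm]])) next
    exam[[nm]] <- exam[[nm]][lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  exam
}

#' Balanced class sampler
#'
#' Returns a draw function emulating a balanced data loader: each draw
#' first picks a class (0 or 1) uniformly, then an exam uniformly within
#' that class, so the long-run positive fraction is 1/2 regardless of the
#' dataset prevalence.
#'
#' @param labels per-exam 0/1 labels; both classes must be present.
#' @return A function `n -> integer vector` of exam indices.
#' @export
balanced_sampler <- function(labels) {
  check_two_classes(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  function(n) {
    take_pos <- stats::runif(n) < 0.5
    idx <- integer(n)
    idx[take_pos] <- pos[sample.int(length(pos), sum(take_pos), replace = TRUE)]
    idx[!take_pos] <- neg[sample.int(length(neg), sum(!take_pos), replace = TRUE)]
    idx
  }
}

#' Draw a balanced index stream
#'
#' Convenience wrapper around [balanced_sampler()] drawing `n` indices at
#' once. Deterministic under [set.seed()].
#'
#' @param labels per-exam 0/1 labels.
#' @param n number of draws.
#' @return Integer vector of exam indices of length `n`.
#' @export
balanced_indices <- function(labels, n) {
  balanced_sampler(labels)(n)
}
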