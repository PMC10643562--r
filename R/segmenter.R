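# A deliberately simple threshold-based lesion scorer used for end-to-end
# pipeline tests. It is NOT a diagnostic model: it exists so that the
# augmentation/registration/evaluation chain can be exercised with a
# segmenter whose behaviour is transparent. It multiplies per-modality
# lesion evidence (bright on high-b DWI, dark on ADC, dark on T2w) inside
# the gland, so inter-modality misalignment directly erodes its scores —
# the property the evaluation stack is meant to detect.

#' Toy multi-modal lesion probability map
#'
#' Voxelwise product of logistic lesion-evidence maps from the high-b DWI
#' (hyperintense), ADC (hypointense) and T2w (hypointense) channels,
#' restricted to the prostate mask and lightly smoothed. Scores fall when
#' the T2w evidence is displaced relative to the diffusion evidence.
#'
#' @param exam a [multimodal_exam()].
#' @param sharpness logistic slope on the z-scored intensities.
#' @return Array of probabilities in \[0, 1\] on the exam grid.
#' @export
toy_segment <- function(exam, sharpness = 3) {
  stopifnot(inherits(exam, "multimodal_exam"))
  pm <- exam$prostate_mask > 0
  if (!any(pm)) abort("toy_segment: empty prostate mask", "misalignr_empty_mask")
  zin <- function(v) {
    mu <- mean(v[pm]); s <- stats::sd(v[pm])
    if (!is.finite(s) || s == 0) s <- 1
    (v - mu) / s
  }
  p_dwi <- stats::plogis(sharpness * zin(exam$dwi_high_b))
  p_adc <- stats::plogis(-sharpness * zin(exam$adc))
  p_t2 <- stats::plogis(-sharpness * zin(exam$t2w))
  prob <- (p_dwi * p_adc * p_t2)^(1 / 3) * pm
  gaussian_smooth(prob, exam$spacing, c(1, 1, 0))
}

#' Patient-level toy score
#'
#' Maximum of the [toy_segment()] probability map — the patient-wise
#' scoring rule used throughout the evaluation layer.
#'
#' @param exam a [multimodal_exam()].
#' @param ... passed to [toy_segment()].
#' @return Scalar score in \[0, 1\].
#' @export
toy_patient_score <- function(exam, ...) {
  patient_score(toy_segment(exam, ...))
}
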