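# Misalignment augmentation: probability-gated random displacement of the
# T2w modality (with its lesion annotations) relative to the diffusion
# sequences. The displacement is the composition of a uniform translation,
# an in-plane rotation and a dorsal-ventral affine squeeze, each sampled
# uniformly on a symmetric interval around the identity, and is meant to be
# placed before any global augmentation in a training pipeline.

#' Misalignment augmentation bounds
#'
#' Maximal amplitudes for the three misalignment components and the gating
#' probability. Defaults are translations up to (10, 10, 6) mm along x, y,
#' z, rotations up to 15 degrees restricted to the x-y plane (the through-
#' plane spacing is too coarse for out-of-plane rotation), and an affine
#' squeeze of up to ratio 0.1 along the dorsal-ventral axis, mimicking the
#' distortion between T2w and DWI caused by magnetic-field inhomogeneity.
#' Typical gating probabilities are 0, 0.1, 0.2 or 0.4; any value in [0,1]
#' is accepted.
#'
#' @param max_translation_mm length-3 nonnegative amplitudes, mm.
#' @param max_rotation_deg nonnegative in-plane rotation amplitude, degrees.
#' @param max_squeeze_ratio nonnegative squeeze ratio r; factors are drawn
#'   from [1-r, 1+r].
#' @param probability gating probability in [0,1]: the chance that the three
#'   components are applied at all (jointly) to a given exam.
#' @return An object of class `misalignment_config`.
#' @export
misalignment_config <- function(max_translation_mm = c(10, 10, 6),
                                max_rotation_deg = 15,
                                max_squeeze_ratio = 0.1,
                                probability = 0.2) {
  stopifnot(length(max_translation_mm) == 3)
  if (any(max_translation_mm < 0) || max_rotation_deg < 0 || max_squeeze_ratio < 0)
    abort("misalignment amplitudes must be nonnegative", "misalignr_invalid_config")
  if (probability < 0 || probability > 1)
    abort("probability must lie in [0, 1]", "misalignr_invalid_config")
  structure(list(max_translation_mm = as.numeric(max_translation_mm),
                 max_rotation_deg = as.numeric(max_rotation_deg),
                 max_squeeze_ratio = as.numeric(max_squeeze_ratio),
                 probability = as.numeric(probability)),
            class = "misalignment_config")
}

#' One realization of the misalignment components
#'
#' @param translation_mm length-3 translation (tx, ty, tz), mm.
#' @param rotation_deg in-plane (about z) rotation angle, degrees.
#' @param squeeze_factor scale factor along the dorsal-ventral (y) axis;
#'   1 means no squeeze.
#' @return An object of class `misalignment_params`.
#' @export
misalignment_params <- function(translation_mm = c(0, 0, 0),
                                rotation_deg = 0,
                                squeeze_factor = 1) {
  stopifnot(length(translation_mm) == 3, is.finite(rotation_deg),
            is.finite(squeeze_factor), all(is.finite(translation_mm)))
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 squeeze_factor = as.numeric(squeeze_factor)),
            class = "misalignment_params")
}

#' @export
print.misalignment_params <- function(x, ...) {
  cat(sprintf("<misalignment_params> t = (%s) mm, rot = %.2f deg, squeeze = %.3f\n",
              paste(signif(x$translation_mm, 4), collapse = ", "),
              x$rotation_deg, x$squeeze_factor))
  invisible(x)
}

#' Sample one misalignment realization
#'
#' Each component is drawn independently and uniformly from its symmetric
#' interval: translations from \[-a, a\] per axis, the rotation from
#' \[-theta_max, theta_max\] and the squeeze factor from \[1-r, 1+r\]. The
#' draw order is fixed (tx, ty, tz, rotation, squeeze) so a seeded RNG
#' reproduces the stream. Uses R's global RNG; seed with [set.seed()].
#'
#' @param config a [misalignment_config()].
#' @return A [misalignment_params()].
#' @export
sample_misalignment <- function(config) {
  stopifnot(inherits(config, "misalignment_config"))
  a <- config$max_translation_mm
  t <- c(stats::runif(1, -a[1], a[1]),
         stats::runif(1, -a[2], a[2]),
         stats::runif(1, -a[3], a[3]))
  th <- stats::runif(1, -config$max_rotation_deg, config$max_rotation_deg)
  s <- stats::runif(1, 1 - config$max_squeeze_ratio, 1 + config$max_squeeze_ratio)
  misalignment_params(t, th, s)
}

#' Apply misalignment augmentation to an exam
#'
#' With probability `config$probability` the exam's T2w volume and its T2w-
#' domain lesion annotation are displaced by a freshly sampled misalignment
#' (linear interpolation for the image, nearest-neighbor for the labels);
#' with the complementary probability the exam is returned unchanged,
#' bit-for-bit. DWI-domain members (high-b DWI, low-b DWI, ADC and the
#' DWI-domain masks) are never touched. The per-exam draw order is fixed:
#' gate first, then (tx, ty, tz, rotation, squeeze) when the gate fires.
#'
#' @param exam a [multimodal_exam()].
#' @param config a [misalignment_config()].
#' @param center `"grid"` (default) rotates/squeezes about the geometric
#'   center of the voxel grid; `"prostate"` about the gland centroid.
#' @param force_params optional [misalignment_params()]: bypass both the
#'   gate and the sampling and apply exactly these parameters (used for
#'   testing and for injecting known ground truth).
#' @return The (possibly displaced) exam. When a displacement was applied,
#'   the sampled parameters and the built transform are attached as
#'   attributes `misalignment_applied` and `misalignment_transform`;
#'   otherwise `misalignment_applied` is `NULL`.
#' @export
apply_misalignment_augmentation <- function(exam, config,
                                            center = c("grid", "prostate"),
                                            force_params = NULL) {
  stopifnot(inherits(exam, "multimodal_exam"))
  center <- match.arg(center)
  if (is.null(force_params)) {
    stopifnot(inherits(config, "misalignment_config"))
    if (stats::runif(1) >= config$probability) {
      attr(exam, "misalignment_applied") <- NULL
      return(exam)
    }
    params <- sample_misalignment(config)
  } else {
    stopifnot(inherits(force_params, "misalignment_params"))
    params <- force_params
  }
  c_mm <- if (center == "prostate") mask_centroid_mm(exam$prostate_mask, exam$spacing)
          else grid_center_mm(dim(exam$t2w), exam$spacing)
  tf <- build_transform(params, c_mm)
  exam$t2w <- resample_with_transform(exam$t2w, exam$spacing, tf,
                                      "linear", fill_value = min(exam$t2w))
  exam$lesion_mask_t2w <- resample_with_transform(exam$lesion_mask_t2w, exam$spacing,
                                                  tf, "nearest", fill_value = 0)
  attr(exam, "misalignment_applied") <- params
  attr(exam, "misalignment_transform") <- tf
  exam
}

# ---- pipeline ordering contract ---------------------------------------------

#' Wrap the misalignment augmentation as a pipeline stage
#'
#' @param config a [misalignment_config()].
#' @param center see [apply_misalignment_augmentation()].
#' @return A callable stage of kind `"misalignment"` for
#'   [augmentation_pipeline()].
#' @export
misalignment_stage <- function(config, center = "grid") {
  stopifnot(inherits(config, "misalignment_config"))
  f <- function(exam) apply_misalignment_augmentation(exam, config, center = center)
  structure(f, class = "augmentation_stage", kind = "misalignment",
            stage_name = "misalignment")
}

#' Wrap a global (whole-exam) augmentation as a pipeline stage
#'
#' Global stages transform every channel of the exam identically (e.g. a
#' global affine or flip) and must come after any misalignment stage, since
#' the misalignment augmentation emulates an acquisition-level offset that
#' exists before any augmentation is applied.
#'
#' @param fn function taking and returning a [multimodal_exam()].
#' @param name stage name used in error messages.
#' @return A callable stage of kind `"global"`.
#' @export
global_stage <- function(fn, name = "global") {
  stopifnot(is.function(fn))
  structure(fn, class = "augmentation_stage", kind = "global", stage_name = name)
}

#' Compose augmentation stages with ordering validation
#'
#' Builds a batch-transform pipeline from stages and enforces the ordering
#' contract: every misalignment stage must precede every global spatial
#' stage (to avoid interpolating an already globally-transformed image a
#' second time). A violation raises a configuration error naming both
#' stages.
#'
#' @param ... stages created by [misalignment_stage()], [global_stage()],
#'   or any bare function (treated as kind `"other"`, unconstrained).
#' @return A function `exam -> exam` applying the stages in order, with the
#'   stage list attached as attribute `stages`.
#' @export
augmentation_pipeline <- function(...) {
  stages <- list(...)
  kinds <- vapply(stages, function(s) attr(s, "kind") %||% "other", character(1))
  names_ <- vapply(stages, function(s) attr(s, "stage_name") %||% "stage", character(1))
  g_first <- which(kinds == "global")
  m_idx <- which(kinds == "misalignment")
  if (length(g_first) && length(m_idx) && any(m_idx > min(g_first))) {
    bad <- min(m_idx[m_idx > min(g_first)])
    abort(sprintf(
      "misalignment stage '%s' (position %d) must precede global stage '%s' (position %d)",
      names_[bad], bad, names_[min(g_first)], min(g_first)),
      "misalignr_pipeline_order")
  }
  f <- function(exam) {
    for (s in stages) exam <- s(exam)
    exam
  }
  attr(f, "stages") <- stages
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
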