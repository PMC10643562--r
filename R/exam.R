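# The multi-modal exam container: one patient's co-acquired volumes, masks,
# spacing and labels — the unit every pipeline stage consumes.

#' Construct a multi-modal prostate MRI exam
#'
#' Holds the bi-parametric channel set (T2w, highest-b DWI, ADC, optionally
#' the lowest-b DWI) on a shared voxel grid, lesion label volumes annotated
#' in the T2w and the DWI domain, the prostate gland mask, and patient-level
#' labels. Lesion label volumes are integer-coded: 0 background, k > 0 the
#' k-th lesion.
#'
#' @param t2w,dwi_high_b,adc 3D numeric arrays on a common grid.
#' @param spacing length-3 voxel spacing in mm (x, y, z).
#' @param lesion_mask_t2w,lesion_mask_dwi integer label volumes (may be all
#'   zero when no lesion is annotated).
#' @param prostate_mask binary gland mask (T2w domain).
#' @param dwi_low_b optional lowest-b DWI volume (DWI domain).
#' @param prostate_mask_dwi optional gland mask in the DWI domain (needed by
#'   segmentation-driven registration).
#' @param cspca_label 0/1 clinically-significant-cancer label, or `NA`.
#' @param pirads integer 1..5 PI-RADS score, or `NA`.
#' @return An object of class `multimodal_exam`.
#' @export
multimodal_exam <- function(t2w, dwi_high_b, adc, spacing,
                            lesion_mask_t2w, lesion_mask_dwi, prostate_mask,
                            dwi_low_b = NULL, prostate_mask_dwi = NULL,
                            cspca_label = NA, pirads = NA) {
  vols <- list(t2w = t2w, dwi_high_b = dwi_high_b, adc = adc,
               lesion_mask_t2w = lesion_mask_t2w,
               lesion_mask_dwi = lesion_mask_dwi,
               prostate_mask = prostate_mask)
  if (!is.null(dwi_low_b)) vols$dwi_low_b <- dwi_low_b
  if (!is.null(prostate_mask_dwi)) vols$prostate_mask_dwi <- prostate_mask_dwi
  d <- dim(t2w)
  if (length(d) != 3) abort("exam volumes must be 3D arrays", "misalignr_invalid_exam")
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]), d))
      abort(sprintf("volume '%s' does not share the exam grid shape", nm),
            "misalignr_invalid_exam")
  }
  if (length(spacing) != 3 || any(spacing <= 0))
    abort("spacing must be 3 positive values (mm)", "misalignr_invalid_exam")
  for (nm in c("lesion_mask_t2w", "lesion_mask_dwi", "prostate_mask")) {
    m <- vols[[nm]]
    if (any(m < 0) || any(m != floor(m)))
      abort(sprintf("label volume '%s' must contain nonnegative integers", nm),
            "misalignr_invalid_exam")
  }
  structure(list(
    t2w = t2w, dwi_high_b = dwi_high_b, adc = adc, dwi_low_b = dwi_low_b,
    spacing = as.numeric(spacing),
    lesion_mask_t2w = lesion_mask_t2w, lesion_mask_dwi = lesion_mask_dwi,
    prostate_mask = prostate_mask, prostate_mask_dwi = prostate_mask_dwi,
    cspca_label = cspca_label, pirads = pirads
  ), class = "multimodal_exam")
}

#' @export
print.multimodal_exam <- function(x, ...) {
  d <- dim(x$t2w)
  cat(sprintf("<%s> %dx%dx%d @ (%s) mm; lesions T2w/DWI: %d/%d; csPCa=%s PI-RADS=%s\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = ", "),
              max(x$lesion_mask_t2w), max(x$lesion_mask_dwi),
              as.character(x$cspca_label), as.character(x$pirads)))
  invisible(x)
}

#' Names of the exam members living in the DWI domain
#' @keywords internal
dwi_domain_members <- function() c("dwi_high_b", "adc", "dwi_low_b",
                                   "lesion_mask_dwi", "prostate_mask_dwi")
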