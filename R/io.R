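# NIfTI volume I/O (canonicalized to RAS), manifest handling, cohort
# arithmetic, and deterministic stratified splitting.

MANIFEST_REQUIRED <- c("exam_id", "cohort", "t2w", "dwi_high_b", "adc",
                       "lesion_mask_t2w", "lesion_mask_dwi", "prostate_mask",
                       "cspca_label", "pirads", "split")

#' Load a manifest from CSV or JSON
#'
#' A manifest lists one exam per row: identifiers, cohort tag, per-modality
#' and per-mask file paths (relative to the manifest location), the csPCa
#' label, PI-RADS score and train/test split. Unless `lazy = TRUE`, every
#' referenced file must exist.
#'
#' @param path `.csv` or `.json` manifest file.
#' @param lazy skip the file-existence check.
#' @return Manifest data frame.
#' @export
load_manifest <- function(path, lazy = FALSE) {
  if (!file.exists(path))
    abort(sprintf("manifest file not found: '%s'", path), "misalignr_io")
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(MANIFEST_REQUIRED, names(m))
  if (length(missing))
    abort(paste0("manifest missing required columns: ", paste(missing, collapse = ", ")),
          "misalignr_manifest_schema")
  for (col in intersect(c("cspca_label", "pirads"), names(m)))
    m[[col]] <- as.integer(m[[col]])
  dup <- m$exam_id[duplicated(m$exam_id)]
  if (length(dup))
    abort(paste0("duplicate exam_id in manifest: ", paste(unique(dup), collapse = ", ")),
          "misalignr_manifest_schema")
  if (!lazy) {
    base <- dirname(path)
    path_cols <- intersect(c("t2w", "dwi_high_b", "dwi_low_b", "adc",
                             "lesion_mask_t2w", "lesion_mask_dwi",
                             "prostate_mask", "prostate_mask_dwi"), names(m))
    for (col in path_cols) {
      p <- file.path(base, m[[col]])
      bad <- p[nzchar(m[[col]]) & !file.exists(p)]
      if (length(bad))
        abort(sprintf("manifest references missing file: '%s'", bad[1]), "misalignr_io")
    }
  }
  m
}

#' Save a manifest to CSV or JSON
#'
#' The format follows the file extension; a round-trip
#' `load(save(load(x)))` is the identity field-by-field.
#'
#' @param manifest manifest data frame.
#' @param path output `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(manifest, path, dataframe = "columns", auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Cohort composition summary
#'
#' Counts of exams with and without clinically significant cancer per
#' cohort and overall, with prevalence percentages rounded half-up to two
#' decimals (`100 * with / (with + without)`).
#'
#' @param manifest manifest data frame (needs `cohort` and `cspca_label`).
#' @return Data frame of class `cohort_summary`: one row per cohort plus a
#'   `total` row, columns `cohort`, `n_without`, `n_with`, `n_exams`,
#'   `prevalence_pct`.
#' @export
cohort_summary <- function(manifest) {
  if (is.null(manifest) || nrow(manifest) == 0)
    abort("empty manifest", "misalignr_empty_input")
  one <- function(tag, lab) {
    w <- sum(lab == 1); wo <- sum(lab == 0)
    data.frame(cohort = tag, n_without = wo, n_with = w, n_exams = w + wo,
               prevalence_pct = round_half_up(100 * w / (w + wo), 2),
               stringsAsFactors = FALSE)
  }
  parts <- lapply(split(manifest$cspca_label, manifest$cohort),
                  function(lab) lab)
  out <- do.call(rbind, c(
    lapply(names(parts), function(tag) one(tag, parts[[tag]])),
    list(one("total", manifest$cspca_label))))
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Deterministic stratified train/test split
#'
#' Assigns each exam to train or test, stratifying jointly by cohort and
#' csPCa label: within each stratum the exams are shuffled with the given
#' seed and the first `round(test_fraction * n)` go to the test set.
#'
#' @param manifest manifest data frame.
#' @param test_fraction fraction of each stratum held out.
#' @param seed integer seed.
#' @return The manifest with its `split` column reassigned.
#' @export
assign_splits <- function(manifest, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  with_preserved_rng(seed, {
    manifest$split <- "train"
    strata <- interaction(manifest$cohort, manifest$cspca_label, drop = TRUE)
    for (s in levels(strata)) {
      idx <- which(strata == s)
      k <- round(test_fraction * length(idx))
      if (k > 0) manifest$split[sample(idx, k)] <- "test"
    }
    manifest
  })
}

# ---- NIfTI volumes -----------------------------------------------------------

#' Read a NIfTI volume, canonicalized to RAS
#'
#' Loads a `.nii`/`.nii.gz` volume, reorders the data so the axes run
#' left-to-Right, posterior-to-Anterior, inferior-to-Superior (making the
#' dorsal-ventral axis unambiguous for the squeeze component), and returns
#' the array with its voxel spacing.
#'
#' @param path NIfTI file path.
#' @return List with `data` (3D array), `spacing` (mm), `orientation`
#'   (original orientation code) and `xform` (RAS voxel-to-world matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    abort(sprintf("volume file not found: '%s'", path), "misalignr_io")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf("not a readable NIfTI file: '%s' (%s)",
                                                    path, conditionMessage(e)),
                                            "misalignr_io"))
  orig <- RNifti::orientation(img)
  if (!identical(orig, "RAS")) RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)[1:3]
  data <- as.array(img)
  data <- array(as.vector(data), dim = dim(data))  # drop NIfTI attributes
  list(data = data, spacing = as.numeric(sp), orientation = orig,
       xform = structure(RNifti::xform(img), code = NULL, imagedim = NULL))
}

#' Write a volume as NIfTI
#'
#' Writes the array with its spacing in the header (RAS axis order, qform
#' code 1). A write/read round-trip reproduces data and spacing bit-exactly
#' for the `"double"` datatype.
#'
#' @param volume 3D array.
#' @param spacing voxel spacing, mm.
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype NIfTI storage type: `"double"`, `"float"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, spacing, path, datatype = "double") {
  stopifnot(length(dim(volume)) == 3, length(spacing) == 3)
  ref <- list(pixdim = c(1, spacing, 0, 0, 0, 0), qform_code = 1)
  img <- RNifti::asNifti(volume, reference = ref, datatype = datatype)
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort(sprintf("failed to write volume: '%s'", path), "misalignr_io")
  invisible(path)
}
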