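# Synthetic multi-modal prostate phantom: an idealized ellipsoid anatomy
# (body, gland = TZ core + PZ shell, spherical lesions) rendered with the
# contrast polarity of bi-parametric prostate MRI — lesions bright on
# high-b DWI, dark on ADC, dark on T2w within the peripheral zone — plus a
# low-b DWI synthesized as a smoothed, contrast-reduced echo of the T2w
# structure (low-b diffusion images are the DWI channel most similar to
# T2w, which intensity-based registration exploits). A known misalignment
# can be injected into the DWI domain and is recorded as ground truth.

#' Phantom generation settings
#'
#' @param grid_shape voxels per axis (x, y, z), strictly positive.
#' @param spacing mm per axis; default matches the common reconstruction
#'   resolution of 0.3125 mm in-plane with 3 mm slices.
#' @param n_lesions number of lesions to place inside the gland (>= 0).
#' @param lesion_radius_range mm interval for lesion radii; the lower bound
#'   must exceed the largest voxel spacing so lesions span at least two
#'   voxels in-plane.
#' @param noise_sigma additive Gaussian noise level, as a fraction of the
#'   nominal tissue contrast (the gland-lesion intensity difference).
#' @param true_misalignment optional [misalignment_params()]: a ground-truth
#'   inter-modality displacement injected into the DWI domain.
#' @param lesion_contrast multiplier in (0, 1] on the lesion contrast;
#'   lesions with contrast >= 0.5 are flagged clinically significant in the
#'   catalog.
#' @param seed integer RNG seed; the same config reproduces the exam
#'   bit-for-bit.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(192, 192, 20),
                           spacing = c(0.3125, 0.3125, 3.0),
                           n_lesions = 2,
                           lesion_radius_range = c(4, 8),
                           noise_sigma = 0.1,
                           true_misalignment = NULL,
                           lesion_contrast = 1,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, length(spacing) == 3,
            length(lesion_radius_range) == 2)
  if (any(grid_shape < 1) || any(grid_shape != floor(grid_shape)))
    abort("grid_shape must be positive integers", "misalignr_invalid_config")
  if (any(spacing <= 0))
    abort("spacing must be strictly positive", "misalignr_invalid_config")
  if (!is_count(n_lesions) || n_lesions < 0)
    abort("n_lesions must be a nonnegative integer", "misalignr_invalid_config")
  if (lesion_radius_range[1] <= max(spacing))
    abort("lesion_radius_range lower bound must exceed the largest voxel spacing",
          "misalignr_invalid_config")
  if (lesion_radius_range[2] < lesion_radius_range[1])
    abort("lesion_radius_range must be an increasing interval", "misalignr_invalid_config")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0", "misalignr_invalid_config")
  if (!is.null(true_misalignment)) stopifnot(inherits(true_misalignment, "misalignment_params"))
  stopifnot(lesion_contrast > 0, lesion_contrast <= 1)
  structure(list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 noise_sigma = as.numeric(noise_sigma),
                 true_misalignment = true_misalignment,
                 lesion_contrast = as.numeric(lesion_contrast),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# nominal intensity of each tissue class per modality, on a unit-contrast
# scale; the gland-lesion difference (~0.5) is the reference "tissue
# contrast" that noise_sigma is a fraction of
phantom_palette <- function() {
  list(
    t2w = c(bg = 0.05, body = 0.40, tz = 0.55, pz = 0.85),
    dwi_high_b = c(bg = 0.02, body = 0.15, tz = 0.30, pz = 0.30),
    adc = c(bg = 0.05, body = 0.55, tz = 0.70, pz = 0.85),
    lesion_delta = c(t2w = -0.40, dwi_high_b = +0.55, adc = -0.50),
    tissue_contrast = 0.5
  )
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic multi-modal prostate exam
#'
#' Builds the ellipsoidal anatomy, places `n_lesions` spherical lesions
#' inside the gland (peripheral or transition zone), renders T2w, high-b
#' DWI, ADC and low-b DWI with the modality-typical lesion contrast
#' polarity, adds Gaussian noise, and emits the prostate and lesion masks
#' in both the T2w domain and the DWI domain. When the config carries a
#' `true_misalignment`, all DWI-domain images and masks are displaced by it
#' and the built transform is recorded in the `truth_transform` field, so
#' the two mask domains are related exactly by that transform (up to
#' nearest-neighbor resampling).
#'
#' @param config a [phantom_config()].
#' @return A `phantom_exam` (a [multimodal_exam()] with `truth_transform`
#'   and a `lesion_catalog` data frame: center mm, radius mm, zone PZ/TZ,
#'   significance flag).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_preserved_rng(config$seed, {
    d <- config$grid_shape; sp <- config$spacing
    fov <- d * sp
    ctr <- grid_center_mm(d, sp)
    g <- grid_coords_mm(d, sp)
    pal <- phantom_palette()

    ell <- function(c_mm, semi) {
      ((g$x - c_mm[1]) / semi[1])^2 + ((g$y - c_mm[2]) / semi[2])^2 +
        ((g$z - c_mm[3]) / semi[3])^2 <= 1
    }
    body_semi <- 0.46 * fov
    # the gland has an absolute anatomical size (~34 x 28 x 24 mm), not a
    # fraction of the imaged volume; the caller chooses a field of view
    # with enough margin for any misalignment it intends to inject
    pros_semi <- c(17, 14, 12)
    tz_semi <- 0.60 * pros_semi
    tz_ctr <- ctr + c(0, 0.25 * pros_semi[2], 0)  # transition zone sits anterior

    body <- ell(ctr, body_semi)
    gland <- ell(ctr, pros_semi)
    tz <- ell(tz_ctr, tz_semi) & gland
    pz <- gland & !tz

    # --- lesion placement: spheres inside the gland, zone-tagged, non-overlapping
    n <- config$n_lesions
    catalog <- data.frame(lesion = integer(0), x_mm = numeric(0), y_mm = numeric(0),
                          z_mm = numeric(0), radius_mm = numeric(0),
                          zone = character(0), significant = logical(0))
    lesion_lab <- array(0L, dim = d)
    if (n > 0) {
      rr <- config$lesion_radius_range
      for (li in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          r <- stats::runif(1, rr[1], min(rr[2], 0.85 * min(pros_semi)))
          zone <- if (stats::runif(1) < 0.7) "PZ" else "TZ"
          shrink <- pmax(pros_semi - r, 0.1)
          u <- stats::runif(3, -1, 1)
          c_mm <- ctr + u * shrink
          inside <- sum(((c_mm - ctr) / shrink)^2) <= 1
          if (!inside) next
          in_tz <- sum(((c_mm - tz_ctr) / tz_semi)^2) <= 1
          if ((zone == "TZ") != in_tz) next
          if (nrow(catalog)) {
            dist <- sqrt(colSums((t(as.matrix(catalog[, c("x_mm", "y_mm", "z_mm")])) - c_mm)^2))
            if (any(dist < r + catalog$radius_mm + 1)) next
          }
          catalog <- rbind(catalog, data.frame(
            lesion = li, x_mm = c_mm[1], y_mm = c_mm[2], z_mm = c_mm[3],
            radius_mm = r, zone = zone,
            significant = config$lesion_contrast >= 0.5))
          vox <- (g$x - c_mm[1])^2 + (g$y - c_mm[2])^2 + (g$z - c_mm[3])^2 <= r^2
          lesion_lab[vox] <- li
          placed <- TRUE
          break
        }
        if (!placed)
          abort(sprintf("placement of lesion %d failed after 200 retries (gland too small)", li),
                "misalignr_lesion_placement")
      }
    }

    render <- function(modality) {
      v <- rep(pal[[modality]]["bg"], prod(d))
      v[body] <- pal[[modality]]["body"]
      v[tz]   <- pal[[modality]]["tz"]
      v[pz]   <- pal[[modality]]["pz"]
      v[lesion_lab > 0] <- v[lesion_lab > 0] +
        pal$lesion_delta[modality] * config$lesion_contrast
      gaussian_smooth(array(v, dim = d), sp, c(1.0, 1.0, 1.5))
    }
    t2w_i <- render("t2w")
    # smooth structural texture inside the body: real T2w carries rich,
    # spatially asymmetric detail, which is what makes the low-b DWI an
    # informative registration target; a piecewise-constant phantom would
    # be mirror-symmetric and ambiguous under in-plane rotation
    tex <- gaussian_smooth(array(stats::rnorm(prod(d)), dim = d), sp, c(5, 5, 5))
    tex <- tex / max(stats::sd(tex), 1e-9)
    t2w_i <- t2w_i + 0.08 * tex * array(body, dim = d)
    hb_i  <- render("dwi_high_b")
    adc_i <- render("adc")
    # low-b DWI: smoothed, contrast-reduced blend of the T2w structure
    lowb_i <- gaussian_smooth(0.25 + 0.6 * t2w_i, sp, c(2.0, 2.0, 3.0))

    gland_m <- array(as.integer(gland), dim = d)
    truth <- NULL
    if (!is.null(config$true_misalignment)) {
      truth <- build_transform(config$true_misalignment, ctr)
      hb_d   <- resample_with_transform(hb_i, sp, truth, "linear")
      adc_d  <- resample_with_transform(adc_i, sp, truth, "linear")
      lowb_d <- resample_with_transform(lowb_i, sp, truth, "linear")
      les_d  <- resample_with_transform(lesion_lab, sp, truth, "nearest", fill_value = 0)
      gland_d <- resample_with_transform(gland_m, sp, truth, "nearest", fill_value = 0)
    } else {
      hb_d <- hb_i; adc_d <- adc_i; lowb_d <- lowb_i
      les_d <- lesion_lab; gland_d <- gland_m
    }

    ns <- config$noise_sigma * pal$tissue_contrast
    if (ns > 0) {
      t2w_i  <- t2w_i  + array(stats::rnorm(prod(d), 0, ns), dim = d)
      hb_d   <- hb_d   + array(stats::rnorm(prod(d), 0, ns), dim = d)
      adc_d  <- adc_d  + array(stats::rnorm(prod(d), 0, ns), dim = d)
      lowb_d <- lowb_d + array(stats::rnorm(prod(d), 0, ns), dim = d)
    }

    exam <- multimodal_exam(
      t2w = t2w_i, dwi_high_b = hb_d, adc = adc_d, dwi_low_b = lowb_d,
      spacing = sp,
      lesion_mask_t2w = array(as.integer(lesion_lab), dim = d),
      lesion_mask_dwi = array(as.integer(les_d), dim = d),
      prostate_mask = gland_m, prostate_mask_dwi = gland_d,
      cspca_label = as.integer(n > 0 && config$lesion_contrast >= 0.5))
    exam$truth_transform <- truth
    exam$lesion_catalog <- catalog
    class(exam) <- c("phantom_exam", class(exam))
    exam
  })
}

# monotone map from lesion burden (conspicuity = sum over lesions of
# equivalent-diameter x contrast) to a 1..5 risk score, with reader noise
synthesize_pirads <- function(catalog, contrast) {
  consp <- if (nrow(catalog)) sum((4 / 3 * pi * catalog$radius_mm^3)^(1 / 3) * contrast) else 0
  raw <- 1 + 2.3 * log1p(consp / 4) + stats::rnorm(1, 0, 0.4)
  as.integer(pmin(5, pmax(1, round(raw))))
}

#' Write a phantom dataset to disk
#'
#' Generates `n_exams` phantoms with deterministically derived per-exam
#' seeds, writes every volume and mask as NIfTI, assigns each exam a csPCa
#' label (prevalence-controlled: positive exams carry full-contrast,
#' significant lesions; negatives carry at most one low-contrast indolent
#' lesion) and a synthetic PI-RADS score that grows monotonically with
#' lesion volume x contrast, and writes a manifest CSV with relative paths.
#' Two runs with identical arguments produce byte-identical manifests.
#'
#' @param config a [phantom_config()]; its `seed` drives all per-exam seeds.
#' @param n_exams number of exams to generate (>= 1).
#' @param out_dir output directory (created if needed).
#' @param misalign `NULL` for aligned exams, a [misalignment_params()] for a
#'   fixed injected misalignment, or a [misalignment_config()] to sample an
#'   independent ground-truth misalignment per exam (gating ignored: every
#'   exam is displaced). Defaults to `config$true_misalignment`.
#' @param prevalence fraction of csPCa-positive exams in expectation;
#'   default 0.344, the prevalence of the cohorts this phantom emulates.
#' @param cohort cohort tag written to the manifest.
#' @return The manifest data frame, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
write_phantom_dataset <- function(config, n_exams, out_dir,
                                  misalign = config$true_misalignment,
                                  prevalence = 0.344, cohort = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  if (!is_count(n_exams) || n_exams < 1)
    abort("n_exams must be a positive integer", "misalignr_invalid_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(sprintf("cannot create output directory '%s'", out_dir), "misalignr_io")
  rows <- vector("list", n_exams)
  for (i in seq_len(n_exams)) {
    seed_i <- as.integer((as.double(config$seed) * 7919 + i * 104729) %% 2147483647)
    row <- with_preserved_rng(seed_i, {
      cspca <- stats::runif(1) < prevalence
      n_les <- if (cspca) max(1L, config$n_lesions) else stats::rbinom(1, 1, 0.5)
      contrast <- if (cspca) 1 else 0.35
      truth <- if (inherits(misalign, "misalignment_config")) sample_misalignment(misalign)
               else misalign
      cfg_i <- config
      cfg_i$n_lesions <- as.integer(n_les)
      cfg_i$lesion_contrast <- contrast
      cfg_i$true_misalignment <- truth
      cfg_i$seed <- as.integer((seed_i + 1) %% 2147483647)
      ex <- generate_phantom(cfg_i)
      id <- sprintf("phantom_%04d", i)
      files <- c(t2w = "t2w", dwi_high_b = "dwi_high_b", dwi_low_b = "dwi_low_b",
                 adc = "adc", lesion_mask_t2w = "lesion_t2w",
                 lesion_mask_dwi = "lesion_dwi", prostate_mask = "prostate",
                 prostate_mask_dwi = "prostate_dwi")
      paths <- sprintf("%s_%s.nii.gz", id, files)
      names(paths) <- names(files)
      for (nm in names(paths)) {
        dt <- if (grepl("mask", nm)) "int16" else "float"
        write_volume(ex[[nm]], ex$spacing, file.path(out_dir, paths[[nm]]), datatype = dt)
      }
      pirads <- synthesize_pirads(ex$lesion_catalog, contrast)
      data.frame(exam_id = id, cohort = cohort,
                 t2w = paths[["t2w"]], dwi_high_b = paths[["dwi_high_b"]],
                 dwi_low_b = paths[["dwi_low_b"]], adc = paths[["adc"]],
                 lesion_mask_t2w = paths[["lesion_mask_t2w"]],
                 lesion_mask_dwi = paths[["lesion_mask_dwi"]],
                 prostate_mask = paths[["prostate_mask"]],
                 prostate_mask_dwi = paths[["prostate_mask_dwi"]],
                 cspca_label = as.integer(cspca), pirads = pirads,
                 split = "train", stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Load one manifest row back into a multimodal exam
#'
#' @param manifest a manifest data frame from [load_manifest()] or
#'   [write_phantom_dataset()].
#' @param exam_id the exam to load.
#' @param dir directory the manifest's relative paths are resolved against.
#' @return A [multimodal_exam()].
#' @export
load_exam <- function(manifest, exam_id, dir) {
  row <- manifest[manifest$exam_id == exam_id, , drop = FALSE]
  if (nrow(row) != 1L)
    abort(sprintf("exam_id '%s' not found in manifest", exam_id), "misalignr_io")
  rd <- function(col) read_volume(file.path(dir, row[[col]]))
  t2 <- rd("t2w")
  as_int <- function(v) array(as.integer(round(v$data)), dim = dim(v$data))
  multimodal_exam(
    t2w = t2$data, dwi_high_b = rd("dwi_high_b")$data, adc = rd("adc")$data,
    dwi_low_b = if ("dwi_low_b" %in% names(row) && nzchar(row$dwi_low_b))
      rd("dwi_low_b")$data else NULL,
    spacing = t2$spacing,
    lesion_mask_t2w = as_int(rd("lesion_mask_t2w")),
    lesion_mask_dwi = as_int(rd("lesion_mask_dwi")),
    prostate_mask = as_int(rd("prostate_mask")),
    prostate_mask_dwi = if ("prostate_mask_dwi" %in% names(row) && nzchar(row$prostate_mask_dwi))
      as_int(rd("prostate_mask_dwi")) else NULL,
    cspca_label = row$cspca_label, pirads = row$pirads)
}
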