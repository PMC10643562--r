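# Registration between the T2w domain (fixed) and the DWI domain (moving).
# Two methods are provided, mirroring the two dataset variants an alignment
# study needs besides the raw unregistered data:
#
#  * register_bspline(): intensity-based, maximizing mutual information
#    between the fixed T2w and the (warped) lowest-b DWI — the diffusion
#    channel most similar to T2w — with a multi-resolution affine-family
#    initialization followed by a cubic B-spline free-form refinement. The
#    fitted parameters are then propagated to the high-b DWI and ADC.
#  * register_gt_matching(): segmentation-driven ("ground-truth matching"),
#    maximizing the overlap of Gaussian-smoothed prostate + lesion masks,
#    initialized by centroid alignment.
#
# Only DWI-domain data are ever resampled; the fixed T2w grid is never
# modified.

#' Registration options
#'
#' @param bins histogram bins for mutual information.
#' @param levels multi-resolution pyramid levels.
#' @param affine_maxit Nelder-Mead iteration caps, coarsest level first
#'   (recycled across levels).
#' @param control_spacing_mm B-spline control-point spacing, mm.
#' @param ffd_maxit L-BFGS-B iteration cap for the free-form refinement
#'   (0 disables the refinement and returns the affine-family fit).
#' @param ffd_stride voxel stride used when evaluating the refinement
#'   objective (speed/accuracy trade-off).
#' @param ffd_penalty ridge penalty weight on control displacements (mm^-2).
#' @param gt_sigma_mm Gaussian smoothing of the masks for GT-matching.
#' @param gt_lesion_weight weight of lesion masks relative to the gland in
#'   the GT-matching overlap objective.
#' @param gt_refine_maxit full-resolution polish iterations for GT-matching.
#' @return Options list.
#' @export
reg_options <- function(bins = 32, levels = 3, affine_maxit = c(250, 120, 40),
                        control_spacing_mm = 40, ffd_maxit = 8, ffd_stride = 2,
                        ffd_penalty = 1e-3, gt_sigma_mm = 1.5,
                        gt_lesion_weight = 2, gt_refine_maxit = 400) {
  list(bins = bins, levels = levels, affine_maxit = affine_maxit,
       control_spacing_mm = control_spacing_mm, ffd_maxit = ffd_maxit,
       ffd_stride = ffd_stride, ffd_penalty = ffd_penalty,
       gt_sigma_mm = gt_sigma_mm, gt_lesion_weight = gt_lesion_weight,
       gt_refine_maxit = gt_refine_maxit)
}

#' Mutual information of two volumes
#'
#' MI of the joint intensity histogram (equal-width bins over each volume's
#' range), in nats. A constant volume carries no information: MI is 0, with
#' a warning.
#'
#' @param a,b numeric arrays of identical shape.
#' @param bins number of histogram bins per axis (>= 2).
#' @return Nonnegative MI in nats.
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    abort("mutual_information: shapes differ", "misalignr_shape_mismatch")
  stopifnot(bins >= 2)
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant volume: mutual information is 0")
    return(0)
  }
  ia <- pmin(pmax(floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1, 1), bins)
  joint <- tabulate(ia + (ib - 1) * bins, nbins = bins * bins) / length(a)
  mi_from_joint(matrix(joint, bins, bins))
}

mi_from_joint <- function(P) {
  px <- rowSums(P); py <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / (px[row(P)[nz]] * py[col(P)[nz]])))
}

# soft (tent-kernel) binning of the moving intensities against hard bins of
# the fixed, making MI differentiable in the moving values
mi_soft <- function(ia, b, bins, rb) {
  if (rb[1] == rb[2]) return(0)
  t <- (b - rb[1]) / (rb[2] - rb[1]) * (bins - 1) + 1
  t <- pmin(pmax(t, 1), bins)
  j0 <- pmin(floor(t), bins - 1)
  w1 <- t - j0
  idx0 <- ia + (j0 - 1) * bins
  idx1 <- ia + j0 * bins
  P <- numeric(bins * bins)
  acc <- rowsum(c(1 - w1, w1), c(idx0, idx1), reorder = FALSE)
  P[as.integer(rownames(acc))] <- acc
  mi_from_joint(matrix(P / length(b), bins, bins))
}

#' Construct a registration result
#' @keywords internal
registration_result <- function(transform, similarity, method, fixed_domain) {
  structure(list(transform = transform, similarity_value = similarity,
                 method = method, fixed_domain = fixed_domain),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> method = %s, similarity = %.4f\n",
              x$method, x$similarity_value))
  invisible(x)
}

# ---- coordinate machinery ----------------------------------------------------

# cubic B-spline free-form deformation: control lattice covering the fixed
# field of view with one extra ring of control points on each side
make_ffd <- function(extent_mm, control_spacing_mm) {
  delta <- rep(control_spacing_mm, length.out = 3)
  dims <- ceiling(extent_mm / delta) + 3L
  list(spacing_mm = delta, dims = as.integer(dims),
       coef = matrix(0, prod(dims), 3))
}

bspline_basis_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# dense basis matrix (n_points x n_control) for evaluation points p (mm)
ffd_basis <- function(ffd, px, py, pz) {
  dm <- ffd$dims; dl <- ffd$spacing_mm
  n <- length(px)
  ax <- function(p, k) {
    u <- p / dl[k] + 2
    i0 <- pmin(pmax(floor(u), 2L), dm[k] - 2L)
    list(i0 = i0, w = bspline_basis_weights(pmin(pmax(u - i0, 0), 1)))
  }
  X <- ax(px, 1); Y <- ax(py, 2); Z <- ax(pz, 3)
  B <- matrix(0, n, prod(dm))
  rows <- seq_len(n)
  for (di in 0:3) for (dj in 0:3) for (dk in 0:3) {
    cidx <- (X$i0 - 1 + di) + (Y$i0 - 2 + dj) * dm[1] + (Z$i0 - 2 + dk) * dm[1] * dm[2]
    w <- X$w[, di + 1] * Y$w[, dj + 1] * Z$w[, dk + 1]
    ij <- cbind(rows, cidx)
    B[ij] <- B[ij] + w
  }
  B
}

# physical sampling coordinates in the moving domain for fixed-domain
# points g = list(x, y, z); a plain spatial_transform samples at T^-1 p,
# a B-spline result adds the free-form displacement on top
sample_coords <- function(transform, g) {
  if (inherits(transform, "spatial_transform")) {
    Minv <- solve(transform$matrix)
    list(x = Minv[1, 1] * g$x + Minv[1, 2] * g$y + Minv[1, 3] * g$z + Minv[1, 4],
         y = Minv[2, 1] * g$x + Minv[2, 2] * g$y + Minv[2, 3] * g$z + Minv[2, 4],
         z = Minv[3, 1] * g$x + Minv[3, 2] * g$y + Minv[3, 3] * g$z + Minv[3, 4])
  } else if (identical(transform$kind, "bspline")) {
    q <- sample_coords(transform$affine, g)
    B <- ffd_basis(transform$ffd, g$x, g$y, g$z)
    D <- B %*% transform$ffd$coef
    list(x = q$x + D[, 1], y = q$y + D[, 2], z = q$z + D[, 3])
  } else {
    abort("unknown transform kind", "misalignr_invalid_transform")
  }
}

# warp a moving-domain volume onto a fixed grid described by (dim, spacing)
warp_onto_grid <- function(vol, spacing_moving, transform, fixed_dim, fixed_spacing,
                           interpolation = "linear", fill = min(vol)) {
  if (inherits(transform, "spatial_transform") && is_identity_transform(transform) &&
      identical(fixed_dim, dim(vol)) && all(fixed_spacing == spacing_moving))
    return(vol)
  g <- grid_coords_mm(fixed_dim, fixed_spacing)
  out <- numeric(prod(fixed_dim))
  # chunk by slabs to bound the dense B-spline basis allocation
  chunk <- max(1L, floor(2e5 / 1))
  idx <- seq_along(g$x)
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    q <- sample_coords(transform, list(x = g$x[sel], y = g$y[sel], z = g$z[sel]))
    ci <- q$x / spacing_moving[1] + 1
    cj <- q$y / spacing_moving[2] + 1
    ck <- q$z / spacing_moving[3] + 1
    out[sel] <- if (interpolation == "linear") interp_trilinear(vol, ci, cj, ck, fill)
                else interp_nearest(vol, ci, cj, ck, fill)
  }
  array(out, dim = fixed_dim)
}

# ---- intensity-based B-spline registration -----------------------------------

# Correction-family affine: Translate(t) o ScaleY(s; c) o RotZ(theta; c).
# The component order is deliberately the reverse of the forward
# misalignment composition (translate o rotate o squeeze): the inverse of
# a forward transform lies exactly in this reversed family, so fitting in
# it lets a registration recover an injected misalignment without a
# structural parameterization error. The in-plane rotation angle of such a
# matrix is recoverable exactly from its (unscaled) first row, see
# transform_rotation_deg().
affine_from_par <- function(p, center) {
  th <- p[4] * pi / 180
  Rz <- diag(4)
  Rz[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sy <- diag(4); Sy[2, 2] <- p[5]
  Tc <- diag(4);  Tc[1:3, 4] <- center
  Tci <- diag(4); Tci[1:3, 4] <- -center
  Tt <- diag(4);  Tt[1:3, 4] <- p[1:3]
  spatial_transform(Tt %*% Tc %*% Sy %*% Rz %*% Tci, center)
}

#' In-plane rotation angle of a fitted correction transform
#'
#' Extracts the rotation (about z, in degrees) from a transform in the
#' correction family fitted by the registration methods, where the first
#' matrix row is unaffected by the dorsal-ventral scale so the angle is
#' exact.
#'
#' @param tf a [spatial_transform()] returned in a `registration_result`.
#' @return Rotation angle in degrees.
#' @export
transform_rotation_deg <- function(tf) {
  atan2(-tf$matrix[1, 2], tf$matrix[1, 1]) * 180 / pi
}

#' Register a moving volume to a fixed volume by mutual information
#'
#' Multi-resolution registration: at each pyramid level an affine family
#' (translation, in-plane rotation, dorsal-ventral scale — the deformation
#' family of inter-sequence misalignment) is optimized by Nelder-Mead on the
#' MI between the fixed volume and the warped moving volume; the fit then
#' initializes a cubic B-spline free-form refinement (control spacing
#' `options$control_spacing_mm`) optimized by L-BFGS-B on soft-binned MI
#' with a ridge penalty on the control displacements. The fixed volume is
#' typically the T2w and the moving volume the lowest-b DWI.
#'
#' @param fixed,moving numeric 3D arrays sharing a physical-space
#'   description.
#' @param spacing voxel spacing (mm) of both volumes.
#' @param options see [reg_options()].
#' @return A `registration_result` with `method = "bspline_mi"`; its
#'   `transform` warps any DWI-domain volume onto the fixed grid via
#'   [propagate()].
#' @export
register_bspline <- function(fixed, moving, spacing, options = reg_options()) {
  if (!identical(dim(fixed), dim(moving)))
    abort("register_bspline: fixed and moving must share a grid", "misalignr_shape_mismatch")
  if (!all(is.finite(fixed)) || !all(is.finite(moving)))
    abort("register_bspline: non-finite voxel values", "misalignr_invalid_input")
  d <- dim(fixed); extent <- (d - 1) * spacing
  center <- grid_center_mm(d, spacing)
  bins <- options$bins
  par <- c(0, 0, 0, 0, 1)
  trace <- list()
  for (lev in seq_len(options$levels)) {
    f <- 2^(options$levels - lev)
    fz <- max(1L, min(f, floor(d[3] / 4)))
    dsF <- downsample_volume(fixed, spacing, c(f, f, fz))
    dsM <- downsample_volume(moving, spacing, c(f, f, fz))
    maxit <- options$affine_maxit[min(lev, length(options$affine_maxit))]
    if (maxit > 0) {
      obj <- function(p) {
        tf <- affine_from_par(p, center)
        w <- warp_onto_grid(dsM$vol, dsM$spacing, tf, dim(dsF$vol), dsF$spacing)
        mi <- suppressWarnings(mutual_information(dsF$vol, w, bins))
        if (!is.finite(mi)) return(1e6)
        -mi
      }
      # at the coarsest level, multi-start over the rotation component:
      # near-symmetric anatomy gives the MI surface twin optima at +/-theta
      starts <- if (lev == 1) lapply(c(0, -10, 10), function(th) {
        s <- par; s[4] <- s[4] + th; s
      }) else list(par)
      fits <- lapply(starts, function(s)
        stats::optim(s, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit,
                                    parscale = c(2, 2, 2, 2, 0.05))))
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      par <- fit$par
      trace[[lev]] <- c(level = lev, value = fit$value, fit$counts[1])
      if (!is.finite(fit$value))
        abort(paste0("register_bspline: optimizer diverged (non-finite metric); trace: ",
                     paste(vapply(trace, function(t) paste(signif(t, 4), collapse = "/"),
                                  character(1)), collapse = "; ")),
              "misalignr_registration_divergence")
    }
  }
  affine <- affine_from_par(par, center)
  transform <- affine
  if (options$ffd_maxit > 0) {
    ffd <- make_ffd(extent, options$control_spacing_mm)
    f <- 2^(max(options$levels - 2, 0))
    fz <- max(1L, min(f, floor(d[3] / 4)))
    dsF <- downsample_volume(fixed, spacing, c(f, f, fz))
    dsM <- downsample_volume(moving, spacing, c(f, f, fz))
    dd <- dim(dsF$vol)
    sx <- seq(1L, dd[1], by = options$ffd_stride)
    sy <- seq(1L, dd[2], by = options$ffd_stride)
    sub <- dsF$vol[sx, sy, , drop = FALSE]
    gx <- rep((sx - 1) * dsF$spacing[1], times = length(sy) * dd[3])
    gy <- rep(rep((sy - 1) * dsF$spacing[2], each = length(sx)), times = dd[3])
    gz <- rep((seq_len(dd[3]) - 1) * dsF$spacing[3], each = length(sx) * length(sy))
    B <- ffd_basis(ffd, gx, gy, gz)
    Minv <- solve(affine$matrix)
    qx0 <- Minv[1, 1] * gx + Minv[1, 2] * gy + Minv[1, 3] * gz + Minv[1, 4]
    qy0 <- Minv[2, 1] * gx + Minv[2, 2] * gy + Minv[2, 3] * gz + Minv[2, 4]
    qz0 <- Minv[3, 1] * gx + Minv[3, 2] * gy + Minv[3, 3] * gz + Minv[3, 4]
    rf <- range(sub)
    iaf <- pmin(pmax(floor((sub - rf[1]) / max(rf[2] - rf[1], 1e-12) * bins) + 1, 1), bins)
    iaf <- as.vector(iaf)
    rm_ <- range(dsM$vol)
    fillm <- min(dsM$vol)
    nctrl <- nrow(ffd$coef)
    objc <- function(cv) {
      C <- matrix(cv, nctrl, 3)
      D <- B %*% C
      ci <- (qx0 + D[, 1]) / dsM$spacing[1] + 1
      cj <- (qy0 + D[, 2]) / dsM$spacing[2] + 1
      ck <- (qz0 + D[, 3]) / dsM$spacing[3] + 1
      w <- interp_trilinear(dsM$vol, ci, cj, ck, fillm)
      -(mi_soft(iaf, w, bins, rm_) - options$ffd_penalty * mean(cv^2))
    }
    fit <- stats::optim(rep(0, nctrl * 3), objc, method = "L-BFGS-B",
                        lower = -options$control_spacing_mm / 2,
                        upper = options$control_spacing_mm / 2,
                        control = list(maxit = options$ffd_maxit,
                                       ndeps = rep(1e-2, nctrl * 3)))
    if (!is.finite(fit$value))
      abort("register_bspline: free-form refinement diverged (non-finite metric)",
            "misalignr_registration_divergence")
    ffd$coef <- matrix(fit$par, nctrl, 3)
    transform <- list(kind = "bspline", affine = affine, ffd = ffd)
  }
  warped <- warp_onto_grid(moving, spacing, transform, d, spacing)
  final_mi <- suppressWarnings(mutual_information(fixed, warped, bins))
  registration_result(transform, final_mi, "bspline_mi",
                      list(dim = d, spacing = spacing))
}

#' Register an exam's DWI domain to its T2w by mutual information
#'
#' Convenience wrapper: uses the exam's lowest-b DWI as the moving image
#' (the diffusion channel most similar to T2w); when absent, falls back to
#' the ADC map with a warning.
#'
#' @param exam a [multimodal_exam()].
#' @param options see [reg_options()].
#' @return A `registration_result`.
#' @export
register_exam_bspline <- function(exam, options = reg_options()) {
  moving <- exam$dwi_low_b
  if (is.null(moving)) {
    warning("no low-b DWI present; falling back to the ADC map as moving image")
    moving <- exam$adc
  }
  register_bspline(exam$t2w, moving, exam$spacing, options)
}

# ---- segmentation-driven (ground-truth-matching) registration ---------------

#' Register by matching prostate and lesion segmentations
#'
#' Fits an affine transform (translation, in-plane rotation,
#' dorsal-ventral scale) that maximizes the soft Dice overlap of
#' Gaussian-smoothed prostate + lesion masks between the two modality
#' domains, initialized by aligning the prostate centroids. Lesion masks
#' are weighted more strongly than the gland so lesion overlap drives the
#' fine alignment. If the fitted transform does not improve the hard
#' prostate Dice, the identity is returned with a warning.
#'
#' @param fixed_masks list with `prostate` (binary) and optionally
#'   `lesions` (label volume), T2w domain.
#' @param moving_masks same structure, DWI domain.
#' @param spacing voxel spacing (mm) shared by both domains.
#' @param options see [reg_options()].
#' @return A `registration_result` with `method = "gt_matching"`.
#' @export
register_gt_matching <- function(fixed_masks, moving_masks, spacing,
                                 options = reg_options()) {
  for (mk in list(fixed_masks, moving_masks))
    if (is.null(mk$prostate) || sum(mk$prostate > 0) == 0)
      abort("register_gt_matching: empty prostate mask", "misalignr_empty_mask")
  d <- dim(fixed_masks$prostate)
  center <- grid_center_mm(d, spacing)
  softmap <- function(mk) {
    w <- (mk$prostate > 0) * 1.0
    if (!is.null(mk$lesions)) w <- w + (mk$lesions > 0) * options$gt_lesion_weight
    gaussian_smooth(array(w, dim = d), spacing, options$gt_sigma_mm)
  }
  Fs <- softmap(fixed_masks); Ms <- softmap(moving_masks)
  t0 <- mask_centroid_mm(fixed_masks$prostate, spacing) -
        mask_centroid_mm(moving_masks$prostate, spacing)
  soft_dice <- function(a, b) 2 * sum(a * b) / (sum(a * a) + sum(b * b))
  fit_at <- function(Fv, Mv, sp, pars, maxit) {
    obj <- function(p) {
      w <- warp_onto_grid(Mv, sp, affine_from_par(p, center), dim(Fv), sp,
                          fill = 0)
      -soft_dice(Fv, w)
    }
    fits <- lapply(pars, function(p)
      stats::optim(p, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, parscale = c(2, 2, 2, 2, 0.05))))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par
  }
  fci <- max(1L, round(2.5 / spacing[1]))
  fcj <- max(1L, round(2.5 / spacing[2]))
  dsF <- downsample_volume(Fs, spacing, c(fci, fcj, 1))
  dsM <- downsample_volume(Ms, spacing, c(fci, fcj, 1))
  # multi-start over the rotation: the overlap surface can hold a shallow
  # local optimum at zero rotation when translation dominates
  starts <- lapply(c(0, -10, 10), function(th) c(t0, th, 1))
  par <- fit_at(dsF$vol, dsM$vol, dsF$spacing, starts, 300)
  if (options$gt_refine_maxit > 0)
    par <- fit_at(Fs, Ms, spacing, list(par), options$gt_refine_maxit)
  tf <- affine_from_par(par, center)
  pre <- dice(fixed_masks$prostate, moving_masks$prostate)
  warped_p <- warp_onto_grid((moving_masks$prostate > 0) * 1, spacing, tf, d, spacing,
                             interpolation = "nearest", fill = 0)
  post <- dice(fixed_masks$prostate, warped_p)
  if (post < pre) {
    warning("GT-matching did not improve prostate overlap; returning identity")
    return(registration_result(spatial_transform(diag(4), center), pre, "identity",
                               list(dim = d, spacing = spacing)))
  }
  registration_result(tf, post, "gt_matching", list(dim = d, spacing = spacing))
}

#' Apply a fitted registration to sibling images and masks
#'
#' The transform estimated from one moving image (e.g. the lowest-b DWI) is
#' applied identically to every other DWI-domain image (highest-b DWI, ADC)
#' with linear interpolation, and to DWI-domain masks with nearest-neighbor
#' interpolation.
#'
#' @param result a `registration_result`.
#' @param images named list of moving-domain image volumes (may be empty).
#' @param masks named list of moving-domain mask volumes (may be empty).
#' @param spacing voxel spacing (mm) of the moving-domain volumes.
#' @return List with warped `images` and `masks`.
#' @export
propagate <- function(result, images = list(), masks = list(), spacing) {
  stopifnot(inherits(result, "registration_result"))
  fd <- result$fixed_domain
  for (v in c(images, masks))
    if (!identical(dim(v), fd$dim))
      abort("propagate: volume does not live on the moving domain grid",
            "misalignr_domain_mismatch")
  list(
    images = lapply(images, function(v)
      warp_onto_grid(v, spacing, result$transform, fd$dim, fd$spacing,
                     interpolation = "linear", fill = min(v))),
    masks = lapply(masks, function(v)
      warp_onto_grid(v, spacing, result$transform, fd$dim, fd$spacing,
                     interpolation = "nearest", fill = 0))
  )
}

#' Register a whole exam and return the aligned exam
#'
#' Runs the chosen registration method and propagates the fitted transform
#' to every DWI-domain member of the exam.
#'
#' @param exam a [multimodal_exam()].
#' @param method `"bspline"` (intensity-based, see [register_exam_bspline()])
#'   or `"gt_matching"` (segmentation-driven, see [register_gt_matching()]).
#' @param options see [reg_options()].
#' @return The exam with all DWI-domain members resampled onto the T2w
#'   grid; the `registration_result` is attached as attribute
#'   `registration`.
#' @export
register_exam <- function(exam, method = c("bspline", "gt_matching"),
                          options = reg_options()) {
  method <- match.arg(method)
  result <- if (method == "bspline") register_exam_bspline(exam, options)
  else register_gt_matching(
    list(prostate = exam$prostate_mask, lesions = exam$lesion_mask_t2w),
    list(prostate = exam$prostate_mask_dwi %||% exam$prostate_mask,
         lesions = exam$lesion_mask_dwi),
    exam$spacing, options)
  imgs <- list(dwi_high_b = exam$dwi_high_b, adc = exam$adc)
  if (!is.null(exam$dwi_low_b)) imgs$dwi_low_b <- exam$dwi_low_b
  msks <- list(lesion_mask_dwi = exam$lesion_mask_dwi)
  if (!is.null(exam$prostate_mask_dwi)) msks$prostate_mask_dwi <- exam$prostate_mask_dwi
  out <- propagate(result, imgs, msks, exam$spacing)
  for (nm in names(out$images)) exam[[nm]] <- out$images[[nm]]
  for (nm in names(out$masks))
    exam[[nm]] <- array(as.integer(round(out$masks[[nm]])), dim = dim(exam$t2w))
  attr(exam, "registration") <- result
  exam
}
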