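# Homogeneous affine transforms in physical (mm) space, and backward
# (pull) resampling of volumes on their own grid.
#
# Convention: voxel (i,j,k) (1-based) sits at physical coordinate
# (i-1, j-1, k-1) * spacing with axes x = left-right, y = dorsal-ventral,
# z = longitudinal (volumes are canonicalized to RAS on load, see
# read_volume()). A transform T moves image content forward: the resampled
# output satisfies out(p) = in(T^-1 p).

#' Construct a spatial transform
#'
#' A 4x4 homogeneous affine acting on physical (mm) coordinates, together
#' with the fixed point about which any rotation/squeeze component was
#' composed (metadata; the center is already baked into the matrix).
#'
#' @param matrix 4x4 numeric matrix; last row must be (0,0,0,1) and the
#'   matrix must be invertible.
#' @param center_mm length-3 fixed point, mm.
#' @return An object of class `spatial_transform`.
#' @export
spatial_transform <- function(matrix = diag(4), center_mm = c(0, 0, 0)) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)), length(center_mm) == 3)
  if (any(abs(matrix[4, ] - c(0, 0, 0, 1)) > 1e-12))
    abort("spatial_transform matrix last row must be (0,0,0,1)", "misalignr_invalid_transform")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    abort("spatial_transform matrix is singular", "misalignr_singular_transform")
  structure(list(matrix = matrix, center_mm = as.numeric(center_mm)),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("<spatial_transform> center_mm =", paste(signif(x$center_mm, 4), collapse = ", "), "\n")
  print(signif(x$matrix, 5))
  invisible(x)
}

#' Test whether a transform is the exact identity
#' @param tf spatial transform
#' @param tol componentwise tolerance on the matrix
#' @export
is_identity_transform <- function(tf, tol = 1e-12) {
  max(abs(tf$matrix - diag(4))) <= tol
}

#' Invert a spatial transform
#' @param tf spatial transform
#' @export
invert_transform <- function(tf) {
  spatial_transform(solve(tf$matrix), tf$center_mm)
}

#' Compose two spatial transforms (`a` applied after `b`)
#' @param a,b spatial transforms
#' @export
compose_transforms <- function(a, b) {
  spatial_transform(a$matrix %*% b$matrix, a$center_mm)
}

#' Apply a spatial transform to points
#' @param tf spatial transform
#' @param pts n x 3 matrix (or length-3 vector) of mm coordinates
#' @return n x 3 matrix of transformed coordinates
#' @export
transform_points <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  ph <- cbind(pts, 1) %*% t(tf$matrix)
  ph[, 1:3, drop = FALSE]
}

#' Build the misalignment transform from sampled parameters
#'
#' Composes, in fixed order, `Translate(t) o RotateZ(theta about center) o
#' ScaleY(s about center)`: the in-plane rotation and the dorsal-ventral
#' squeeze share a fixed point and the translation is applied last. At the
#' small default amplitudes the order-dependence of the composition is
#' sub-voxel.
#'
#' @param params a [misalignment_params()] object.
#' @param center_mm rotation/squeeze fixed point (mm), typically the grid
#'   center or the prostate centroid.
#' @return A [spatial_transform()].
#' @export
build_transform <- function(params, center_mm) {
  stopifnot(inherits(params, "misalignment_params"))
  th <- params$rotation_deg * pi / 180
  Rz <- diag(4)
  Rz[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sy <- diag(4)
  Sy[2, 2] <- params$squeeze_factor
  Tc <- diag(4);  Tc[1:3, 4] <- center_mm
  Tci <- diag(4); Tci[1:3, 4] <- -center_mm
  Tt <- diag(4);  Tt[1:3, 4] <- params$translation_mm
  M <- Tt %*% Tc %*% Rz %*% Sy %*% Tci
  spatial_transform(M, center_mm)
}

#' Resample a volume under a spatial transform on its own grid
#'
#' Backward (pull) resampling: the output voxel at physical coordinate `p`
#' takes the value of the input at `T^-1 p`, so image content moves forward
#' by `T`. Out-of-domain voxels receive `fill_value`. An exactly-identity
#' transform returns the input bit-for-bit.
#'
#' @param volume 3D numeric array.
#' @param spacing length-3 voxel spacing, mm.
#' @param transform a [spatial_transform()].
#' @param interpolation `"linear"` for images, `"nearest"` for label volumes.
#' @param fill_value value for voxels mapped outside the input domain;
#'   defaults to the volume minimum (0 is appropriate for masks).
#' @return Resampled array with the same dimensions.
#' @export
resample_with_transform <- function(volume, spacing, transform,
                                    interpolation = c("linear", "nearest"),
                                    fill_value = min(volume)) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(dim(volume)) == 3, length(spacing) == 3)
  if (is_identity_transform(transform)) return(volume)
  Minv <- solve(transform$matrix)
  g <- grid_coords_mm(dim(volume), spacing)
  qx <- Minv[1, 1] * g$x + Minv[1, 2] * g$y + Minv[1, 3] * g$z + Minv[1, 4]
  qy <- Minv[2, 1] * g$x + Minv[2, 2] * g$y + Minv[2, 3] * g$z + Minv[2, 4]
  qz <- Minv[3, 1] * g$x + Minv[3, 2] * g$y + Minv[3, 3] * g$z + Minv[3, 4]
  ci <- qx / spacing[1] + 1; cj <- qy / spacing[2] + 1; ck <- qz / spacing[3] + 1
  v <- if (interpolation == "linear") interp_trilinear(volume, ci, cj, ck, fill_value)
       else interp_nearest(volume, ci, cj, ck, fill_value)
  array(v, dim = dim(volume))
}
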