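# Internal numerical helpers shared across modules.

#' @keywords internal
abort <- function(message, class) {
  stop(structure(
    class = c(class, "misalignr_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)

#' Round half away from zero to a fixed number of decimals
#'
#' `base::round()` rounds half to even; printed prevalence percentages use
#' conventional half-up rounding (34.435 -> 34.44), so this is used wherever
#' a two-decimal percentage is reported.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Trilinear sampling of a 3D array at continuous (1-based) voxel indices
#'
#' Out-of-domain samples are set to `fill`. Indices exactly on the upper
#' face are handled by clamping the upper interpolation corner.
#' @keywords internal
interp_trilinear <- function(vol, ci, cj, ck, fill) {
  d <- dim(vol)
  inside <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
  i0 <- pmin(pmax(floor(ci), 1), d[1]); fi <- pmin(pmax(ci - i0, 0), 1)
  j0 <- pmin(pmax(floor(cj), 1), d[2]); fj <- pmin(pmax(cj - j0, 0), 1)
  k0 <- pmin(pmax(floor(ck), 1), d[3]); fk <- pmin(pmax(ck - k0, 0), 1)
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  s1 <- d[1]; s2 <- d[1] * d[2]
  b000 <- i0 + (j0 - 1) * s1 + (k0 - 1) * s2
  v <- (1 - fi) * (1 - fj) * (1 - fk) * vol[b000] +
       fi       * (1 - fj) * (1 - fk) * vol[i1 + (j0 - 1) * s1 + (k0 - 1) * s2] +
       (1 - fi) * fj       * (1 - fk) * vol[i0 + (j1 - 1) * s1 + (k0 - 1) * s2] +
       fi       * fj       * (1 - fk) * vol[i1 + (j1 - 1) * s1 + (k0 - 1) * s2] +
       (1 - fi) * (1 - fj) * fk       * vol[i0 + (j0 - 1) * s1 + (k1 - 1) * s2] +
       fi       * (1 - fj) * fk       * vol[i1 + (j0 - 1) * s1 + (k1 - 1) * s2] +
       (1 - fi) * fj       * fk       * vol[i0 + (j1 - 1) * s1 + (k1 - 1) * s2] +
       fi       * fj       * fk       * vol[i1 + (j1 - 1) * s1 + (k1 - 1) * s2]
  v[!inside] <- fill
  v
}

#' @keywords internal
interp_nearest <- function(vol, ci, cj, ck, fill) {
  d <- dim(vol)
  ri <- round(ci); rj <- round(cj); rk <- round(ck)
  inside <- ri >= 1 & ri <= d[1] & rj >= 1 & rj <= d[2] & rk >= 1 & rk <= d[3]
  ri <- pmin(pmax(ri, 1), d[1]); rj <- pmin(pmax(rj, 1), d[2]); rk <- pmin(pmax(rk, 1), d[3])
  v <- vol[ri + (rj - 1) * d[1] + (rk - 1) * d[1] * d[2]]
  v[!inside] <- fill
  v
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Truncated (3 sigma) kernels, renormalized row-wise at the boundaries
#' (replicate-style edge handling). sigma is given per axis in mm and
#' converted with the voxel spacing; sigma <= 0 skips that axis.
#' @keywords internal
gaussian_smooth <- function(vol, spacing, sigma_mm) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  out <- vol
  for (ax in 1:3) {
    sv <- sigma_mm[ax] / spacing[ax]
    if (sv <= 1e-8) next
    r <- max(1L, ceiling(3 * sv))
    k <- stats::dnorm(seq(-r, r), sd = sv)
    n <- dim(out)[ax]
    # band matrix with renormalized truncated rows
    K <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      idx <- seq_len(n)
      tgt <- idx + off
      keep <- tgt >= 1 & tgt <= n
      K[cbind(idx[keep], tgt[keep])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(out, perm)
    da <- dim(a)
    m <- K %*% matrix(a, nrow = da[1])
    dim(m) <- da
    out <- aperm(m, order(perm))
  }
  out
}

#' Physical coordinates of every voxel center, origin at the first voxel
#' @keywords internal
grid_coords_mm <- function(dim3, spacing) {
  list(
    x = rep((seq_len(dim3[1]) - 1) * spacing[1], times = dim3[2] * dim3[3]),
    y = rep(rep((seq_len(dim3[2]) - 1) * spacing[2], each = dim3[1]), times = dim3[3]),
    z = rep((seq_len(dim3[3]) - 1) * spacing[3], each = dim3[1] * dim3[2])
  )
}

#' Center of the voxel grid in mm
#' @keywords internal
grid_center_mm <- function(dim3, spacing) (dim3 - 1) * spacing / 2

#' Centroid (mm) of the nonzero voxels of a mask
#' @keywords internal
mask_centroid_mm <- function(mask, spacing) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  (colMeans(idx) - 1) * spacing
}

#' Block-smoothed strided downsampling (for registration pyramids)
#' @keywords internal
downsample_volume <- function(vol, spacing, factor) {
  factor <- pmax(1L, as.integer(rep(factor, length.out = 3)))
  if (all(factor == 1L)) return(list(vol = vol, spacing = spacing))
  sm <- gaussian_smooth(vol, spacing, sigma_mm = 0.45 * (factor - 1L) * spacing)
  d <- dim(vol)
  ix <- seq(1L, d[1], by = factor[1])
  iy <- seq(1L, d[2], by = factor[2])
  iz <- seq(1L, d[3], by = factor[3])
  list(vol = sm[ix, iy, iz, drop = FALSE], spacing = spacing * factor)
}

#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}
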