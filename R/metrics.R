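#' Dice overlap of two binary volumes
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 0 when both volumes are
#' empty.
#'
#' @param a,b Logical/binary arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice_score(array(c(TRUE, TRUE), 2), array(c(TRUE, FALSE), 2))
#' @export
dice_score <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}

#' Skeletonize a super-resolution vessel image
#'
#' Binarizes the density image and thins it to one-voxel-wide centerlines
#' with a homotopy-preserving 3-D thinning: only simple points (deletion
#' leaves object 26-topology and background 6-topology unchanged) that are
#' not curve endpoints are removed, in six directional subiterations until
#' stability. The skeleton is always a subset of the binarized support.
#'
#' @param image A [render_density()] `ulm_image`, or a 3-D array.
#' @param binarize_threshold Voxels strictly above this value form the
#'   vessel support (default 0: any rendered intensity).
#' @return Binary 3-D integer array of centerline voxels.
#' @export
skeletonize_ulm <- function(image, binarize_threshold = 0) {
  arr <- if (inherits(image, "ulm_image")) image$density else image
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  bin <- as.integer(arr > binarize_threshold)
  d <- dim(arr)
  array(thin3(bin, as.integer(d)), d)
}

#' Vascular dropout metric: centerline density per cubic millimetre
#'
#' Counts skeleton voxels inside the region of interest and divides by
#' the ROI volume. A shrinking value over time indicates disappearance of
#' functional (detectable-flow) vasculature.
#'
#' @param skeleton Binary skeleton array from [skeletonize_ulm()].
#' @param roi Binary ROI mask, same shape as `skeleton`.
#' @param voxel_size_mm Voxel size of the skeleton grid, mm.
#' @return Centerline voxels per mm^3.
#' @export
vascular_density <- function(skeleton, roi, voxel_size_mm) {
  stopifnot(all(dim(skeleton) == dim(roi)), voxel_size_mm > 0)
  roi <- roi != 0
  vol_mm3 <- sum(roi) * voxel_size_mm^3
  if (vol_mm3 <= 0) stop("vascular_density: ROI volume is zero")
  sum(skeleton[roi] != 0) / vol_mm3
}

#' Hemisphere region-of-interest mask
#'
#' Builds the analysis mask used by the vascular dropout metric: one
#' lateral hemisphere, optionally restricted to the anterior half of the
#' elevation axis (the implant side analysed in practice).
#'
#' @param dims Integer 3-vector of grid voxel counts.
#' @param voxel_size_mm Grid voxel size, mm.
#' @param side `"left"` (lateral coordinate below the midline) or
#'   `"right"`.
#' @param anterior_only Restrict to the anterior (lower elevation) half.
#' @return Logical 3-D array.
#' @export
roi_hemisphere <- function(dims, voxel_size_mm, side = c("left", "right"),
                           anterior_only = FALSE) {
  side <- match.arg(side)
  dims <- as.integer(dims)
  x <- voxel_center_mm(seq_len(dims[2]), voxel_size_mm)
  mid <- dims[2] * voxel_size_mm / 2
  in_side <- if (side == "left") x < mid else x > mid
  mask <- array(FALSE, dims)
  mask[, in_side, ] <- TRUE
  if (anterior_only) {
    y <- voxel_center_mm(seq_len(dims[3]), voxel_size_mm)
    mask[, , y > dims[3] * voxel_size_mm / 2] <- FALSE
  }
  mask
}

#' Bilateral symmetry score of a vessel image
#'
#' Measures how mirror-symmetric the reconstructed vasculature is about
#' the sagittal midline. The image is downsampled to a fifth-wavelength
#' voxel by mean pooling (suppressing small-vessel asymmetries), centered
#' laterally by shifting the lateral center of mass onto the grid
#' midline, rotationally centered about the depth and elevation axes by a
#' grid search (within `rotation_range_deg` in 1 degree steps, each axis
#' in turn, maximizing the mirror dice; rotation about the lateral axis
#' cannot affect the comparison and is skipped), power-compressed with
#' exponent 0.5, dilated with a spherical kernel of 0.4 wavelength
#' radius, Gaussian-filtered, binarized (nonzero), and compared to its
#' lateral reflection with the dice score.
#'
#' @param image A [render_density()] `ulm_image`.
#' @param wavelength Acoustic wavelength, mm (sets the pooling target and
#'   dilation radius).
#' @param rotation_range_deg Half-width of the rotation search, degrees.
#' @param rotation_search Set `FALSE` to skip rotational centering.
#' @param center_lateral Set `FALSE` to skip the lateral center-of-mass
#'   shift and score the volume against its mirror in place. Centering
#'   folds a strictly one-sided volume onto itself (a centered single
#'   hemisphere is mirror-symmetric about its own center of mass), so the
#'   raw one-hemisphere-versus-mirror comparison needs `FALSE`.
#' @return Dice score in `[0, 1]` with attributes `lateral_shift_voxels`,
#'   `rotation_deg` (depth, elevation); an empty image returns 0 with a
#'   warning.
#' @export
bilateral_symmetry <- function(image, wavelength = wavelength_mm(),
                               rotation_range_deg = 10,
                               rotation_search = TRUE,
                               center_lateral = TRUE) {
  stopifnot(inherits(image, "ulm_image"))
  if (all(image$density == 0)) {
    warning("bilateral_symmetry: empty image, dice reported as 0")
    return(structure(0, lateral_shift_voxels = NA_integer_,
                     rotation_deg = c(NA_real_, NA_real_)))
  }
  target <- wavelength / 5
  f <- max(1L, as.integer(round(target / image$render_voxel_mm)))
  pooled <- pool_mean3(image$density, f)

  # lateral translational centering: integer COM shift onto the midline
  d <- dim(pooled)
  shift <- 0L
  if (center_lateral) {
    lat_mass <- apply(pooled, 2, sum)
    com <- sum(lat_mass * seq_len(d[2])) / sum(lat_mass)
    shift <- as.integer(round((d[2] + 1) / 2 - com))
    pooled <- shift_lateral(pooled, shift)
  }

  dil_r <- 0.4 * wavelength / (image$render_voxel_mm * f)
  score_of <- function(vol) {
    proc <- sqrt(vol)
    proc <- binary_dilate3(proc, dil_r)
    proc <- gauss3(proc + 0, 1)
    bin <- proc > 1e-12
    dice_score(bin, bin[, rev(seq_len(dim(bin)[2])), , drop = FALSE])
  }

  angles <- c(0, 0)
  if (rotation_search && rotation_range_deg > 0) {
    grid <- seq(-rotation_range_deg, rotation_range_deg, by = 1)
    grid <- grid[order(abs(grid), grid)] # ties resolved toward 0 degrees
    for (axis in 1:2) { # 1: about depth axis, 2: about elevation axis
      best <- -Inf; best_a <- 0
      for (a in grid) {
        sc <- score_of(rotate_about_axis(pooled, a, axis))
        if (sc > best + 1e-12) { best <- sc; best_a <- a }
      }
      angles[axis] <- best_a
      if (best_a != 0) pooled <- rotate_about_axis(pooled, best_a, axis)
    }
  }
  structure(score_of(pooled),
            lateral_shift_voxels = shift,
            rotation_deg = angles)
}

# mean pooling by an integer factor (zero-pad to a multiple)
pool_mean3 <- function(arr, f) {
  if (f == 1) return(arr)
  d <- dim(arr)
  dp <- ceiling(d / f) * f
  if (any(dp != d)) {
    tmp <- array(0, dp)
    tmp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    arr <- tmp
  }
  dn <- dp / f
  # average over f^3 blocks
  a <- array(arr, c(f, dn[1], f, dn[2], f, dn[3]))
  apply(a, c(2, 4, 6), mean)
}

# integer shift along the lateral (second) dimension, zero fill
shift_lateral <- function(arr, s) {
  if (s == 0) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  if (s > 0) out[, (1 + s):d[2], ] <- arr[, seq_len(d[2] - s), , drop = FALSE]
  else out[, seq_len(d[2] + s), ] <- arr[, (1 - s):d[2], , drop = FALSE]
  out
}

# nearest-neighbour rotation of the lateral coordinate plane about the
# grid center; axis 1 rotates the (lateral, elevation) plane (about
# depth), axis 2 rotates the (depth, lateral) plane (about elevation)
rotate_about_axis <- function(arr, angle_deg, axis) {
  if (angle_deg == 0) return(arr)
  d <- dim(arr)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  if (axis == 1) { u <- 2; w <- 3 } else { u <- 1; w <- 2 }
  cu <- (d[u] + 1) / 2; cw <- (d[w] + 1) / 2
  iu <- slice.index(array(0L, d), u) - cu
  iw <- slice.index(array(0L, d), w) - cw
  su <- round(ct * iu - st * iw + cu)
  sw <- round(st * iu + ct * iw + cw)
  ok <- su >= 1 & su <= d[u] & sw >= 1 & sw <= d[w]
  out <- array(0, d)
  idx <- arrayInd(which(ok), d)
  src <- idx
  src[, u] <- su[ok]
  src[, w] <- sw[ok]
  out[idx] <- arr[src]
  out
}
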