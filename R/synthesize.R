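#' Synthesize a beamformed-like intensity volume stack
#'
#' Turns ground-truth bubble records into a 4-D intensity stack with the
#' statistical structure the downstream analysis assumes: each bubble
#' contributes a Gaussian blob of the stated FWHM (default one wavelength,
#' i.e. two half-wavelength voxels) centered at its subvoxel position with
#' unit peak amplitude; a static, spatially smooth tissue field — rank one
#' in time, the minimal model the SVD clutter filter addresses — is added
#' in every frame; and i.i.d. Gaussian electronic noise is added per voxel
#' per frame before envelope rectification (absolute value), so all
#' intensities are nonnegative.
#'
#' Bubbles outside the grid are clipped (dropped from the raster with a
#' message), not an error; their count is available as the `n_clipped`
#' attribute of the returned stack.
#'
#' @param truth Ground-truth records from [simulate_mb_transits()].
#' @param grid A [grid_spec()] for one volume.
#' @param psf_fwhm_mm Blob full width at half maximum, mm; defaults to one
#'   wavelength at `center_frequency`.
#' @param tissue_amplitude Peak amplitude of the static tissue field in
#'   units of the bubble peak (default 10: clutter well above bubbles, as
#'   in vivo).
#' @param noise_sigma Standard deviation of the additive noise in bubble
#'   peak units (default 0.01, i.e. 40 dB below a bubble peak, the regime in which a 3-4 % noise-floor cut removes it).
#' @param n_volumes Number of frames; defaults to the `n_volumes`
#'   attribute of `truth`.
#' @param volume_rate Volumetric frame rate, Hz.
#' @param center_frequency Hz; sets the default wavelength.
#' @param sound_speed m/s.
#' @param seed Integer RNG seed for tissue field and noise.
#' @param frames Optional integer vector of volume indices to synthesize
#'   (default all of `1:n_volumes`); lets a caller stream the stack
#'   batch-by-batch. Frame `frames[i]` of the request becomes slice `i`
#'   of the returned stack.
#' @param tissue Optional precomputed static tissue field (3-D array on
#'   `grid`); pass the same field to every batch of a streamed stack so
#'   the clutter really is identical in all frames.
#' @return A [volume_stack()].
#' @export
synthesize_volume_stack <- function(truth, grid,
                                    psf_fwhm_mm = NULL,
                                    tissue_amplitude = 10,
                                    noise_sigma = 0.01,
                                    n_volumes = attr(truth, "n_volumes"),
                                    volume_rate = 500,
                                    center_frequency = 7.81e6,
                                    sound_speed = 1540,
                                    seed = 1,
                                    frames = NULL,
                                    tissue = NULL) {
  stopifnot(inherits(grid, "grid_spec"), !is.null(n_volumes), n_volumes >= 1)
  if (is.null(frames)) frames <- seq_len(n_volumes)
  frame_of <- integer(n_volumes)
  frame_of[frames] <- seq_along(frames)
  nt_out <- length(frames)
  if (is.null(psf_fwhm_mm)) {
    psf_fwhm_mm <- wavelength_mm(center_frequency, sound_speed)
  }
  v <- grid$voxel_size_mm
  dims <- grid$dim
  sigma_mm <- psf_sigma_from_fwhm(psf_fwhm_mm)
  r_vox <- ceiling(3 * sigma_mm / v)

  stack <- array(0, c(dims, nt_out))

  # bubbles: truncated Gaussian blob at each subvoxel position
  n_clipped <- 0L
  if (nrow(truth) > 0) {
    inside <- truth$z_mm >= 0 & truth$z_mm <= grid$extent_mm[1] &
      truth$x_mm >= 0 & truth$x_mm <= grid$extent_mm[2] &
      truth$y_mm >= 0 & truth$y_mm <= grid$extent_mm[3] &
      truth$volume_index >= 1 & truth$volume_index <= n_volumes
    n_clipped <- sum(!inside)
    inside <- inside & truth$volume_index %in% frames
    if (n_clipped > 0) {
      message("synthesize_volume_stack: clipped ", n_clipped,
              " bubble records outside the grid")
    }
    tr <- truth[inside, , drop = FALSE]
    off <- -r_vox:r_vox
    for (rec in seq_len(nrow(tr))) {
      p <- c(tr$z_mm[rec], tr$x_mm[rec], tr$y_mm[rec])
      c0 <- floor(p / v) + 1L
      iz <- c0[1] + off; ix <- c0[2] + off; iy <- c0[3] + off
      okz <- iz >= 1 & iz <= dims[1]
      okx <- ix >= 1 & ix <= dims[2]
      oky <- iy >= 1 & iy <= dims[3]
      gz <- exp(-((iz[okz] - 0.5) * v - p[1])^2 / (2 * sigma_mm^2))
      gx <- exp(-((ix[okx] - 0.5) * v - p[2])^2 / (2 * sigma_mm^2))
      gy <- exp(-((iy[oky] - 0.5) * v - p[3])^2 / (2 * sigma_mm^2))
      blob <- outer(outer(gz, gx), gy)
      f <- frame_of[tr$volume_index[rec]]
      stack[iz[okz], ix[okx], iy[oky], f] <-
        stack[iz[okz], ix[okx], iy[oky], f] + blob
    }
  }

  nvox <- prod(dims)
  with_seed(seed, {
    if (is.null(tissue) && tissue_amplitude > 0) {
      tissue <- tissue_field(dims, tissue_amplitude)
    }
    if (!is.null(tissue)) {
      stack <- stack + as.vector(tissue) # recycled over frames
    }
    if (noise_sigma > 0) {
      stack <- stack + rnorm(nvox * nt_out, sd = noise_sigma)
    }
  })
  stack <- abs(stack)

  out <- volume_stack(stack, voxel_size_mm = v, volume_rate = volume_rate,
                      center_frequency = center_frequency,
                      sound_speed = sound_speed)
  attr(out, "n_clipped") <- n_clipped
  out
}

# static smooth positive random field in [0.3, 1] * amplitude
tissue_field <- function(dims, amplitude, smooth_sigma = 4) {
  w <- array(rnorm(prod(dims)), dims)
  g <- array(gaussian_filter3(as.numeric(w), dims, smooth_sigma, TRUE), dims)
  rng <- range(g)
  scaled <- (g - rng[1]) / max(rng[2] - rng[1], 1e-12)
  amplitude * (0.3 + 0.7 * scaled)
}
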