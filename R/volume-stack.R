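#' 4-D beamformed intensity volume stack
#'
#' Container for beamformed intensity data on an isotropic half-wavelength
#' grid: a nonnegative array of shape (depth, lateral, elevation, time)
#' plus the acquisition geometry needed downstream.
#'
#' @param data Nonnegative 4-D array (N_dep x N_lat x N_el x N_t).
#' @param voxel_size_mm Isotropic voxel size, mm (default \eqn{\lambda/2}).
#' @param volume_rate Volumetric frame rate, Hz.
#' @param center_frequency Transmit center frequency, Hz.
#' @param sound_speed Assumed sound speed, m/s.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data,
                         voxel_size_mm = wavelength_mm(center_frequency, sound_speed) / 2,
                         volume_rate = 500,
                         center_frequency = 7.81e6,
                         sound_speed = 1540) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (min(data) < 0) stop("volume_stack: intensities must be nonnegative")
  stopifnot(voxel_size_mm > 0, volume_rate > 0)
  lambda <- wavelength_mm(center_frequency, sound_speed)
  if (abs(voxel_size_mm - lambda / 2) > 0.25 * lambda) {
    warning("voxel_size_mm is far from lambda/2 for the declared center frequency")
  }
  structure(
    list(data = data,
         voxel_size_mm = voxel_size_mm,
         volume_rate = volume_rate,
         center_frequency = center_frequency,
         sound_speed = sound_speed),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d x %d x %d voxels x %d volumes @ %.4f mm, %g vps\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm, x$volume_rate))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

#' Number of volumes (time frames) in a stack
#' @param stack A [volume_stack()].
#' @return Integer frame count.
#' @export
n_volumes <- function(stack) dim(stack$data)[4]

#' Grid specification of a stack
#' @param stack A [volume_stack()].
#' @return The spatial [grid_spec()] of one volume.
#' @export
stack_grid <- function(stack) {
  grid_spec(dim(stack$data)[1:3], stack$voxel_size_mm)
}
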