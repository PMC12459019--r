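#' Acquisition parameters of the volumetric imaging sequence
#'
#' Collects the constants of the ultrafast volumetric acquisition this
#' pipeline assumes and derives the quantities every later stage uses: the
#' wavelength, the half-wavelength beamforming voxel, the compounded volume
#' rate, and the total number of volumes in a session.
#'
#' The defaults describe a 7.81 MHz matrix-probe sequence: five compounded
#' plane waves fired at a 2500 Hz pulse repetition frequency give a
#' 500 volumes-per-second (vps) rate, and a 200 s contrast acquisition
#' yields 100 000 volumes. The beamforming grid is isotropic at
#' \eqn{\lambda/2} where \eqn{\lambda = c / f_c}.
#'
#' @param center_frequency Transmit center frequency, Hz.
#' @param sound_speed Assumed speed of sound in tissue, m/s.
#' @param prf Pulse repetition frequency, Hz.
#' @param n_angles Number of compounded plane-wave transmits per volume.
#' @param duration_s Length of one contrast acquisition, seconds.
#'
#' @return A one-row tibble with the stated constants and the derived
#'   `wavelength_mm`, `voxel_size_mm` (\eqn{\lambda/2}), `volume_rate`
#'   (vps) and `n_volumes`.
#' @examples
#' acquisition_params()
#' @export
acquisition_params <- function(center_frequency = 7.81e6,
                               sound_speed = 1540,
                               prf = 2500,
                               n_angles = 5,
                               duration_s = 200) {
  stopifnot(center_frequency > 0, sound_speed > 0, prf > 0, n_angles >= 1)
  lambda <- wavelength_mm(center_frequency, sound_speed)
  rate <- prf / n_angles
  tibble::tibble(
    center_frequency = center_frequency,
    sound_speed = sound_speed,
    prf = prf,
    n_angles = n_angles,
    duration_s = duration_s,
    wavelength_mm = lambda,
    voxel_size_mm = lambda / 2,
    volume_rate = rate,
    n_volumes = duration_s * rate
  )
}

#' Ultrasound wavelength in millimetres
#'
#' @param center_frequency Center frequency, Hz.
#' @param sound_speed Speed of sound, m/s.
#' @return Wavelength \eqn{c/f_c} in mm.
#' @examples
#' wavelength_mm() # ~0.1972 mm at 7.81 MHz
#' @export
wavelength_mm <- function(center_frequency = 7.81e6, sound_speed = 1540) {
  sound_speed / center_frequency * 1000
}

#' Gaussian standard deviation from a full width at half maximum
#'
#' The point spread function of a microbubble is modeled as a Gaussian
#' whose lateral/elevation FWHM is about one wavelength (two half-wavelength
#' voxels); the matched filter kernel uses
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}.
#'
#' @param fwhm Full width at half maximum (any unit; the result carries it).
#' @return The standard deviation in the same unit.
#' @examples
#' psf_sigma_from_fwhm(2) # ~0.85 voxels; 0.8 is used as the kernel default
#' @export
psf_sigma_from_fwhm <- function(fwhm) {
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Imaging-session success rate
#'
#' Fraction of acquired datasets that yielded analysable vascular images,
#' reported as a percentage.
#'
#' @param n_used Number of datasets retained for analysis.
#' @param n_acquired Number of datasets acquired.
#' @return Percentage in `[0, 100]`.
#' @examples
#' dataset_success_rate(33, 40)
#' @export
dataset_success_rate <- function(n_used, n_acquired) {
  stopifnot(n_acquired > 0, n_used >= 0, n_used <= n_acquired)
  100 * n_used / n_acquired
}
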