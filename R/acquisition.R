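#' Acquisition configuration
#'
#' Describes the spectrometer geometry and detection settings used by the
#' interferogram simulator.  Defaults mirror a white-light spectral-domain
#' system detecting 400--700 nm on 8192 binned spectrometer pixels
#' (0.044 nm/pixel) and raster-scanning 512 A-scans per B-scan.
#'
#' @param n_pixels number of spectrometer pixels (>= 16).
#' @param wavelength_min,wavelength_max detected wavelength range in nm.
#' @param n_ascans A-scans per B-scan.
#' @param n_bscans B-scans per volume.
#' @param shot_scale variance of the signal-proportional (shot-like) noise per
#'   detector count; 0 disables it.
#' @param read_std standard deviation of additive read noise in counts.
#' @param pixel_mtf_width standard deviation (rad/nm) of the Gaussian
#'   spectrometer pixel response in k.  Attenuates fringe visibility with
#'   depth (sensitivity roll-off); 0 disables roll-off.
#' @param dc_level reference-arm DC level relative to the fringe amplitude
#'   scale (the non-interferometric background added to both channels).
#' @param depth_jitter_um per-A-scan axial jitter (standard deviation, um)
#'   applied to all layer depths of that A-scan.  Models surface topography /
#'   axial motion; decorrelates fringes laterally so that B-scan-mean
#'   background subtraction leaves the fringes intact.  Default 0.
#' @param amplitude_scale detector counts corresponding to a unit-reflectivity
#'   fringe amplitude at the source peak.
#' @param seed integer seed for the simulator's random draws (noise and
#'   depolarizing-layer states).
#'
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_pixels = 8192L,
                               wavelength_min = 400,
                               wavelength_max = 700,
                               n_ascans = 512L,
                               n_bscans = 1L,
                               shot_scale = 0,
                               read_std = 0,
                               pixel_mtf_width = 0,
                               dc_level = 1,
                               depth_jitter_um = 0,
                               amplitude_scale = 1000,
                               seed = 1L) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 16L) stop("n_pixels must be >= 16")
  if (!(wavelength_min < wavelength_max))
    stop("wavelength_min must be < wavelength_max")
  if (shot_scale < 0 || read_std < 0 || pixel_mtf_width < 0)
    stop("noise and roll-off parameters must be >= 0")
  structure(list(
    n_pixels = n_pixels,
    wavelength_min = wavelength_min,
    wavelength_max = wavelength_max,
    n_ascans = as.integer(n_ascans),
    n_bscans = as.integer(n_bscans),
    shot_scale = shot_scale,
    read_std = read_std,
    pixel_mtf_width = pixel_mtf_width,
    dc_level = dc_level,
    depth_jitter_um = depth_jitter_um,
    amplitude_scale = amplitude_scale,
    seed = as.integer(seed)
  ), class = "acquisition_config")
}

#' Wavelength axis of an acquisition configuration
#'
#' Uniform grid in wavelength (nm, ascending), as sampled by the spectrometer.
#'
#' @param config an [acquisition_config()].
#' @return numeric vector of length `n_pixels`.
#' @export
wavelength_axis <- function(config) {
  seq(config$wavelength_min, config$wavelength_max,
      length.out = config$n_pixels)
}

#' Maximum (Nyquist) imaging depth of a configuration
#'
#' Depth sampling after k-space resampling is `dz = pi / (N * dk)` with `dk`
#' the uniform k step; the positive-frequency half of the FFT then spans
#' `N/2 * dz`.
#'
#' @param config an [acquisition_config()].
#' @return maximum optical-path depth in um.
#' @export
max_depth_um <- function(config) {
  k_hi <- 2 * pi / config$wavelength_min
  k_lo <- 2 * pi / config$wavelength_max
  dk <- (k_hi - k_lo) / (config$n_pixels - 1)
  dz_nm <- pi / (config$n_pixels * dk)
  config$n_pixels / 2 * dz_nm / 1000
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %d px, %g-%g nm, %d x %d A/B-scans, z_max %.0f um\n",
    x$n_pixels, x$wavelength_min, x$wavelength_max,
    x$n_ascans, x$n_bscans, max_depth_um(x)))
  invisible(x)
}
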