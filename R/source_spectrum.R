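#' Source spectrum on the spectrometer grid
#'
#' Builds the detected source power spectrum sampled on the uniform
#' wavelength grid of an acquisition configuration, normalized to peak 1.
#'
#' @param config an [acquisition_config()].
#' @param shape one of `"gaussian"`, `"rectangular"`, `"tabulated"`.
#' @param center_nm,fwhm_nm Gaussian center and full width at half maximum of
#'   the power spectrum (nm); required for `shape = "gaussian"`.
#' @param table for `shape = "tabulated"`: a two-column matrix or data frame
#'   (wavelength_nm, power) interpolated linearly onto the grid.
#'
#' @return object of class `source_spectrum` with fields `wavelength_nm`,
#'   `power` (peak-normalized, >= 0) and `shape`.
#' @export
make_source_spectrum <- function(config,
                                 shape = c("gaussian", "rectangular",
                                           "tabulated"),
                                 center_nm = NULL, fwhm_nm = NULL,
                                 table = NULL) {
  shape <- match.arg(shape)
  wl <- wavelength_axis(config)
  power <- switch(shape,
    gaussian = {
      if (is.null(center_nm) || is.null(fwhm_nm))
        stop("gaussian shape needs center_nm and fwhm_nm")
      if (fwhm_nm <= 0) stop("fwhm_nm must be > 0")
      if (center_nm < config$wavelength_min ||
          center_nm > config$wavelength_max)
        stop("center_nm outside the detected wavelength range")
      exp(-4 * log(2) * ((wl - center_nm) / fwhm_nm)^2)
    },
    rectangular = rep(1, length(wl)),
    tabulated = {
      if (is.null(table)) stop("tabulated shape needs a table")
      tab <- as.matrix(table)
      p <- stats::approx(tab[, 1], tab[, 2], xout = wl, rule = 2)$y
      if (any(p < 0)) stop("tabulated power must be >= 0")
      p
    })
  power <- power / max(power)
  structure(list(wavelength_nm = wl, power = power, shape = shape),
            class = "source_spectrum")
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf("<source_spectrum> %s, %d px, %g-%g nm\n", x$shape,
              length(x$power), min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}
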