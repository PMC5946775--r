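#' One-call reconstruction pipeline
#'
#' Background subtraction (optional), channel alignment (optional),
#' k-space resampling, dispersion correction and Fourier transform.
#'
#' @param frame a `raw_frame`.
#' @param background subtract the B-scan-average background spectrum.
#'   Disable for laterally uniform noiseless phantoms, whose fringes are
#'   identical in every A-scan and would be removed together with the
#'   background.
#' @param calib optional [channel_calibration()] applied before resampling.
#' @param dispersion `NULL`, a `dispersion_model`, or `"auto"` for
#'   [optimize_dispersion()] with `n_bands` bands.
#' @param n_bands bands for `"auto"` (default 3).
#' @param interp interpolation order for alignment and resampling.
#' @param pad zero-padding factor for the transform.
#' @return a `complex_tomogram`.
#' @export
reconstruct <- function(frame, background = TRUE, calib = NULL,
                        dispersion = NULL, n_bands = 3L,
                        interp = c("cubic", "linear"), pad = 1L) {
  interp <- match.arg(interp)
  if (background) frame <- subtract_background(frame)
  if (!is.null(calib)) frame <- align_channels(frame, calib, interp)
  kf <- resample_to_k(frame, interp)
  model <- if (identical(dispersion, "auto"))
    optimize_dispersion(kf, n_bands = n_bands) else dispersion
  tomogram(kf, model, pad)
}
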