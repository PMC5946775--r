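#' Phase retardation image with SNR masking
#'
#' Per pixel, `delta = arctan(|A_V| / |A_H|)` in degrees (0--90).  The value
#' is only computed where the reflectivity exceeds the mean noise level by
#' `threshold_db` (default 4 dB, the midpoint of the usual 3--5 dB range);
#' below that, the pixel is masked (sentinel `NA`, rendered neutral gray on
#' export) because the amplitude ratio of noise is meaningless.
#'
#' @param tomo a `complex_tomogram`.
#' @param threshold_db intensity cutoff above the mean noise floor, dB
#'   (>= 0).
#' @param floor_fraction passed to [noise_floor()].
#' @param noise_floor_linear optional explicit linear noise floor (overrides
#'   the estimate from the deepest bins).
#' @return object of class `retardation_image`: `delta_deg` (NA where
#'   masked), logical `mask` (TRUE = computed), and the applied
#'   `threshold_db`.
#' @export
retardation <- function(tomo, threshold_db = 4, floor_fraction = 0.1,
                        noise_floor_linear = NULL) {
  if (threshold_db < 0) stop("threshold_db must be >= 0")
  R <- reflectivity(tomo)
  floor_lin <- noise_floor_linear %||% noise_floor(R, floor_fraction)
  mask <- R >= floor_lin * 10^(threshold_db / 10)
  delta <- rad2deg(atan2(Mod(tomo$A_V), Mod(tomo$A_H)))
  delta[!mask] <- NA_real_
  structure(list(delta_deg = delta, mask = mask,
                 threshold_db = threshold_db,
                 z_axis_um = tomo$z_axis_um),
            class = "retardation_image")
}

#' @export
print.retardation_image <- function(x, ...) {
  cat(sprintf("<retardation_image> %d x %d, %.0f%% above %g dB threshold\n",
              nrow(x$delta_deg), ncol(x$delta_deg),
              100 * mean(x$mask), x$threshold_db))
  invisible(x)
}

#' First-order error propagation through the retardation equation
#'
#' Propagates per-channel amplitude standard deviations through
#' `delta = arctan(A_V / A_H)`:
#' `sigma_delta^2 = ((A_H*sigma_V)^2 + (A_V*sigma_H)^2) / (A_H^2 + A_V^2)^2`
#' (radians), reported in degrees together with the mean retardation.
#'
#' @param mean_H,std_H,mean_V,std_V channel amplitude means and standard
#'   deviations (vectors allowed).
#' @return list with `delta_mean_deg` and `delta_std_deg`.
#' @export
propagate_error <- function(mean_H, std_H, mean_V, std_V) {
  if (any(std_H < 0) || any(std_V < 0)) stop("standard deviations must be >= 0")
  if (any(mean_H == 0 & mean_V == 0))
    stop("channel means must not both be zero")
  denom <- (mean_H^2 + mean_V^2)^2
  var_rad <- ((mean_H * std_V)^2 + (mean_V * std_H)^2) / denom
  list(delta_mean_deg = rad2deg(atan2(abs(mean_V), abs(mean_H))),
       delta_std_deg = rad2deg(sqrt(var_rad)))
}

#' Mean and propagated error of repeated measurements
#'
#' For a tomogram of repeated A-scans acquired at a fixed beam position
#' (e.g. 512 repeats on a static phantom), computes per-depth channel
#' amplitude means and standard deviations over the repeats and feeds them
#' through [propagate_error()], giving the mean retardation with its
#' propagated standard deviation at every depth.
#'
#' @param tomo a `complex_tomogram` whose columns are repeats (>= 2).
#' @return list with per-depth `delta_mean_deg`, `delta_std_deg`, and the
#'   channel statistics `mean_H`, `std_H`, `mean_V`, `std_V`.
#' @export
repeated_measurement_stats <- function(tomo) {
  aH <- Mod(tomo$A_H); aV <- Mod(tomo$A_V)
  if (ncol(aH) < 2) stop("need >= 2 repeats")
  mean_H <- rowMeans(aH); mean_V <- rowMeans(aV)
  std_H <- apply(aH, 1, stats::sd); std_V <- apply(aV, 1, stats::sd)
  pe <- propagate_error(pmax(mean_H, .Machine$double.xmin), std_H,
                        mean_V, std_V)
  c(pe, list(mean_H = mean_H, std_H = std_H,
             mean_V = mean_V, std_V = std_V,
             z_axis_um = tomo$z_axis_um))
}
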