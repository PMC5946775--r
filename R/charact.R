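#' Full width at half maximum of a point spread function
#'
#' FWHM of the dominant peak of an A-scan profile, by linear interpolation
#' of the half-maximum crossings on either side of the peak.  For
#' axial-resolution measurements pass the A-scan magnitude profile
#' (`Mod(A_H)`), whose FWHM obeys the coherence-length relation
#' `FWHM_z = (2*ln2/pi) * lambda0^2 / Delta_lambda` for a Gaussian source.
#'
#' @param profile nonnegative A-scan profile.
#' @param z_axis_um depth axis (same length).
#' @return FWHM in um.
#' @export
psf_fwhm <- function(profile, z_axis_um) {
  if (length(profile) != length(z_axis_um))
    stop("profile and z axis lengths differ")
  p <- which.max(profile)
  half <- profile[p] / 2
  lo <- p
  while (lo > 1 && profile[lo] > half) lo <- lo - 1
  hi <- p
  n <- length(profile)
  while (hi < n && profile[hi] > half) hi <- hi + 1
  if (profile[lo] > half || profile[hi] > half)
    stop("no half-maximum crossing found (flat or saturated profile)")
  zl <- z_axis_um[lo] + (half - profile[lo]) /
    (profile[lo + 1] - profile[lo]) * (z_axis_um[lo + 1] - z_axis_um[lo])
  zr <- z_axis_um[hi - 1] + (half - profile[hi - 1]) /
    (profile[hi] - profile[hi - 1]) * (z_axis_um[hi] - z_axis_um[hi - 1])
  zr - zl
}

#' Axial resolution of a tomogram channel
#'
#' Convenience wrapper: [psf_fwhm()] on the magnitude profile of the
#' strongest A-scan of one polarization channel.
#'
#' @param tomo a `complex_tomogram` of a point reflector.
#' @param channel `"H"` or `"V"`.
#' @param z_min_um depths below this are ignored (residual DC /
#'   autocorrelation energy sits at the zero-delay line), default 5.
#' @return FWHM in um (air optical path).
#' @export
axial_resolution <- function(tomo, channel = c("H", "V"), z_min_um = 5) {
  channel <- match.arg(channel)
  A <- Mod(if (channel == "H") tomo$A_H else tomo$A_V)
  keep <- tomo$z_axis_um >= z_min_um
  A <- A[keep, , drop = FALSE]
  j <- which.max(apply(A, 2, max))
  psf_fwhm(A[, j], tomo$z_axis_um[keep])
}

#' System sensitivity from an attenuated-mirror measurement
#'
#' Sensitivity = measured SNR plus the attenuation introduced by a neutral
#' density filter in the sample arm: `SNR + 10 * pass_count * OD` dB
#' (double-pass by default, since the OCT signal traverses the filter
#' twice).
#'
#' @param snr_db measured signal-to-noise ratio, dB (>= 0).
#' @param nd_optical_density optical density of the ND filter (>= 0).
#' @param pass_count number of passes through the filter (default 2).
#' @return sensitivity in dB.
#' @export
sensitivity <- function(snr_db, nd_optical_density, pass_count = 2) {
  if (snr_db < 0 || nd_optical_density < 0) stop("inputs must be >= 0")
  snr_db + 10 * pass_count * nd_optical_density
}

#' Sensitivity roll-off from peak measurements at several depths
#'
#' Least-squares line fit to peak signal (dB) versus depth; the decay is
#' reported as a positive dB/mm figure.  Invariant to a constant dB offset.
#'
#' @param z_mm depths (mm), at least 3 spanning >= 0.5 mm.
#' @param peak_db peak signal at each depth, dB.
#' @return roll-off decay in dB/mm (positive = decaying).
#' @export
rolloff <- function(z_mm, peak_db) {
  if (length(z_mm) < 3) stop("need >= 3 depth points")
  if (diff(range(z_mm)) < 0.5)
    stop("depth points must span >= 0.5 mm")
  -unname(stats::coef(stats::lm(peak_db ~ z_mm))[2])
}

#' Predicted roll-off of the Gaussian pixel-response model
#'
#' With a Gaussian spectrometer pixel response of standard deviation
#' `sigma_k` (rad/nm) in k, fringe amplitude at depth z is attenuated by
#' `exp(-2 * (sigma_k * z)^2)`; this returns the corresponding peak dB drop
#' at the requested depths (amplitude measure, 20*log10).
#'
#' @param z_mm depths in mm.
#' @param pixel_mtf_width `sigma_k` in rad/nm (the simulator's parameter).
#' @return dB drop (<= 0) at each depth.
#' @export
rolloff_predicted_db <- function(z_mm, pixel_mtf_width) {
  z_nm <- z_mm * 1e6
  20 * log10(exp(-2 * (pixel_mtf_width * z_nm)^2))
}

#' Air-to-tissue conversion of axial distances
#'
#' Optical-path values measured in air divide by the tissue group refractive
#' index (1.37 for rodent retina); reported to 2 significant figures by
#' convention (e.g. 1.0 um in air -> 0.73 um in tissue, 2.2 mm -> 1.6 mm).
#'
#' @param value_air value measured in air (any length unit).
#' @param refractive_index tissue group index (> 1).
#' @param digits significant digits for reporting; `NULL` for no rounding.
#' @return the value in tissue.
#' @export
to_tissue <- function(value_air, refractive_index = 1.37, digits = 2) {
  if (refractive_index <= 1) stop("refractive index must be > 1")
  v <- value_air / refractive_index
  if (is.null(digits)) v else signif(v, digits)
}

#' Characterization report of a simulated system
#'
#' Measures, per polarization channel, the axial PSF FWHM of a mirror frame
#' and (optionally) the sensitivity roll-off from mirror frames at several
#' depths.
#'
#' @param mirror_tomo a `complex_tomogram` of a single mirror.
#' @param rolloff_tomos optional list of tomograms of mirrors at different
#'   depths for the roll-off fit.
#' @return list of class `characterization_report`: `fwhm_air_um` per
#'   channel, `depth_range_mm`, and `rolloff_db_per_mm` per channel when
#'   measured.
#' @export
characterize <- function(mirror_tomo, rolloff_tomos = NULL) {
  rep_ <- list(
    fwhm_air_um = c(H = axial_resolution(mirror_tomo, "H"),
                    V = tryCatch(axial_resolution(mirror_tomo, "V"),
                                 error = function(e) NA_real_)),
    depth_range_mm = max(mirror_tomo$z_axis_um) / 1000
  )
  if (!is.null(rolloff_tomos)) {
    pk <- function(t, ch) {
      A <- Mod(if (ch == "H") t$A_H else t$A_V)
      keep <- t$z_axis_um >= 5
      A <- A[keep, , drop = FALSE]
      j <- which.max(apply(A, 2, max))
      i <- which.max(A[, j])
      c(z = t$z_axis_um[keep][i] / 1000, db = 20 * log10(A[i, j]))
    }
    for (ch in c("H", "V")) {
      m <- vapply(rolloff_tomos, pk, numeric(2), ch = ch)
      rep_$rolloff_db_per_mm[ch] <- if (all(is.finite(m["db", ])))
        rolloff(m["z", ], m["db", ]) else NA_real_
    }
  }
  structure(rep_, class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("<characterization_report> FWHM(air) H %.3f / V %.3f um, depth range %.2f mm\n",
              x$fwhm_air_um["H"], x$fwhm_air_um["V"], x$depth_range_mm))
  if (!is.null(x$rolloff_db_per_mm))
    cat(sprintf("  roll-off H %.1f / V %.1f dB/mm\n",
                x$rolloff_db_per_mm["H"], x$rolloff_db_per_mm["V"]))
  invisible(x)
}
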