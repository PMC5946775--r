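#' Remove the background spectrum
#'
#' Subtracts, per channel, the average spectrum over all A-scans of each
#' B-scan (the non-interferometric reference-arm background).  Idempotent.
#'
#' @param frame a `raw_frame`.
#' @return the frame with zero-mean columns per channel.
#' @export
subtract_background <- function(frame) {
  stopifnot_frame(frame)
  sub <- function(M) {
    if (length(dim(M)) == 3) {
      for (b in seq_len(dim(M)[3])) {
        M[, , b] <- M[, , b] - rowMeans(M[, , b, drop = FALSE], dims = 1)
      }
      M
    } else {
      M - rowMeans(M)
    }
  }
  frame$channel_H <- sub(frame$channel_H)
  frame$channel_V <- sub(frame$channel_V)
  frame
}

#' Inter-channel spectral calibration
#'
#' Mapping of the second (V) spectrometer's pixel coordinate onto the first
#' (H) spectrometer's: a spectral feature at H-pixel `x` sits at V-pixel
#' `m*x + c`.  `norm_curve` corrects the per-wavelength intensity difference
#' between channels (multiplies the aligned V channel).
#'
#' @param slope_m dimensionless slope (> 0).
#' @param intercept_c offset in pixels.
#' @param norm_curve per-pixel gain applied to V after remapping (scalar or
#'   vector of `n_pixels`), > 0 where source power is nonzero.
#' @return object of class `channel_calibration`.
#' @export
channel_calibration <- function(slope_m = 1, intercept_c = 0,
                                norm_curve = 1) {
  if (slope_m <= 0) stop("slope_m must be > 0")
  structure(list(slope_m = slope_m, intercept_c = intercept_c,
                 norm_curve = norm_curve),
            class = "channel_calibration")
}

#' Estimate the inter-channel calibration from spectral landmarks
#'
#' Fits `m, c` by least squares from >= 2 landmark positions identified in
#' both channels (e.g. color-filter absorption edges), and estimates the
#' per-pixel normalization curve as the smoothed ratio of the channel fringe
#' envelopes.
#'
#' @param frame a `raw_frame` (used for the envelope ratio).
#' @param landmarks_H,landmarks_V pixel positions (>= 2 each) of the same
#'   spectral features in channel H and channel V.
#' @param power_floor fraction of the peak envelope below which the
#'   normalization curve is clamped to 1 (no reliable ratio there).
#' @param smooth_frac running-mean window for the envelopes, as a fraction
#'   of `n_pixels`.
#' @return a [channel_calibration()].
#' @export
estimate_calibration <- function(frame, landmarks_H, landmarks_V,
                                 power_floor = 0.1, smooth_frac = 0.02) {
  stopifnot_frame(frame)
  if (length(landmarks_H) < 2 || length(landmarks_H) != length(landmarks_V))
    stop("need >= 2 landmarks identified in both channels")
  fit <- stats::lm.fit(cbind(1, landmarks_H), landmarks_V)
  c_hat <- fit$coefficients[1]
  m_hat <- fit$coefficients[2]
  H <- as.matrix(frame$channel_H)
  V <- as.matrix(frame$channel_V)
  n <- nrow(H)
  win <- max(3L, round(smooth_frac * n))
  # per-column fringe envelope via the analytic-signal magnitude (robust to
  # identical A-scans, unlike lateral-deviation estimates)
  env <- function(M) {
    e <- rowMeans(vapply(seq_len(ncol(M)), function(j)
      Mod(analytic_signal(M[, j] - mean(M[, j]))), numeric(n)))
    running_mean(e, win)
  }
  env_H <- env(H)
  # envelope of V evaluated on the remapped coordinate so the ratio is
  # formed between corresponding wavelengths
  xi <- m_hat * seq_len(n) + c_hat
  env_V <- env(V)
  env_Vr <- stats::approx(seq_len(n), env_V, xout = xi, rule = 2)$y
  norm_curve <- env_H / pmax(env_Vr, .Machine$double.eps)
  norm_curve[env_H < power_floor * max(env_H)] <- 1
  channel_calibration(unname(m_hat), unname(c_hat), norm_curve)
}

#' Align the V channel onto the H channel's spectral axis
#'
#' Resamples channel V at the pixel coordinate `m*x + c` (cubic
#' interpolation), zero-filling pixels whose source coordinate falls outside
#' the detector, then multiplies by the normalization curve.  Channel H is
#' untouched.
#'
#' @param frame a `raw_frame`.
#' @param calib a [channel_calibration()].
#' @param interp `"cubic"` (default) or `"linear"`.
#' @return the frame with channel V aligned and normalized.
#' @export
align_channels <- function(frame, calib, interp = c("cubic", "linear")) {
  stopifnot_frame(frame)
  interp <- match.arg(interp)
  V <- as.matrix(frame$channel_V)
  n <- nrow(V)
  xi <- calib$slope_m * seq_len(n) + calib$intercept_c
  Vr <- interp_columns(seq_len(n), V, xi, method = interp)
  frame$channel_V <- Vr * calib$norm_curve
  frame$meta$calibration <- calib
  frame
}

#' Resample spectra to be uniform in wavenumber k
#'
#' Spectra acquired on a uniform wavelength grid are interpolated onto a
#' uniform grid in `k = 2*pi/lambda` spanning
#' `[2*pi/lambda_max, 2*pi/lambda_min]` with the same number of samples, the
#' prerequisite for an undistorted FFT depth profile.
#'
#' @param frame a `raw_frame` (background-subtracted, channels aligned).
#' @param interp `"cubic"` (default) or `"linear"`.
#' @return object of class `kspace_frame` with `channel_H`, `channel_V` on
#'   the uniform `k_axis` (rad/nm) and inherited `meta`.
#' @export
resample_to_k <- function(frame, interp = c("cubic", "linear")) {
  stopifnot_frame(frame)
  interp <- match.arg(interp)
  wl <- frame$wavelength_nm
  if (any(diff(wl) <= 0)) stop("wavelength axis must be strictly increasing")
  k_px <- rev(2 * pi / wl)           # ascending in k
  n <- length(wl)
  k_axis <- seq(2 * pi / max(wl), 2 * pi / min(wl), length.out = n)
  res <- function(M) {
    M <- as.matrix(M)
    interp_columns(k_px, M[rev(seq_len(n)), , drop = FALSE], k_axis,
                   method = interp)
  }
  structure(list(channel_H = res(frame$channel_H),
                 channel_V = res(frame$channel_V),
                 k_axis = k_axis, meta = frame$meta,
                 analytic = FALSE),
            class = "kspace_frame")
}

#' @export
print.kspace_frame <- function(x, ...) {
  cat(sprintf("<kspace_frame> %d px x %d A-scans, k %.5f-%.5f rad/nm%s\n",
              nrow(x$channel_H), ncol(x$channel_H), min(x$k_axis),
              max(x$k_axis), if (isTRUE(x$analytic)) " (analytic)" else ""))
  invisible(x)
}

#' Fourier transform to a complex tomogram
#'
#' Per channel: take the complex analytic representation of the spectral
#' fringe (FFT half-spectrum method), multiply by `exp(i * Phi(k))` when a
#' dispersion model is given, Fourier transform along k and keep the
#' positive-depth half.  Depth sampling is `dz = pi / (N * dk)` (optical
#' path), so `z_axis` is in um from the zero-delay line.
#'
#' @param kframe a [resample_to_k()] result (real fringes, or analytic ones
#'   from [apply_dispersion()]).
#' @param model optional `dispersion_model` from [build_phase_curve()] /
#'   [optimize_dispersion()]; its k grid must match.
#' @param pad zero-padding factor (integer >= 1) applied in k before the
#'   transform for sub-bin PSF sampling; the physical depth range is
#'   unchanged, the z step divides by `pad`.
#' @return object of class `complex_tomogram` with complex matrices `A_H`,
#'   `A_V` (`N*pad/2 x n_ascans`), `z_axis_um`, and inherited `meta`.
#' @export
tomogram <- function(kframe, model = NULL, pad = 1L) {
  if (!inherits(kframe, "kspace_frame")) stop("expected a kspace_frame")
  pad <- as.integer(pad)
  if (pad < 1L) stop("pad must be >= 1")
  k_axis <- kframe$k_axis
  n <- length(k_axis)
  phase <- NULL
  if (!is.null(model)) {
    if (length(model$k_axis) != n ||
        max(abs(model$k_axis - k_axis)) > 1e-9 * max(abs(k_axis)))
      stop("dispersion model k grid does not match the frame")
    phase <- model$phase_curve
  }
  dk <- (max(k_axis) - min(k_axis)) / (n - 1)
  nfft <- n * pad
  dz_nm <- pi / (nfft * dk)
  nz <- nfft %/% 2L
  z_axis_um <- (seq_len(nz) - 1) * dz_nm / 1000

  tr <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0i, nz, ncol(M))
    for (j in seq_len(ncol(M))) {
      xa <- if (is.complex(M[, j])) M[, j] else analytic_signal(M[, j])
      if (!is.null(phase)) xa <- xa * exp(1i * phase)
      if (pad > 1L) xa <- c(xa, rep(0i, nfft - n))
      out[, j] <- stats::fft(xa)[seq_len(nz)]
    }
    out
  }
  meta <- kframe$meta
  meta$dispersion <- if (is.null(model)) NULL else
    model[c("coeffs", "k0", "bands_k")]
  structure(list(A_H = tr(kframe$channel_H), A_V = tr(kframe$channel_V),
                 z_axis_um = z_axis_um, meta = meta),
            class = "complex_tomogram")
}

#' @export
print.complex_tomogram <- function(x, ...) {
  cat(sprintf("<complex_tomogram> %d z-bins x %d A-scans, z 0-%.0f um\n",
              nrow(x$A_H), ncol(x$A_H), max(x$z_axis_um)))
  invisible(x)
}

#' Reflectivity image
#'
#' Per pixel, the sum of the squared channel amplitudes
#' `R = |A_H|^2 + |A_V|^2` -- invariant to the sample's retardance and axis
#' for polarization-preserving layers.  Pass a list of co-registered
#' tomograms to average multiple frames for speckle reduction.
#'
#' @param tomo a `complex_tomogram` or a list of them (averaged).
#' @return matrix of linear reflectivity (arbitrary units).
#' @export
reflectivity <- function(tomo) {
  if (inherits(tomo, "complex_tomogram")) tomo <- list(tomo)
  acc <- NULL
  for (t in tomo) {
    R <- Mod(t$A_H)^2 + Mod(t$A_V)^2
    acc <- if (is.null(acc)) R else acc + R
  }
  acc / length(tomo)
}

#' Mean noise floor of a reflectivity image
#'
#' Estimated as the mean linear reflectivity over the deepest `fraction` of
#' z-bins, where no sample signal is expected.
#'
#' @param intensity linear reflectivity matrix (z in rows).
#' @param fraction fraction of the deepest bins used (default 0.1).
#' @return scalar linear noise floor (>= smallest positive double).
#' @export
noise_floor <- function(intensity, fraction = 0.1) {
  nz <- nrow(intensity)
  sel <- seq.int(max(1L, nz - ceiling(fraction * nz) + 1L), nz)
  max(mean(intensity[sel, , drop = FALSE]), .Machine$double.xmin)
}

#' Reflectivity in decibels
#'
#' `10*log10(R / reference)`; the reference defaults to the frame's mean
#' noise floor so that intensity thresholds can be expressed as "dB above
#' the mean noise level".
#'
#' @param tomo a `complex_tomogram`, list of them, or a linear reflectivity
#'   matrix.
#' @param reference `"noise_floor"`, `"max"`, or a numeric linear reference.
#' @param floor_fraction passed to [noise_floor()].
#' @return matrix of dB values.
#' @export
reflectivity_db <- function(tomo, reference = "noise_floor",
                            floor_fraction = 0.1) {
  R <- if (is.matrix(tomo) && !is.complex(tomo)) tomo else reflectivity(tomo)
  ref <- if (is.numeric(reference)) reference
  else switch(reference,
              noise_floor = noise_floor(R, floor_fraction),
              max = max(R),
              stop("unknown reference"))
  10 * log10(pmax(R, .Machine$double.xmin) / ref)
}
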