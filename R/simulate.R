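#' Imposed dispersion for the simulator
#'
#' Describes the wavelength-dependent phase distortion the simulator adds to
#' the fringe phase: within band i (in wavelength), the term
#' `a2[i]*(k - k0)^2 + a3[i]*(k - k0)^3` (radians, k in rad/nm).  Broadband
#' systems show coefficients that vary with wavelength by up to an order of
#' magnitude, which is what a multi-band correction must undo.
#'
#' @param bands_nm matrix/data frame with columns (lo, hi) in nm; bands must
#'   tile the detected range without overlap.
#' @param a2,a3 per-band coefficients (rad per (rad/nm)^2 and (rad/nm)^3).
#' @param k0 reference wavenumber (rad/nm); default the center of the k range
#'   implied by the band limits.
#' @return object of class `dispersion_spec`.
#' @export
dispersion_spec <- function(bands_nm, a2, a3, k0 = NULL) {
  bands_nm <- as.matrix(bands_nm)
  o <- order(bands_nm[, 1])
  bands_nm <- bands_nm[o, , drop = FALSE]
  a2 <- a2[o]; a3 <- a3[o]
  if (nrow(bands_nm) > 1 &&
      any(abs(bands_nm[-nrow(bands_nm), 2] - bands_nm[-1, 1]) > 1e-9))
    stop("bands must tile the spectral range without gaps or overlap")
  if (length(a2) != nrow(bands_nm) || length(a3) != nrow(bands_nm))
    stop("one (a2, a3) pair per band required")
  if (is.null(k0)) {
    k0 <- (2 * pi / min(bands_nm) + 2 * pi / max(bands_nm)) / 2
  }
  structure(list(bands_nm = bands_nm, a2 = a2, a3 = a3, k0 = k0),
            class = "dispersion_spec")
}

# imposed phase (radians) per pixel given per-pixel wavelength
#' @noRd
imposed_phase <- function(spec, wavelength_nm) {
  k <- 2 * pi / wavelength_nm
  phase <- rep(NA_real_, length(k))
  for (i in seq_len(nrow(spec$bands_nm))) {
    sel <- wavelength_nm >= spec$bands_nm[i, 1] - 1e-9 &
      wavelength_nm <= spec$bands_nm[i, 2] + 1e-9
    dk <- k[sel] - spec$k0
    phase[sel] <- spec$a2[i] * dk^2 + spec$a3[i] * dk^3
  }
  if (anyNA(phase)) stop("dispersion bands do not cover the spectrum")
  phase
}

#' Simulate a dual-channel spectral interferogram
#'
#' Forward model of polarization-sensitive spectral-domain OCT detection.
#' The sample is illuminated with circularly polarized light; each layer
#' contributes interference fringes to the horizontally (H) and vertically
#' (V) polarized spectrometer channels with envelopes
#' `S(k) * sqrt(R) * cos(delta)` and `S(k) * sqrt(R) * sin(delta)`
#' respectively, modulating `cos(2 k z + phi)`; the V channel carries an
#' axis-dependent phase offset `180 - 2*theta` degrees (two-channel PS-OCT
#' convention).  Optional imposed dispersion adds a per-band polynomial
#' phase; a Gaussian spectrometer pixel response attenuates fringe
#' visibility with depth (sensitivity roll-off); seeded shot and read noise
#' are added per pixel.  Depolarizing layers draw an independent uniform
#' retardance in \[0, 90\] deg and a uniform axis per A-scan.
#'
#' @param sample a [layered_sample()].
#' @param source a [make_source_spectrum()] on the same grid.
#' @param config an [acquisition_config()].
#' @param dispersion optional [dispersion_spec()].
#' @return object of class `raw_frame` with fields `channel_H`, `channel_V`
#'   (`n_pixels x n_ascans` matrices, or `x n_bscans` arrays), the
#'   `wavelength_nm` axis and `meta` (config, sample label, seed).
#' @export
simulate_frame <- function(sample, source, config, dispersion = NULL) {
  if (!inherits(sample, "layered_sample")) stop("sample must be a layered_sample")
  if (length(sample$layers) == 0) stop("sample is empty")
  wl <- wavelength_axis(config)
  if (length(source$power) != length(wl) ||
      max(abs(source$wavelength_nm - wl)) > 1e-9)
    stop("source spectrum grid does not match the acquisition grid")
  zmax <- max_depth_um(config)
  all_layers <- c(sample$layers,
                  unlist(lapply(sample$variants, `[[`, "layers"),
                         recursive = FALSE))
  depths <- vapply(all_layers, function(l) l$depth_um, numeric(1))
  if (any(depths >= zmax))
    stop(sprintf(
      "layer at %.0f um beyond the %.0f um depth range: signal would alias",
      max(depths), zmax))

  k <- 2 * pi / wl
  S <- source$power
  phase_d <- if (!is.null(dispersion)) imposed_phase(dispersion, wl) else 0
  n <- config$n_pixels
  na <- config$n_ascans
  nb <- config$n_bscans
  set.seed(config$seed)

  mk_bscan <- function() {
    H <- matrix(0, n, na)
    V <- matrix(0, n, na)
    for (a in seq_len(na)) {
      jitter_nm <- if (config$depth_jitter_um > 0)
        stats::rnorm(1, 0, config$depth_jitter_um) * 1000 else 0
      for (ly in layers_at(sample, a)) {
        if (isTRUE(ly$depolarizing)) {
          delta <- deg2rad(stats::runif(1, 0, 90))
          theta <- deg2rad(stats::runif(1, 0, 180))
        } else {
          delta <- if (is.na(ly$retardance_ref_nm))
            deg2rad(ly$retardance_deg)
          else
            deg2rad(ly$retardance_deg * ly$retardance_ref_nm / wl)
          theta <- deg2rad(ly$axis_deg)
        }
        w_chroma <- stats::approx(c(460, 550, 640), ly$chroma,
                                  xout = wl, rule = 2)$y
        z_nm <- ly$depth_um * 1000 + jitter_nm
        vis <- if (config$pixel_mtf_width > 0)
          exp(-2 * (config$pixel_mtf_width * z_nm)^2) else 1
        env <- config$amplitude_scale * S *
          sqrt(ly$reflectivity * w_chroma) * vis
        carrier <- 2 * k * z_nm + phase_d
        H[, a] <- H[, a] + env * cos(delta) * cos(carrier)
        V[, a] <- V[, a] + env * sin(delta) * cos(carrier + pi - 2 * theta)
      }
    }
    dc <- config$dc_level * config$amplitude_scale * S
    H <- H + dc
    V <- V + dc
    if (config$read_std > 0 || config$shot_scale > 0) {
      noisify <- function(M) {
        M + stats::rnorm(length(M), 0, config$read_std) +
          stats::rnorm(length(M)) * sqrt(config$shot_scale * pmax(M, 0))
      }
      H <- noisify(H)
      V <- noisify(V)
    }
    list(H = H, V = V)
  }

  if (nb == 1L) {
    b <- mk_bscan()
    ch_H <- b$H; ch_V <- b$V
  } else {
    ch_H <- array(0, c(n, na, nb))
    ch_V <- array(0, c(n, na, nb))
    for (bi in seq_len(nb)) {
      b <- mk_bscan()
      ch_H[, , bi] <- b$H
      ch_V[, , bi] <- b$V
    }
  }
  structure(list(channel_H = ch_H, channel_V = ch_V,
                 wavelength_nm = wl,
                 meta = list(config = config, label = sample$label,
                             seed = config$seed)),
            class = "raw_frame")
}

#' @export
print.raw_frame <- function(x, ...) {
  d <- dim(x$channel_H)
  cat(sprintf("<raw_frame> '%s', %s px x ascans%s\n",
              x$meta$label %||% "", paste(d, collapse = " x "),
              if (length(d) == 3) " x bscans" else ""))
  invisible(x)
}
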