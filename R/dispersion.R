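#' Default band boundaries for multi-band dispersion compensation
#'
#' Splits the processing grid into `n` contiguous bands, by default into
#' equal thirds of the k range (equal information per band on the uniform-k
#' grid); equal thirds of the wavelength range are selectable.
#'
#' @param k_axis uniform k grid (rad/nm).
#' @param n number of bands (1 or 3 typical).
#' @param by `"k"` or `"lambda"`.
#' @return an `n x 2` matrix of (k_lo, k_hi) tiling the grid.
#' @export
dispersion_bands <- function(k_axis, n = 3L, by = c("k", "lambda")) {
  by <- match.arg(by)
  k_lo <- min(k_axis); k_hi <- max(k_axis)
  edges <- if (by == "k") {
    seq(k_lo, k_hi, length.out = n + 1)
  } else {
    wl_edges <- seq(2 * pi / k_hi, 2 * pi / k_lo, length.out = n + 1)
    rev(2 * pi / wl_edges)
  }
  cbind(lo = edges[-(n + 1)], hi = edges[-1])
}

#' Build a multi-band phase-correction model
#'
#' Evaluates, per band i, the phase-correction polynomial
#' `Phi(k) = a1_i*(k - k0) - a2_i*(k - k0)^2 - a3_i*(k - k0)^3`, concatenates
#' the per-band curves at the band edges, and smooths the concatenated curve
#' (local cubic / Savitzky-Golay) so that no discontinuity or kink remains
#' at the seams.  The per-band linear term a1 compensates the first-order
#' dispersion introduced by the concatenation so the image appears at the
#' same depth in every band.
#'
#' @param k_axis uniform k grid (rad/nm).
#' @param bands `B x 2` matrix of (k_lo, k_hi) covering the grid (B = 1 or 3
#'   typical), e.g. from [dispersion_bands()].
#' @param coeffs `B x 3` matrix of (a1, a2, a3) per band.
#' @param k0 reference wavenumber (rad/nm), inside the grid; default grid
#'   center.
#' @param smooth_frac smoothing window as a fraction of the number of pixels
#'   (default 0.05); ignored for single-band models (no seams).
#' @return object of class `dispersion_model` with the evaluated
#'   `phase_curve` (radians per k pixel).
#' @export
build_phase_curve <- function(k_axis, bands, coeffs, k0 = NULL,
                              smooth_frac = 0.05) {
  bands <- as.matrix(bands)
  coeffs <- matrix(as.numeric(coeffs), ncol = 3)
  if (nrow(coeffs) != nrow(bands)) stop("one (a1, a2, a3) row per band")
  if (is.null(k0)) k0 <- (min(k_axis) + max(k_axis)) / 2
  if (k0 < min(k_axis) || k0 > max(k_axis)) stop("k0 outside the k grid")
  o <- order(bands[, 1])
  bands <- bands[o, , drop = FALSE]
  coeffs <- coeffs[o, , drop = FALSE]
  tol <- 1e-9 * max(abs(k_axis))
  if (bands[1, 1] > min(k_axis) + tol ||
      bands[nrow(bands), 2] < max(k_axis) - tol)
    stop("bands do not cover the k grid")
  band_of <- rep(NA_integer_, length(k_axis))
  for (i in seq_len(nrow(bands))) {
    sel <- k_axis >= bands[i, 1] - tol & k_axis <= bands[i, 2] + tol
    band_of[sel & is.na(band_of)] <- i
  }
  if (anyNA(band_of)) stop("bands do not cover the k grid")
  dk0 <- k_axis - k0
  a1 <- coeffs[band_of, 1]; a2 <- coeffs[band_of, 2]; a3 <- coeffs[band_of, 3]
  phase <- a1 * dk0 - a2 * dk0^2 - a3 * dk0^3
  win <- 0L
  if (nrow(bands) > 1 && smooth_frac > 0) {
    win <- max(5L, round(smooth_frac * length(k_axis)))
    phase <- sg_smooth(phase, win)
  }
  if (any(abs(diff(phase)) >= pi))
    warning("phase curve steps by >= pi between pixels; ",
            "coefficients are likely beyond the grid's Nyquist limit")
  structure(list(k_axis = k_axis, bands_k = bands, coeffs = coeffs,
                 k0 = k0, phase_curve = phase, smooth_window = win),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d band(s), k0 = %.5f rad/nm\n",
              nrow(x$bands_k), x$k0))
  for (i in seq_len(nrow(x$coeffs)))
    cat(sprintf("  band %d [%.5f, %.5f]: a1 = %.4g, a2 = %.4g, a3 = %.4g\n",
                i, x$bands_k[i, 1], x$bands_k[i, 2],
                x$coeffs[i, 1], x$coeffs[i, 2], x$coeffs[i, 3]))
  invisible(x)
}

#' Apply a phase-correction model to k-space fringes
#'
#' Converts each channel to its complex analytic representation and
#' multiplies by `exp(i * Phi(k))`.  A phase-only operator: per-pixel
#' spectral magnitude is unchanged.
#'
#' @param kframe a [resample_to_k()] result.
#' @param model a `dispersion_model` on the same k grid.
#' @return the kframe with complex (analytic) phase-corrected channels.
#' @export
apply_dispersion <- function(kframe, model) {
  if (!inherits(kframe, "kspace_frame")) stop("expected a kspace_frame")
  n <- length(kframe$k_axis)
  if (length(model$k_axis) != n ||
      max(abs(model$k_axis - kframe$k_axis)) > 1e-9 * max(abs(kframe$k_axis)))
    stop("dispersion model k grid does not match the frame")
  ph <- exp(1i * model$phase_curve)
  corr <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0i, nrow(M), ncol(M))
    for (j in seq_len(ncol(M))) {
      xa <- if (is.complex(M[, j])) M[, j] else analytic_signal(M[, j])
      out[, j] <- xa * ph
    }
    out
  }
  kframe$channel_H <- corr(kframe$channel_H)
  kframe$channel_V <- corr(kframe$channel_V)
  kframe$analytic <- TRUE
  kframe
}

# band-limited A-scan intensity used by the sharpness search
#' @noRd
band_ascan <- function(xa, sel, extra_phase, nfft) {
  y <- rep(0i, length(xa))
  y[sel] <- xa[sel] * exp(1i * extra_phase[sel])
  y <- c(y, rep(0i, nfft - length(xa)))
  A <- stats::fft(y)[seq_len(nfft %/% 2L)]
  Mod(A)^2
}

#' Automatic dispersion-coefficient search
#'
#' Replaces manual by-eye tuning of the correction constants: per band, a
#' deterministic Nelder-Mead downhill-simplex search over (a2, a3) seeded at
#' zero minimizes the Shannon entropy of the normalized band-limited
#' reflectivity A-scan (low entropy = sharp peaks); afterwards the per-band
#' a1 terms are set so that the strongest reflector appears at the same
#' depth in every band's reconstruction.
#'
#' @param kframe a [resample_to_k()] frame containing at least one
#'   reflector (background-subtracted).
#' @param n_bands number of bands (1 or 3).
#' @param bands optional explicit band matrix; default [dispersion_bands()].
#' @param ascan A-scan index used for the objective; default the column with
#'   the largest fringe energy.
#' @param k0 reference wavenumber; default grid center.
#' @param a2_max,a3_max search bounds (penalty beyond); defaults scale with
#'   the grid so that the bound corresponds to ~50 rad of edge phase.
#' @param maxit maximum simplex iterations per band.
#' @param smooth_frac passed to [build_phase_curve()].
#' @param pad zero-padding factor for the objective's reconstructions.
#' @return a `dispersion_model` with extra fields `objective` (per band) and
#'   `converged` (logical per band; best-so-far returned with a warning on
#'   non-convergence).
#' @export
optimize_dispersion <- function(kframe, n_bands = 3L, bands = NULL,
                                ascan = NULL, k0 = NULL,
                                a2_max = NULL, a3_max = NULL,
                                maxit = 400L, smooth_frac = 0.05,
                                pad = 2L) {
  if (!inherits(kframe, "kspace_frame")) stop("expected a kspace_frame")
  k_axis <- kframe$k_axis
  n <- length(k_axis)
  if (is.null(bands)) bands <- dispersion_bands(k_axis, n_bands)
  if (is.null(k0)) k0 <- (min(k_axis) + max(k_axis)) / 2
  H <- as.matrix(kframe$channel_H)
  if (is.null(ascan)) ascan <- which.max(colSums(Mod(H)^2))
  xa <- if (is.complex(H[, ascan])) H[, ascan] else
    analytic_signal(H[, ascan])
  dk0 <- k_axis - k0
  half <- (max(k_axis) - min(k_axis)) / 2
  if (is.null(a2_max)) a2_max <- 50 / half^2
  if (is.null(a3_max)) a3_max <- 50 / half^3
  scale2 <- 1 / half^2
  scale3 <- 1 / half^3
  nfft <- n * as.integer(pad)
  tol <- 1e-9 * max(abs(k_axis))

  B <- nrow(bands)
  coeffs <- matrix(0, B, 3)
  objective <- numeric(B)
  converged <- logical(B)
  peaks <- numeric(B)
  energy <- numeric(B)
  dz_nm <- pi / (nfft * (max(k_axis) - min(k_axis)) / (n - 1))

  for (i in seq_len(B)) {
    sel <- k_axis >= bands[i, 1] - tol & k_axis <= bands[i, 2] + tol
    obj <- function(p) {
      a2 <- p[1]; a3 <- p[2]
      if (abs(a2) > a2_max || abs(a3) > a3_max) return(1e6)
      profile_entropy(band_ascan(xa, sel, -a2 * dk0^2 - a3 * dk0^3, nfft))
    }
    # deterministic coarse scan to escape the many local optima of the
    # sharpness landscape under strong dispersion, then simplex refinement
    a2_grid <- seq(-a2_max, a2_max, length.out = 41L)
    best2 <- a2_grid[which.min(vapply(a2_grid, function(a) obj(c(a, 0)),
                                      numeric(1)))]
    a3_grid <- seq(-a3_max, a3_max, length.out = 41L)
    best3 <- a3_grid[which.min(vapply(a3_grid, function(a) obj(c(best2, a)),
                                      numeric(1)))]
    fit <- stats::optim(c(best2, best3), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = c(scale2, scale3)))
    coeffs[i, 2:3] <- fit$par
    objective[i] <- -fit$value
    converged[i] <- fit$convergence == 0L
    prof <- band_ascan(xa, sel, -fit$par[1] * dk0^2 - fit$par[2] * dk0^3,
                       nfft)
    p <- which.max(prof)
    # parabolic sub-bin peak interpolation
    if (p > 1 && p < length(prof)) {
      d <- (prof[p - 1] - prof[p + 1]) /
        (2 * (prof[p - 1] - 2 * prof[p] + prof[p + 1]))
      peaks[i] <- (p - 1 + d) * dz_nm
    } else peaks[i] <- (p - 1) * dz_nm
    energy[i] <- max(prof)
  }
  if (!all(converged))
    warning("coefficient search did not converge in every band; ",
            "returning best-so-far")
  ref_band <- which.max(energy)
  # a1 shifts the band's peak by a1/2 in optical path; align to the
  # strongest band's depth
  coeffs[, 1] <- 2 * (peaks[ref_band] - peaks)
  model <- build_phase_curve(k_axis, bands, coeffs, k0, smooth_frac)
  model$objective <- objective
  model$converged <- converged
  model
}

#' Round-trip dispersion coefficients through JSON
#'
#' @param model a `dispersion_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_dispersion_json <- function(model, path) {
  jsonlite::write_json(list(
    k0 = model$k0,
    bands_k = unname(model$bands_k),
    coeffs = unname(model$coeffs),
    smooth_window = model$smooth_window
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dispersion_json
#' @param k_axis k grid on which to re-evaluate the phase curve.
#' @export
read_dispersion_json <- function(path, k_axis) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- matrix(as.numeric(j$bands_k), ncol = 2)
  coeffs <- matrix(as.numeric(j$coeffs), ncol = 3)
  smooth_frac <- if (j$smooth_window > 0)
    j$smooth_window / length(k_axis) else 0
  build_phase_curve(k_axis, bands, coeffs, j$k0, smooth_frac)
}
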