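# shared simulation shortcuts for the test suite; all fixtures are built in
# code, nothing is read from disk

quiet_cfg <- function(n_pixels = 2048, n_ascans = 1, seed = 1, ...) {
  acquisition_config(n_pixels = n_pixels, n_ascans = n_ascans,
                     dc_level = 0, seed = seed, ...)
}

gauss_src <- function(cfg, center = 550, fwhm = 150) {
  make_source_spectrum(cfg, "gaussian", center_nm = center, fwhm_nm = fwhm)
}

# noiseless single-reflector k-space frame
mirror_kframe <- function(depth_um = 150, cfg = quiet_cfg(),
                          src = gauss_src(cfg), retardance_deg = 0,
                          axis_deg = 0, dispersion = NULL) {
  ph <- make_phantom("mirror", depth_um = depth_um,
                     retardance_deg = retardance_deg, axis_deg = axis_deg)
  resample_to_k(simulate_frame(ph, src, cfg, dispersion))
}

# retardation (deg) at the brightest pixel of an A-scan
delta_at_peak <- function(tomo, ascan = 1) {
  R <- Mod(tomo$A_H[, ascan])^2 + Mod(tomo$A_V[, ascan])^2
  i <- which.max(R)
  atan2(Mod(tomo$A_V[i, ascan]), Mod(tomo$A_H[i, ascan])) * 180 / pi
}

# exact k-space coherence length: FWHM (um) of the magnitude PSF of a
# Gaussian power spectrum specified by its wavelength FWHM
coherence_fwhm_um <- function(lambda0, dlambda) {
  dk <- 2 * pi / (lambda0 - dlambda / 2) - 2 * pi / (lambda0 + dlambda / 2)
  4 * log(2) / dk / 1000
}

analytic_env <- function(x) visoct:::analytic_signal(x)

layers_at_public <- function(sample, ascan) visoct:::layers_at(sample, ascan)

# smooth x10 coefficient ramp for the multi-band dispersion experiment:
# a2 and a3 grow quadratically in k from the band center to x10 at the
# spectrum edges, sampled as 24 narrow constant-coefficient bands
ramp_dispersion_spec <- function(k_axis, a2_scale = 3e5, a3_scale = 4.5e7,
                                 n_gen = 24) {
  k0 <- mean(range(k_axis))
  bk <- dispersion_bands(k_axis, n_gen)
  xc <- (bk[, 1] + bk[, 2]) / 2 - k0
  prof <- 1 + 9 * (xc / max(abs(xc)))^2
  bands_nm <- cbind(2 * pi / bk[n_gen:1, 2], 2 * pi / bk[n_gen:1, 1])
  dispersion_spec(bands_nm, a2 = rev(a2_scale * prof),
                  a3 = rev(a3_scale * prof), k0 = k0)
}
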