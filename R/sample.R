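#' Single reflecting layer of a phantom
#'
#' A discrete reflector at one optical-path depth.  Polarization is described
#' by a single-pass retardance and fast-axis orientation; `depolarizing`
#' layers instead draw an independent random retardance and axis per A-scan
#' (speckle-scale randomization, as produced by dense melanin granules).
#'
#' @param depth_um optical path from the zero-delay line, um (> 0).
#' @param reflectivity amplitude-squared reflectance fraction in (0, 1].
#' @param retardance_deg single-pass retardance at the reference wavelength,
#'   degrees in \[0, 90\].
#' @param retardance_ref_nm reference wavelength (nm) at which
#'   `retardance_deg` is specified; the simulator scales the retardance as
#'   `ref / lambda` (a waveplate's 1/lambda dispersion).  `NA` (default)
#'   makes the layer achromatic (constant retardance at all wavelengths).
#' @param axis_deg fast-axis orientation, degrees.
#' @param depolarizing logical.
#' @param chroma relative scattering weights at (460, 550, 640) nm,
#'   interpolated across the spectrum and applied to the reflectivity.
#' @param label free text.
#' @return object of class `oct_layer`.
#' @export
layer <- function(depth_um, reflectivity, retardance_deg = 0,
                  retardance_ref_nm = NA_real_, axis_deg = 0,
                  depolarizing = FALSE, chroma = c(1, 1, 1), label = "") {
  if (depth_um <= 0) stop("depth_um must be > 0")
  if (reflectivity <= 0 || reflectivity > 1)
    stop("reflectivity must be in (0, 1]")
  if (retardance_deg < 0 || retardance_deg > 90)
    stop("retardance_deg must be in [0, 90]")
  if (any(chroma < 0) || length(chroma) != 3)
    stop("chroma must be 3 nonnegative weights at (460, 550, 640) nm")
  structure(list(depth_um = depth_um, reflectivity = reflectivity,
                 retardance_deg = retardance_deg,
                 retardance_ref_nm = retardance_ref_nm,
                 axis_deg = axis_deg, depolarizing = depolarizing,
                 chroma = chroma, label = label),
            class = "oct_layer")
}

#' Layered phantom
#'
#' An ordered set of [layer()]s, optionally with lateral variants: A-scan
#' ranges over which a different layer list applies (e.g. a focal lesion).
#'
#' @param layers list of [layer()], depths strictly increasing.
#' @param label free text.
#' @param variants optional list of `list(ascans = <integer vector>,
#'   layers = <list of layer>)` entries replacing the base layer list for
#'   those A-scan indices.
#' @return object of class `layered_sample`.
#' @export
layered_sample <- function(layers, label = "", variants = NULL) {
  if (length(layers) == 0) stop("a sample needs at least one layer")
  depths <- vapply(layers, function(l) l$depth_um, numeric(1))
  if (any(diff(depths) <= 0))
    stop("layer depths must be strictly increasing")
  if (sum(vapply(layers, function(l) isTRUE(l$depolarizing), logical(1))) > 1)
    stop("at most one depolarizing band per phantom")
  structure(list(layers = layers, label = label, variants = variants),
            class = "layered_sample")
}

#' @export
print.layered_sample <- function(x, ...) {
  cat(sprintf("<layered_sample> '%s', %d layers, %g-%g um\n", x$label,
              length(x$layers), x$layers[[1]]$depth_um,
              x$layers[[length(x$layers)]]$depth_um))
  invisible(x)
}

# layers applying to one A-scan (resolving lateral variants)
#' @noRd
layers_at <- function(sample, ascan) {
  if (!is.null(sample$variants)) {
    for (v in sample$variants) {
      if (ascan %in% v$ascans) return(v$layers)
    }
  }
  sample$layers
}

#' Folded retardance of an ideal waveplate
#'
#' Single-pass retardance of a waveplate at wavelength `lambda` follows
#' `delta(lambda) = 90 * design_nm / lambda` degrees (quarter wave at the
#' design wavelength, 1/lambda dispersion).  An amplitude-ratio detection
#' `arctan(|A_V| / |A_H|)` cannot distinguish `delta` from `180 - delta` or
#' `-delta`, so the reported value is folded into \[0, 90\] degrees:
#' `delta_meas = arctan(|sin delta| / |cos delta|)`.
#'
#' @param wavelength_nm measurement wavelength(s), nm.
#' @param design_nm design wavelength of the quarter-wave plate, nm.
#' @return folded retardance in degrees, in \[0, 90\]; vectorized.
#' @export
qwp_fold <- function(wavelength_nm, design_nm) {
  if (any(wavelength_nm <= 0) || any(design_nm <= 0))
    stop("wavelengths must be > 0")
  delta <- deg2rad(90 * design_nm / wavelength_nm)
  rad2deg(atan2(abs(sin(delta)), abs(cos(delta))))
}

#' Built-in phantom presets
#'
#' @param preset one of:
#'   * `"mirror"`: a single polarization-preserving reflector,
#'   * `"qwp1300"`: quarter-wave plate designed for 1300 nm on a mirror
#'     (retardance 90 deg referenced to 1300 nm),
#'   * `"retina"`: a 12-layer murine-retina-like stack (< 300 um total)
#'     with a depolarizing RPE band,
#'   * `"retina_lesion"`: the retina stack plus a focal hyperreflective
#'     structure elevated above the RPE over a lateral footprint,
#'   * `"vessel"`: retina stack with a red-weighted chromatic layer
#'     (blood backscatters more at long wavelengths).
#' @param depth_um depth of the reflector for `"mirror"`/`"qwp1300"`.
#' @param reflectivity reflectivity for `"mirror"`/`"qwp1300"`.
#' @param retardance_deg retardance for `"mirror"` (achromatic), default 0.
#' @param axis_deg fast-axis orientation for `"mirror"`/`"qwp1300"`.
#' @param lesion_height_um lesion elevation above the RPE top surface, um.
#' @param lesion_ascans A-scan indices of the lesion footprint (default the
#'   middle third of `n_ascans`).
#' @param n_ascans number of A-scans (used to default `lesion_ascans`).
#' @return a [layered_sample()].
#' @export
make_phantom <- function(preset = c("mirror", "qwp1300", "retina",
                                    "retina_lesion", "vessel"),
                         depth_um = 200, reflectivity = 1,
                         retardance_deg = 0, axis_deg = 0,
                         lesion_height_um = 30, lesion_ascans = NULL,
                         n_ascans = 512L) {
  preset <- match.arg(preset)
  retina_layers <- function() list(
    layer(60,  0.050, label = "RNFL"),
    layer(70,  0.020, label = "GCL"),
    layer(85,  0.030, label = "IPL"),
    layer(105, 0.015, label = "INL"),
    layer(120, 0.030, label = "OPL"),
    layer(140, 0.008, label = "ONL"),
    layer(165, 0.040, label = "ELM"),
    layer(180, 0.060, label = "IS/OS"),
    layer(195, 0.030, label = "OS"),
    layer(205, 0.035, label = "IZ"),
    layer(260, 0.060, depolarizing = TRUE, label = "RPE"),
    layer(270, 0.020, label = "BM")
  )
  switch(preset,
    mirror = layered_sample(
      list(layer(depth_um, reflectivity, retardance_deg = retardance_deg,
                 axis_deg = axis_deg, label = "mirror")),
      label = "mirror"),
    qwp1300 = layered_sample(
      list(layer(depth_um, reflectivity, retardance_deg = 90,
                 retardance_ref_nm = 1300, axis_deg = axis_deg,
                 label = "QWP1300+mirror")),
      label = "qwp1300"),
    retina = layered_sample(retina_layers(), label = "retina"),
    retina_lesion = {
      base <- retina_layers()
      rpe_depth <- 260
      lesion <- layer(rpe_depth - lesion_height_um, 0.08, label = "lesion")
      with_lesion <- c(base[1:10], list(lesion), base[11:12])
      if (is.null(lesion_ascans)) {
        third <- max(1L, n_ascans %/% 3L)
        lesion_ascans <- seq.int(third + 1L, min(2L * third, n_ascans))
      }
      layered_sample(base, label = "retina_lesion",
                     variants = list(list(ascans = lesion_ascans,
                                          layers = with_lesion)))
    },
    vessel = {
      base <- retina_layers()
      ves <- layer(95, 0.05, chroma = c(0.15, 0.3, 1), label = "vessel")
      with_vessel <- c(base[1:3], list(ves), base[4:12])
      layered_sample(with_vessel, label = "vessel")
    })
}
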