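#' Gaussian spectral window for a target axial resolution
#'
#' Solves the Gaussian window width in k from the coherence-length relation
#' `FWHM_z(air) = 4*ln(2) / Delta_k_FWHM`, with the air-path width obtained
#' from the tissue target as `target * n_tissue`.  Windowing is always
#' performed in k-space so that the axial resolution is the same for every
#' band center.
#'
#' @param center_nm window center wavelength (nm); defaults 460 (blue),
#'   550 (green), 640 (red) are the true-color band centers.
#' @param target_tissue_um target axial resolution in retinal tissue, um.
#' @param n_tissue tissue group refractive index (default 1.37).
#' @param role optional `"red"`, `"green"` or `"blue"` tag.
#' @return object of class `band_spec` with `center_nm`, `center_k`
#'   (rad/nm), `fwhm_k` (rad/nm, FWHM of the window) and the targets.
#' @export
window_for_resolution <- function(center_nm, target_tissue_um = 4,
                                  n_tissue = 1.37, role = NULL) {
  if (target_tissue_um <= 0) stop("target resolution must be > 0")
  fwhm_z_air_nm <- target_tissue_um * n_tissue * 1000
  fwhm_k <- 4 * log(2) / fwhm_z_air_nm
  structure(list(center_nm = center_nm, center_k = 2 * pi / center_nm,
                 fwhm_k = fwhm_k, target_tissue_um = target_tissue_um,
                 n_tissue = n_tissue, role = role),
            class = "band_spec")
}

# Gaussian window values on a k grid
#' @noRd
band_window <- function(band, k_axis) {
  exp(-4 * log(2) * ((k_axis - band$center_k) / band$fwhm_k)^2)
}

#' Band-limited (spectroscopic) reconstruction
#'
#' Multiplies the k-space fringes by a Gaussian window (after any dispersion
#' correction phase) and Fourier transforms, yielding the complex tomogram of
#' one spectroscopic channel; use [reflectivity()] for the band intensity
#' image or [retardation()] for spectrally resolved retardation.
#'
#' @param kframe a [resample_to_k()] frame.
#' @param band a [window_for_resolution()] spec, or `NULL` for the full band.
#' @param model optional `dispersion_model`.
#' @param pad zero-padding factor (see [tomogram()]).
#' @param max_clip maximum tolerated fraction of window energy falling
#'   outside the k grid (default 0.01); exceeded -> error.
#' @return a `complex_tomogram` for that band.
#' @export
band_reconstruct <- function(kframe, band, model = NULL, pad = 1L,
                             max_clip = 0.01) {
  if (!inherits(kframe, "kspace_frame")) stop("expected a kspace_frame")
  if (is.null(band)) return(tomogram(kframe, model, pad))
  k_axis <- kframe$k_axis
  if (band$center_k < min(k_axis) || band$center_k > max(k_axis))
    stop("band center outside the spectral range")
  w <- band_window(band, k_axis)
  # energy clipped by the finite grid, relative to the analytic window
  dk <- (max(k_axis) - min(k_axis)) / (length(k_axis) - 1)
  total <- band$fwhm_k / 2 * sqrt(pi / (2 * log(2)))  # integral of w^2 / dk
  clipped <- 1 - sum(w^2) * dk / total
  if (clipped > max_clip)
    stop(sprintf("window clipped by the grid edge: %.1f%% of its energy lost",
                 100 * clipped))
  win <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0i, nrow(M), ncol(M))
    for (j in seq_len(ncol(M))) {
      xa <- if (is.complex(M[, j])) M[, j] else analytic_signal(M[, j])
      out[, j] <- xa * w
    }
    out
  }
  kf <- kframe
  if (!is.null(model)) {
    kf <- apply_dispersion(kf, model)
    model <- NULL
  }
  kf$channel_H <- win(kf$channel_H)
  kf$channel_V <- win(kf$channel_V)
  kf$analytic <- TRUE
  out <- tomogram(kf, NULL, pad)
  out$meta$band <- band[c("center_nm", "fwhm_k", "role")]
  out
}

#' Compose a true-color RGB image from three band images
#'
#' Each wavelength channel is smoothed by a rectangular mean filter (3
#' lateral x 2 axial pixels, reducing the wavelength-dependent speckle),
#' normalized by histogram shape (quantile-matched to the green channel's
#' intensity distribution so relative local contrast is preserved), scaled
#' by the green channel's near-maximum, and stacked into an RGB image
#' clipped to \[0, 1\].
#'
#' @param red,green,blue co-registered linear band intensity images
#'   (z in rows, lateral in columns), e.g. `reflectivity(band_reconstruct(...))`.
#' @param smooth apply the 3 x 2 mean filter (default TRUE).
#' @param normalize `"match"` (histogram matching, default) or `"none"`.
#' @return object of class `true_color_image`: array `rgb`
#'   (nz x nx x 3, in \[0, 1\]) and `provenance`.
#' @export
true_color <- function(red, green, blue, smooth = TRUE,
                       normalize = c("match", "none")) {
  normalize <- match.arg(normalize)
  if (!all(dim(red) == dim(green)) || !all(dim(green) == dim(blue)))
    stop("band images must share the same shape")
  chans <- list(R = red, G = green, B = blue)
  if (smooth) {
    # kernel: 2 axial (rows) x 3 lateral (columns)
    chans <- lapply(chans, box_filter, kernel = c(2L, 3L))
  }
  if (normalize == "match") {
    chans$R <- histogram_match(chans$R, chans$G)
    chans$B <- histogram_match(chans$B, chans$G)
  }
  hi <- stats::quantile(chans$G, 0.999, names = FALSE)
  if (hi <= 0) hi <- max(chans$G, 1e-12)
  rgb <- array(0, c(nrow(red), ncol(red), 3))
  for (i in 1:3) rgb[, , i] <- pmin(pmax(chans[[i]] / hi, 0), 1)
  structure(list(rgb = rgb,
                 provenance = list(smooth = smooth, normalize = normalize)),
            class = "true_color_image")
}

#' En-face projection
#'
#' Mean intensity over a depth range (or an explicit z mask) at each lateral
#' position.  Works on a B-scan matrix (z x x), a volume (z x x x b) and on
#' RGB volumes (z x x x 3 with `rgb = TRUE`).
#'
#' @param volume matrix or 3D array with depth in the first dimension.
#' @param z_range integer range of z indices `c(lo, hi)`; default all.
#' @param mask optional logical vector over z (overrides `z_range`).
#' @param rgb treat the third dimension as color rather than B-scans.
#' @return vector (from a B-scan), matrix (from a volume) or
#'   lateral x 3 matrix (RGB).
#' @export
enface_project <- function(volume, z_range = NULL, mask = NULL, rgb = FALSE) {
  nz <- dim(volume)[1] %||% length(volume)
  sel <- if (!is.null(mask)) which(mask)
  else if (!is.null(z_range)) seq.int(z_range[1], z_range[length(z_range)])
  else seq_len(nz)
  if (length(sel) == 0) stop("empty depth range")
  if (any(sel < 1 | sel > nz)) stop("z_range outside the volume")
  if (is.matrix(volume)) return(colMeans(volume[sel, , drop = FALSE]))
  if (length(dim(volume)) == 3) {
    return(apply(volume[sel, , , drop = FALSE], c(2, 3), mean))
  }
  stop("volume must be a matrix or 3D array")
}

#' Lesion height map above the RPE surface
#'
#' For each lateral position, the maximum height (um) above the given RPE
#' top surface at which the reflectivity exceeds the noise floor by
#' `threshold_db`, searched within `max_height_um` of the surface; zero
#' where no supra-RPE signal is present.  Returns the height map together
#' with the grayscale en-face projection of the signal from the RPE surface
#' down (the base image the heat map is rendered over).
#'
#' @param intensity linear reflectivity B-scan (z x lateral).
#' @param rpe_top integer z index of the RPE top surface per lateral
#'   position (manual segmentation accepted as input).
#' @param z_axis_um depth axis of the image.
#' @param threshold_db dB above the mean noise floor a pixel must reach.
#' @param max_height_um search window above the surface (default 40).
#' @param exclude_um guard band just above the surface excluded from the
#'   search (default 2), so the RPE's own point-spread wing does not
#'   register as supra-RPE signal.
#' @param floor_fraction passed to [noise_floor()].
#' @param noise_floor_linear optional explicit linear floor.
#' @return list with `height_um` (per lateral position), `base` (grayscale
#'   sub-RPE en-face projection) and the applied threshold.
#' @export
lesion_height_map <- function(intensity, rpe_top, z_axis_um,
                              threshold_db = 4, max_height_um = 40,
                              exclude_um = 2, floor_fraction = 0.1,
                              noise_floor_linear = NULL) {
  nz <- nrow(intensity); nx <- ncol(intensity)
  if (length(rpe_top) != nx) stop("one surface index per lateral position")
  if (any(rpe_top < 1 | rpe_top > nz)) stop("surface index outside volume")
  floor_lin <- noise_floor_linear %||% noise_floor(intensity, floor_fraction)
  cut <- floor_lin * 10^(threshold_db / 10)
  dz <- z_axis_um[2] - z_axis_um[1]
  up_bins <- floor(max_height_um / dz)
  guard <- ceiling(exclude_um / dz)
  height <- numeric(nx)
  base <- numeric(nx)
  for (x in seq_len(nx)) {
    top <- rpe_top[x]
    lo <- max(1L, top - up_bins)
    hi <- top - 1L - guard
    if (hi >= lo) {
      seg <- intensity[lo:hi, x]
      hit <- which(seg > cut)
      if (length(hit) > 0) {
        zi <- lo + hit[1] - 1L            # shallowest exceedance
        height[x] <- z_axis_um[top] - z_axis_um[zi]
      }
    }
    base[x] <- mean(intensity[top:nz, x])
  }
  list(height_um = height, base = base, threshold_db = threshold_db,
       max_height_um = max_height_um, exclude_um = exclude_um)
}
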