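FRAME_SCHEMA_VERSION <- "visoct-frame/1"
TOMO_SCHEMA_VERSION <- "visoct-tomogram/1"

# small FNV-1a hash for config provenance strings
#' @noRd
config_hash <- function(x) {
  s <- charToRaw(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in as.integer(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write / read a raw spectral frame container (HDF5)
#'
#' Layout: `/raw/channel_H`, `/raw/channel_V` (pixel x A-scan \[x B-scan\]
#' arrays), `/axes/wavelength_nm`, `/meta/json` (JSON-serialized acquisition
#' config, phantom label, seed and schema version).  The round trip is
#' lossless (double precision end to end).
#'
#' @param frame a `raw_frame`.
#' @param path HDF5 file path (overwritten).
#' @return `path` invisibly (write); a `raw_frame` (read).
#' @export
write_frame <- function(frame, path) {
  stopifnot_frame(frame)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "raw")
  rhdf5::h5createGroup(path, "axes")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(frame$channel_H, path, "raw/channel_H")
  rhdf5::h5write(frame$channel_V, path, "raw/channel_V")
  rhdf5::h5write(frame$wavelength_nm, path, "axes/wavelength_nm")
  meta <- frame$meta
  meta$version <- FRAME_SCHEMA_VERSION
  meta$config_hash <- config_hash(meta$config)
  if (!is.null(meta$config)) meta$config <- unclass(meta$config)
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA, force = TRUE)),
                 path, "meta/json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  have <- file.path(sub("^/", "", ls$group), ls$name)
  need <- c("raw/channel_H", "raw/channel_V", "axes/wavelength_nm",
            "meta/json")
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop("container is missing dataset(s): ", paste(missing, collapse = ", "))
  H <- rhdf5::h5read(path, "raw/channel_H")
  V <- rhdf5::h5read(path, "raw/channel_V")
  wl <- as.numeric(rhdf5::h5read(path, "axes/wavelength_nm"))
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta/json")[1])
  rhdf5::h5closeAll()
  if (is.null(meta$version) || meta$version != FRAME_SCHEMA_VERSION)
    stop("unsupported container version: ",
         meta$version %||% "<missing>", " (expected ", FRAME_SCHEMA_VERSION,
         ")")
  if (!is.null(meta$config)) {
    cfg <- meta$config
    meta$config <- acquisition_config(
      n_pixels = cfg$n_pixels, wavelength_min = cfg$wavelength_min,
      wavelength_max = cfg$wavelength_max, n_ascans = cfg$n_ascans,
      n_bscans = cfg$n_bscans, shot_scale = cfg$shot_scale,
      read_std = cfg$read_std, pixel_mtf_width = cfg$pixel_mtf_width,
      dc_level = cfg$dc_level, depth_jitter_um = cfg$depth_jitter_um,
      amplitude_scale = cfg$amplitude_scale, seed = cfg$seed)
  }
  structure(list(channel_H = if (length(dim(H)) == 2) as.matrix(H) else H,
                 channel_V = if (length(dim(V)) == 2) as.matrix(V) else V,
                 wavelength_nm = wl, meta = meta),
            class = "raw_frame")
}

#' Write / read a complex tomogram container (HDF5)
#'
#' Layout: `/tomo/A_H_re`, `/tomo/A_H_im`, `/tomo/A_V_re`, `/tomo/A_V_im`,
#' `/axes/z_um`, `/meta/json`.
#'
#' @param tomo a `complex_tomogram`.
#' @param path HDF5 file path (overwritten).
#' @return `path` invisibly (write); a `complex_tomogram` (read).
#' @export
write_tomogram <- function(tomo, path) {
  if (!inherits(tomo, "complex_tomogram")) stop("expected a complex_tomogram")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "tomo")
  rhdf5::h5createGroup(path, "axes")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(Re(tomo$A_H), path, "tomo/A_H_re")
  rhdf5::h5write(Im(tomo$A_H), path, "tomo/A_H_im")
  rhdf5::h5write(Re(tomo$A_V), path, "tomo/A_V_re")
  rhdf5::h5write(Im(tomo$A_V), path, "tomo/A_V_im")
  rhdf5::h5write(tomo$z_axis_um, path, "axes/z_um")
  meta <- tomo$meta
  meta$version <- TOMO_SCHEMA_VERSION
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA, force = TRUE)),
                 path, "meta/json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  need <- c("tomo/A_H_re", "tomo/A_H_im", "tomo/A_V_re", "tomo/A_V_im",
            "axes/z_um", "meta/json")
  ls <- rhdf5::h5ls(path)
  have <- file.path(sub("^/", "", ls$group), ls$name)
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop("container is missing dataset(s): ", paste(missing, collapse = ", "))
  AH <- rhdf5::h5read(path, "tomo/A_H_re") +
    1i * rhdf5::h5read(path, "tomo/A_H_im")
  AV <- rhdf5::h5read(path, "tomo/A_V_re") +
    1i * rhdf5::h5read(path, "tomo/A_V_im")
  z <- as.numeric(rhdf5::h5read(path, "axes/z_um"))
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta/json")[1])
  rhdf5::h5closeAll()
  structure(list(A_H = AH, A_V = AV, z_axis_um = z, meta = meta),
            class = "complex_tomogram")
}

#' Export an image with deterministic scaling
#'
#' Scales the image linearly onto \[0, 1\] over `range` (default its finite
#' range), renders masked pixels as a documented neutral gray, optionally
#' applies a colormap, and records the scaling in a JSON sidecar file
#' (`<path>.json`) so exports are reproducible.
#'
#' @param image numeric matrix; `NA` allowed only where `mask` is FALSE.
#' @param path output file.
#' @param kind `"png8"`, `"tiff16"` or `"tiff32f"`.  `tiff32f` stores the
#'   scaled values as 32-bit floats; the sidecar's `scale_min`/`scale_max`
#'   recover the physical values as `value * (max - min) + min`.
#' @param colormap `NULL` for grayscale, or a vector of colors ramped over
#'   \[0, 1\] (e.g. for retardation maps).
#' @param mask logical matrix, TRUE = valid pixel.  Invalid pixels render
#'   as `gray`.
#' @param range scaling range `c(lo, hi)`.
#' @param gray gray value for masked pixels (default 0.5).
#' @return `path`, invisibly.
#' @export
export_image <- function(image, path,
                         kind = c("png8", "tiff16", "tiff32f"),
                         colormap = NULL, mask = NULL, range = NULL,
                         gray = 0.5) {
  kind <- match.arg(kind)
  if (is.null(mask)) {
    if (any(!is.finite(image)))
      stop("non-finite pixels present but no mask given")
    mask <- array(TRUE, dim(image))
  }
  if (any(!is.finite(image[mask])))
    stop("non-finite pixels present outside the mask")
  vals <- image[mask]
  if (is.null(range)) range <- if (length(vals)) range(vals) else c(0, 1)
  span <- diff(range)
  if (span <= 0) span <- 1
  scaled <- (image - range[1]) / span
  scaled[!mask] <- NA
  scaled <- pmin(pmax(scaled, 0), 1)

  if (kind == "tiff32f") {
    out <- scaled
    out[is.na(out)] <- gray
    tiff::writeTIFF(out, path, bits.per.sample = 32, reduce = FALSE)
  } else if (kind == "tiff16") {
    out <- scaled
    out[is.na(out)] <- gray
    tiff::writeTIFF(out, path, bits.per.sample = 16)
  } else {
    if (is.null(colormap)) {
      out <- scaled
      out[is.na(out)] <- gray
      out <- round(out * 255) / 255
      png::writePNG(out, path)
    } else {
      ramp <- grDevices::colorRamp(colormap)
      flat <- as.vector(scaled)
      rgb <- matrix(gray * 255, length(flat), 3)
      ok <- !is.na(flat)
      rgb[ok, ] <- ramp(flat[ok])
      arr <- array(rgb / 255, c(nrow(image), ncol(image), 3))
      arr <- round(arr * 255) / 255
      png::writePNG(arr, path)
    }
  }
  jsonlite::write_json(list(kind = kind, scale_min = range[1],
                            scale_max = range[2], masked_gray = gray,
                            colormap = colormap),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
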