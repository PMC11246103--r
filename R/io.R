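# File interchange: TIFF (canonical, 8/16-bit integer in, float-scaled
# out) and PNG (8/16-bit input only), each with a YAML sidecar carrying
# the calibration (pitch, wavelength, z) and the linear scale applied,
# so any file round-trips to physical units exactly.

sidecar_path <- function(path) paste0(path, ".yaml")

read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)",
         call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a hologram to a 16-bit TIFF with a calibration sidecar
#'
#' Intensity is scaled linearly to the full integer range; the scale
#' factor, grid calibration and recording distance are stored in a YAML
#' sidecar (`<path>.yaml`) so [read_hologram()] restores physical units.
#'
#' @param holo A [hologram()].
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar (e.g. the
#'   phantom spec and seed for exact replay).
#' @return `path`, invisibly.
#' @export
write_hologram <- function(holo, path, extra = NULL) {
  stopifnot(inherits(holo, "hologram"))
  scale <- max(holo$intensity)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(holo$intensity / scale, path, bits.per.sample = 16L)
  meta <- c(list(type = "hologram", nx = holo$grid$nx, ny = holo$grid$ny,
                 pitch = holo$grid$pitch,
                 wavelength = holo$grid$wavelength,
                 z = holo$z_record, scale = scale, bits = 16L), extra)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

require_fields <- function(meta, fields, where) {
  missing <- setdiff(fields, names(meta))
  if (length(missing))
    stop("missing calibration field(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read a hologram from TIFF/PNG plus its calibration
#'
#' @param path Image path (TIFF or PNG, single channel; extra channels
#'   are dropped).
#' @param meta Calibration as a named list or a YAML path; defaults to
#'   the `<path>.yaml` sidecar.  Must provide `pitch`, `wavelength`,
#'   `z`; `scale` (default 1) converts pixel values to intensity.
#' @return A [hologram()].
#' @export
read_hologram <- function(path, meta = sidecar_path(path)) {
  if (is.character(meta)) {
    if (!file.exists(meta))
      stop("missing calibration sidecar: ", meta, call. = FALSE)
    meta <- yaml::read_yaml(meta)
  }
  require_fields(meta, c("pitch", "wavelength", "z"), "hologram metadata")
  img <- read_image_gray(path)
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  grid <- grid_spec(ncol(img), nrow(img), meta$pitch, meta$wavelength)
  hologram(img * scale, grid, z_record = meta$z)
}

#' Write a real-valued map (phase, amplitude) as a scaled float TIFF
#'
#' The map is shifted/scaled into `[0, 1]` for storage; offset and scale
#' go into the YAML sidecar so [read_map()] restores the values.
#'
#' @param values Real matrix (e.g. unwrapped phase in radians).
#' @param path Output TIFF path.
#' @param type Free-form content tag recorded in the sidecar.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, path, type = "map", extra = NULL) {
  values <- phase_values(values)
  offset <- min(values)
  scale <- max(values) - offset
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((values - offset) / scale, path, bits.per.sample = 32L)
  yaml::write_yaml(c(list(type = type, offset = offset, scale = scale),
                     extra),
                   sidecar_path(path))
  invisible(path)
}

#' Read a map written by [write_map()]
#'
#' @param path TIFF path with its YAML sidecar.
#' @return Real matrix in original units.
#' @export
read_map <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  read_image_gray(path) * meta$scale + meta$offset
}
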