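#' Calibrated grayscale image
#'
#' Container pairing an 8-bit grayscale raster with its physical
#' calibration. Pixel values are integers in 0..255; `scale_mm_per_px`
#' is the side length of one pixel in millimetres, typically obtained
#' from a micrometer (stage ruler) image via [calibrate_from_ruler()].
#'
#' @param pixels integer matrix of gray values in 0..255; rows are image
#'   rows (top to bottom), columns are image columns (left to right).
#' @param scale_mm_per_px physical pixel size, mm per pixel (> 0).
#' @param source_id identifier carried through all downstream records.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, scale_mm_per_px, source_id = "image") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("`scale_mm_per_px` must be a single positive number")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("`pixels` must contain gray values in 0..255")
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, scale_mm_per_px = as.numeric(scale_mm_per_px),
         source_id = as.character(source_id)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %s: %d x %d px, %.6g mm/px\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$scale_mm_per_px))
  invisible(x)
}

#' Binary grain mask
#'
#' A binary raster marking one grain cross-section as foreground,
#' together with its physical calibration. After [extract_roi()] the
#' foreground is guaranteed to be a single 8-connected component.
#'
#' @param pixels matrix of 0/1 (or logical) values; 1 = foreground.
#' @param scale_mm_per_px physical pixel size, mm per pixel (> 0).
#' @param source_id identifier of the originating image.
#' @param provenance named list recording how the mask was produced
#'   (threshold method and value, polarity, components dropped, ...).
#' @return An object of class `grain_mask`.
#' @export
grain_mask <- function(pixels, scale_mm_per_px, source_id = "mask",
                       provenance = list()) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("`scale_mm_per_px` must be a single positive number")
  px <- pixels
  if (is.logical(px)) px <- px + 0L
  if (!all(px %in% c(0L, 1L))) stop("mask pixels must be 0/1")
  storage.mode(px) <- "integer"
  if (sum(px) == 0L) stop("mask has empty foreground")
  structure(
    list(pixels = px, scale_mm_per_px = as.numeric(scale_mm_per_px),
         source_id = as.character(source_id), provenance = provenance),
    class = "grain_mask")
}

#' @export
print.grain_mask <- function(x, ...) {
  cat(sprintf("<grain_mask> %s: %d x %d px, %d foreground px, %.6g mm/px\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), x$scale_mm_per_px))
  invisible(x)
}

# ITU-R BT.601 luma weights for RGB -> grayscale
.luma601 <- c(0.299, 0.587, 0.114)

#' Load a micrograph as a calibrated 8-bit grayscale image
#'
#' Reads a PNG or TIFF image, converts color images to 8-bit luminance
#' using the ITU-R BT.601 weights (0.299 R + 0.587 G + 0.114 B), and
#' attaches the physical pixel size.
#'
#' @param path path to a PNG or TIFF file. BMP is not supported.
#' @param scale_mm_per_px physical pixel size, mm per pixel (> 0).
#' @param source_id identifier; defaults to the file name.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, scale_mm_per_px,
                       source_id = basename(path)) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path)
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1L ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("`scale_mm_per_px` must be a single positive number")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = stop("BMP input is not supported; convert to PNG or TIFF"),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      gray <- arr[, , 1] * .luma601[1] + arr[, , 2] * .luma601[2] +
        arr[, , 3] * .luma601[3]
    } else {
      gray <- arr[, , 1]  # gray + alpha
    }
  } else {
    gray <- arr
  }
  calibrated_image(round(gray * 255), scale_mm_per_px, source_id)
}

#' Pixel calibration from a stage-ruler image
#'
#' Computes the physical pixel size from the measured pixel length of a
#' feature of known physical length, e.g. a 100 micrometre stage ruler
#' (0.1 mm) imaged under the same optics as the grain sections.
#'
#' @param ruler_length_px measured length of the ruler in pixels (> 0).
#' @param known_length_mm true physical length in mm (> 0).
#' @return Scale in mm per pixel.
#' @examples
#' calibrate_from_ruler(200, 0.1)  # 100 um over 200 px -> 5e-4 mm/px
#' @export
calibrate_from_ruler <- function(ruler_length_px, known_length_mm) {
  if (!is.numeric(ruler_length_px) || length(ruler_length_px) != 1L ||
      !is.finite(ruler_length_px) || ruler_length_px <= 0)
    stop("`ruler_length_px` must be a single positive number")
  if (!is.numeric(known_length_mm) || length(known_length_mm) != 1L ||
      !is.finite(known_length_mm) || known_length_mm <= 0)
    stop("`known_length_mm` must be a single positive number")
  known_length_mm / ruler_length_px
}

#' Optional linear contrast standardization
#'
#' Min-max rescaling of an 8-bit image to the full 0..255 range; a
#' reproducible stand-in for interactive brightness/contrast
#' adjustment. A constant image is returned unchanged.
#'
#' @param img a [calibrated_image()].
#' @return A [calibrated_image()] with rescaled pixels.
#' @export
standardize_contrast <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  v <- img$pixels
  rng <- range(v)
  if (rng[1] == rng[2]) return(img)
  calibrated_image(round((v - rng[1]) / (rng[2] - rng[1]) * 255),
                   img$scale_mm_per_px, img$source_id)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a [grain_mask()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "grain_mask"))
  png::writePNG(mask$pixels * 1.0, path)
  invisible(path)
}

#' Read a 0/255 PNG/TIFF mask back as a grain mask
#'
#' @param path path to the mask image.
#' @param scale_mm_per_px physical pixel size, mm per pixel.
#' @param source_id identifier; defaults to the file name.
#' @return A [grain_mask()].
#' @export
read_mask <- function(path, scale_mm_per_px, source_id = basename(path)) {
  img <- load_image(path, scale_mm_per_px, source_id)
  grain_mask(img$pixels >= 128L, scale_mm_per_px, source_id,
             provenance = list(read_from = path))
}
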