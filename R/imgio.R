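# Image ingestion, channel handling, field-of-view estimation and spatial
# calibration. All rasters are row-major with origin at the top-left pixel;
# pixel coordinates used in box files are 0-based and half-open.

#' Construct a fundus image object
#'
#' A \code{fundus_image} holds an 8-bit RGB raster (H x W x 3 integer array,
#' values 0..255) together with an optional circular field-of-view (FOV)
#' mask and an optional spatial calibration.
#'
#' @param pixels H x W x 3 numeric/integer array with values in 0..255.
#' @param fov optional H x W logical matrix, \code{TRUE} inside the imaged
#'   circular field.
#' @param calibration optional \code{\link{calibration}} object.
#' @return An object of class \code{fundus_image}.
#' @export
fundus_image <- function(pixels, fov = NULL, calibration = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    abort_validation("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 32 || d[2] < 32)
    abort_validation("image must be at least 32 x 32 pixels, got ", d[1], " x ", d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort_validation("pixel values must lie in [0, 255]")
  pixels <- array(as.integer(round(pixels)), d)  # also drops reader attributes
  if (!is.null(fov)) {
    check_mask(fov, "fov")
    if (!identical(dim(fov), d[1:2]))
      abort_validation("fov mask dimensions must match the image")
  }
  if (!is.null(calibration) && !inherits(calibration, "fundus_calibration"))
    abort_validation("calibration must be built with calibration() or derive_calibration()")
  structure(list(pixels = pixels, fov = fov, calibration = calibration),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %d x %d RGB>\n", d[1], d[2]))
  if (!is.null(x$fov))
    cat(sprintf("  fov: %d px (%.1f%% of frame)\n", sum(x$fov), 100 * mean(x$fov)))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration: %.6g mm/px (%s)\n",
                x$calibration$mm_per_pixel, x$calibration$source))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

#' Read a colour fundus photograph
#'
#' Reads a PNG, TIFF or JPEG raster into a \code{\link{fundus_image}}.
#' Grayscale inputs are replicated to three channels with a warning; 16-bit
#' inputs are down-scaled to 8-bit by integer division by 256 (65535 maps to
#' 255) with a warning. No FOV mask or calibration is attached.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return A \code{\link{fundus_image}}.
#' @export
read_fundus <- function(path) {
  if (!is.character(path) || length(path) != 1)
    abort_validation("path must be a single file path")
  if (!file.exists(path)) abort_io("cannot read image: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      r <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) abort_io("failed to decode PNG '", path, "': ", conditionMessage(e)))
      depth <- attr(r, "info")$bit.depth
      if (!is.null(depth) && depth > 8) {
        warning("16-bit input '", path, "' down-scaled to 8-bit by integer division", call. = FALSE)
        floor(round(r * 65535) / 256)
      } else round(r * 255)
    },
    tif = ,
    tiff = {
      r <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) abort_io("failed to decode TIFF '", path, "': ", conditionMessage(e)))
      depth <- attr(r, "bits.per.sample")
      if (!is.null(depth) && depth > 8) {
        warning("16-bit input '", path, "' down-scaled to 8-bit by integer division", call. = FALSE)
        round(r * 65535) %/% 256
      } else round(r * 255)
    },
    jpg = ,
    jpeg = {
      r <- tryCatch(EBImage::readImage(path),
                    error = function(e) abort_io("failed to decode JPEG '", path, "': ", conditionMessage(e)))
      # EBImage stores x,y (column-major in screen coords): transpose to H x W
      a <- EBImage::imageData(r)
      if (length(dim(a)) == 2) a <- t(a)
      else a <- aperm(a, c(2, 1, 3))
      round(a * 255)
    },
    abort_io("unsupported image format '", ext, "' for '", path, "'")
  )
  if (length(dim(px)) == 2) {
    warning("grayscale input '", path, "' replicated to 3 channels", call. = FALSE)
    px <- array(px, c(dim(px), 3))
  } else if (dim(px)[3] == 4) {
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  } else if (dim(px)[3] != 3) {
    abort_io("expected 1, 3 or 4 channels in '", path, "', got ", dim(px)[3])
  }
  fundus_image(px)
}

#' Write a binary mask as a black/white PNG
#'
#' @param mask H x W logical matrix.
#' @param path output PNG path; detected pixels are written as 255, the rest 0.
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Write a fundus image as PNG
#'
#' @param img a \code{\link{fundus_image}}.
#' @param path output PNG path.
#' @export
write_fundus_png <- function(img, path) {
  stopifnot(inherits(img, "fundus_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Grayscale conversion (BT.601 luma)
#'
#' Converts RGB to the working intensity scale using the BT.601 weights:
#' \code{v = (0.2989 R + 0.5870 G + 0.1140 B) / 255}.
#'
#' @param img a \code{\link{fundus_image}}.
#' @return An H x W numeric matrix in [0, 1].
#' @export
rgb_to_gray <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  p <- img$pixels
  clamp01((0.2989 * p[, , 1] + 0.5870 * p[, , 2] + 0.1140 * p[, , 3]) / 255)
}

#' Extract the green plane
#'
#' Faint exudates contrast best against the retinal background in the green
#' channel, which is why both the faint-lesion pipeline and the
#' maximum-entropy baseline operate on it.
#'
#' @param img a \code{\link{fundus_image}}.
#' @return An H x W numeric matrix in [0, 1] (\code{G / 255}).
#' @export
extract_green <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  img$pixels[, , 2] / 255
}

#' Estimate the circular field-of-view mask
#'
#' Fundus photographs have a near-black matting outside the circular imaged
#' field. The mask is the largest connected region of pixels whose maximum
#' channel value exceeds \code{dark_threshold}, after morphological closing
#' with a disc of radius 5 px. If that region covers more than 99\% of the
#' frame the whole frame is returned with a warning (no detectable surround).
#'
#' @param img a \code{\link{fundus_image}}.
#' @param dark_threshold 8-bit level separating matting from retina (default 10).
#' @return An H x W logical matrix.
#' @export
estimate_fov_mask <- function(img, dark_threshold = 10) {
  stopifnot(inherits(img, "fundus_image"))
  p <- img$pixels
  bright <- pmax(p[, , 1], p[, , 2], p[, , 3]) > dark_threshold
  if (!any(bright)) abort_validation("cannot estimate FOV: image is entirely dark")
  # an opening first removes isolated speckles in the dark surround (noise
  # above the threshold) so they cannot attach to the field during closing
  bright <- as.matrix(EBImage::opening(bright * 1L, disc_kernel(2))) > 0
  if (!any(bright)) abort_validation("cannot estimate FOV: image is entirely dark")
  closed <- as.matrix(EBImage::closing(bright * 1L, disc_kernel(5))) > 0
  lab <- matrix(as.integer(EBImage::bwlabel(closed)), nrow(closed), ncol(closed))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  if (sum(mask) > 0.99 * length(mask)) {
    warning("no dark surround found; using the whole frame as FOV", call. = FALSE)
    mask <- matrix(TRUE, nrow(mask), ncol(mask))
  }
  mask
}

#' Spatial calibration
#'
#' @param mm_per_pixel isotropic scale in millimetres of retina per pixel.
#' @param source provenance tag: \code{"user_supplied"}, \code{"fov_derived"}
#'   or \code{"default"}.
#' @return An object of class \code{fundus_calibration}.
#' @export
calibration <- function(mm_per_pixel, source = "user_supplied") {
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1 ||
      is.na(mm_per_pixel) || mm_per_pixel <= 0)
    abort_validation("mm_per_pixel must be a single positive number")
  source <- match.arg(source, c("user_supplied", "fov_derived", "default"))
  structure(list(mm_per_pixel = mm_per_pixel, source = source),
            class = "fundus_calibration")
}

#' @export
print.fundus_calibration <- function(x, ...) {
  cat(sprintf("<calibration %.6g mm/px, %s>\n", x$mm_per_pixel, x$source))
  invisible(x)
}

# Schematic emmetropic-eye retinal scale: 1 degree of visual field spans
# about 0.288 mm on the retina.
MM_PER_DEGREE <- 0.288

#' Derive calibration from the field-of-view geometry
#'
#' Converts an acquisition field of view in degrees into a pixel scale via
#' the schematic-eye constant 0.288 mm of retina per degree:
#' \code{mm_per_pixel = fov_degrees * 0.288 / fov_diameter_px}. Fundus
#' photographs here follow a 50-degree protocol, so a 50-degree field that
#' spans 1440 px gives 0.01 mm/px.
#'
#' @param fov_diameter_px diameter of the imaged circular field in pixels.
#' @param fov_degrees acquisition field of view in degrees (default 50).
#' @return A \code{\link{calibration}} with source \code{"fov_derived"}.
#' @export
derive_calibration <- function(fov_diameter_px, fov_degrees = 50) {
  if (!is.numeric(fov_diameter_px) || length(fov_diameter_px) != 1 ||
      is.na(fov_diameter_px) || fov_diameter_px <= 0)
    abort_validation("fov_diameter_px must be a single positive number")
  if (!is.numeric(fov_degrees) || length(fov_degrees) != 1 ||
      is.na(fov_degrees) || fov_degrees <= 0)
    abort_validation("fov_degrees must be a single positive number")
  calibration(fov_degrees * MM_PER_DEGREE / fov_diameter_px, source = "fov_derived")
}

#' Default calibration from an estimated field of view
#'
#' When no calibration is supplied, the FOV diameter is estimated from the
#' FOV mask area (diameter of the equal-area circle) and combined with the
#' default 50-degree protocol. The result is tagged \code{"default"} so
#' reports record that the scale is a documented stand-in, not a measured
#' camera constant.
#'
#' @param img a \code{\link{fundus_image}} (FOV estimated if absent).
#' @param fov_degrees acquisition field of view in degrees (default 50).
#' @return A \code{\link{calibration}} with source \code{"default"}.
#' @export
default_calibration <- function(img, fov_degrees = 50) {
  fov <- if (!is.null(img$fov)) img$fov else estimate_fov_mask(img)
  diam <- 2 * sqrt(sum(fov) / pi)
  cal <- derive_calibration(diam, fov_degrees)
  cal$source <- "default"
  cal
}
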