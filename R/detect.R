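# Two-pronged hard-exudate detection. Step 1 targets bright exudates on the
# grayscale image with a large structuring element (one quarter of the image
# width); step 2 targets faint exudates on the green plane with a small one
# (one twenty-fifth of the width) and a lower threshold. Each step is
# white top-hat -> CLAHE -> fixed threshold; the two masks are unioned.

#' Detection parameters
#'
#' Holds the tunable constants of the two-pronged pipeline. The defaults are
#' the empirically determined operating point: step 1 uses a disc whose
#' radius is one quarter of the image width and threshold 0.37; step 2 uses
#' one twenty-fifth of the width and threshold 0.25. Thresholds are on the
#' [0,1] scale of the equalized image. CLAHE runs on an 8 x 8 tile grid with
#' clip fraction 0.01.
#'
#' @param step1_radius_frac disc radius for step 1 as a fraction of image
#'   width (default 1/4).
#' @param step1_threshold binarization threshold for step 1 (default 0.37).
#' @param step2_radius_frac disc radius for step 2 as a fraction of image
#'   width (default 1/25).
#' @param step2_threshold binarization threshold for step 2 (default 0.25).
#' @param clahe_tiles integer pair: CLAHE contextual tile grid (default c(8, 8)).
#' @param clahe_clip CLAHE clip limit as a fraction of tile pixel count,
#'   in (0, 1] (default 0.01).
#' @return An object of class \code{detect_params}.
#' @export
detect_params <- function(step1_radius_frac = 1 / 4, step1_threshold = 0.37,
                          step2_radius_frac = 1 / 25, step2_threshold = 0.25,
                          clahe_tiles = c(8L, 8L), clahe_clip = 0.01) {
  for (t in c(step1_threshold, step2_threshold))
    if (!is.numeric(t) || t <= 0 || t >= 1)
      abort_validation("thresholds must lie strictly in (0, 1)")
  for (f in c(step1_radius_frac, step2_radius_frac))
    if (!is.numeric(f) || f <= 0 || f > 0.5)
      abort_validation("radius fractions must lie in (0, 0.5]")
  clahe_tiles <- as.integer(rep(clahe_tiles, length.out = 2))
  if (any(clahe_tiles < 1)) abort_validation("clahe_tiles must be >= 1")
  if (!is.numeric(clahe_clip) || clahe_clip <= 0 || clahe_clip > 1)
    abort_validation("clahe_clip must lie in (0, 1]")
  structure(list(step1_radius_frac = step1_radius_frac,
                 step1_threshold = step1_threshold,
                 step2_radius_frac = step2_radius_frac,
                 step2_threshold = step2_threshold,
                 clahe_tiles = clahe_tiles, clahe_clip = clahe_clip),
            class = "detect_params")
}

#' White top-hat filtering
#'
#' Subtracts the grayscale opening (erosion then dilation with a flat disc)
#' from the image: bright structures smaller than the disc survive while
#' smooth background illumination is flattened. At image borders the
#' neighbourhood is restricted to pixels inside the frame.
#'
#' @param img H x W numeric matrix in [0, 1].
#' @param radius disc radius in pixels; must be below \code{min(H, W) / 2}.
#' @return H x W numeric matrix in [0, 1]; zero wherever the image equals
#'   its opening.
#' @export
white_top_hat <- function(img, radius) {
  check_intensity(img)
  radius <- as.integer(round(radius))
  if (radius < 1) abort_validation("radius must be >= 1")
  if (radius >= min(dim(img)) / 2)
    abort_validation("structuring element radius ", radius,
                     " is too large for a ", nrow(img), " x ", ncol(img), " image")
  kern <- disc_kernel(radius)
  out <- img - as.matrix(EBImage::opening(img, kern))
  clamp01(out)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The input is first stretched to the full [0,1] range by its global
#' minimum and maximum (as mainstream CLAHE implementations do), then
#' equalized locally over a grid of contextual tiles with bilinear
#' interpolation between tile mappings, clipping each tile histogram at
#' \code{clip} times the tile pixel count. With a 1 x 1 tile grid the
#' operation reduces to global histogram equalization. Images whose sides
#' are not divisible by the tile grid are edge-padded for the transform and
#' cropped back. A spatially constant image is returned unchanged (its
#' histogram is degenerate).
#'
#' @param img H x W numeric matrix in [0, 1].
#' @param tiles integer pair, contextual tile grid (default c(8, 8)).
#' @param clip clip limit as a fraction of tile pixel count, in (0, 1]
#'   (default 0.01).
#' @param bins number of histogram bins (default 256).
#' @return H x W numeric matrix in [0, 1].
#' @export
adaptive_hist_eq <- function(img, tiles = c(8L, 8L), clip = 0.01, bins = 256L) {
  check_intensity(img)
  tiles <- as.integer(rep(tiles, length.out = 2))
  if (any(is.na(tiles)) || any(tiles < 1) || any(tiles > dim(img)))
    abort_validation("tiles must be between 1 and the image size")
  if (!is.numeric(clip) || is.na(clip) || clip <= 0 || clip > 1)
    abort_validation("clip must lie in (0, 1]")
  rng <- range(img)
  if (diff(rng) == 0) return(img)  # degenerate histogram: single level
  img <- (img - rng[1]) / (rng[2] - rng[1])
  if (prod(tiles) < 4) {
    out <- as.matrix(EBImage::equalize(img, range = c(0, 1), levels = bins))
    return(clamp01(out))
  }
  H <- nrow(img); W <- ncol(img)
  padH <- (tiles[1] - H %% tiles[1]) %% tiles[1]
  padW <- (tiles[2] - W %% tiles[2]) %% tiles[2]
  x <- img
  if (padH > 0) x <- rbind(x, x[rep(H, padH), , drop = FALSE])
  if (padW > 0) x <- cbind(x, x[, rep(W, padW), drop = FALSE])
  # EBImage's clip limit is expressed as a multiple of the uniform bin
  # height; clip * bins converts from the fraction-of-tile convention.
  out <- EBImage::clahe(x, nx = tiles[2], ny = tiles[1], bins = bins,
                        limit = clip * bins)
  clamp01(as.matrix(out)[seq_len(H), seq_len(W), drop = FALSE])
}

#' Fixed-threshold binarization
#'
#' @param img H x W numeric matrix in [0, 1].
#' @param threshold cut point strictly inside (0, 1); pixels strictly above
#'   it are detected.
#' @return H x W logical matrix.
#' @export
binarize <- function(img, threshold) {
  check_intensity(img)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold >= 1)
    abort_validation("threshold must lie strictly in (0, 1)")
  img > threshold
}

# Shared filtering chain of both steps. The near-black camera matting
# outside the FOV would otherwise dominate both the morphology (a huge
# erosion floor at the field rim) and the tile equalization. Setting the
# matting to white before the top-hat makes the erosion ignore it (the
# morphology then sees only retinal minima), and the out-of-FOV top-hat is
# zeroed before equalization so rim tiles resemble interior background.
# The FOV intersection comes last so no rim response survives.
detect_step <- function(chan, fov, radius_frac, threshold, p) {
  r <- max(1L, as.integer(round(radius_frac * ncol(chan))))
  chan[!fov] <- 1
  th <- white_top_hat(chan, r)
  th[!fov] <- 0
  enh <- adaptive_hist_eq(th, p$clahe_tiles, p$clahe_clip)
  binarize(enh, threshold) & fov
}

fov_or_estimate <- function(img) {
  if (!is.null(img$fov)) img$fov else estimate_fov_mask(img)
}

# detection on an entirely dark frame is an empty mask, not an error
fov_or_empty <- function(img) {
  tryCatch(fov_or_estimate(img),
           hequant_validation_error = function(e)
             matrix(FALSE, dim(img$pixels)[1], dim(img$pixels)[2]))
}

#' Step 1: bright hard-exudate detection
#'
#' Grayscale conversion, white top-hat with a disc of radius
#' \code{step1_radius_frac} times the image width, CLAHE, then thresholding
#' at \code{step1_threshold}; the result is intersected with the FOV mask.
#'
#' @param img a \code{\link{fundus_image}}; the FOV is estimated if absent.
#' @param p a \code{\link{detect_params}}.
#' @return H x W logical detection mask.
#' @export
detect_step1 <- function(img, p = detect_params()) {
  stopifnot(inherits(img, "fundus_image"))
  fov <- fov_or_empty(img)
  if (!any(fov)) return(fov)
  detect_step(rgb_to_gray(img), fov,
              p$step1_radius_frac, p$step1_threshold, p)
}

#' Step 2: faint hard-exudate detection
#'
#' Same chain as \code{\link{detect_step1}} but on the green plane, with a
#' much smaller disc (\code{step2_radius_frac} of the width) and the lower
#' threshold \code{step2_threshold}, so low-contrast exudates that step 1
#' misses still separate from their local background.
#'
#' @inheritParams detect_step1
#' @return H x W logical detection mask.
#' @export
detect_step2 <- function(img, p = detect_params()) {
  stopifnot(inherits(img, "fundus_image"))
  fov <- fov_or_empty(img)
  if (!any(fov)) return(fov)
  detect_step(extract_green(img), fov,
              p$step2_radius_frac, p$step2_threshold, p)
}

#' Union of detection masks
#'
#' @param m1,m2 H x W logical matrices of equal dimensions.
#' @return Pixelwise OR of the two masks.
#' @export
combine_masks <- function(m1, m2) {
  check_mask(m1, "m1"); check_mask(m2, "m2")
  if (!identical(dim(m1), dim(m2)))
    abort_validation("mask dimensions differ: ", paste(dim(m1), collapse = "x"),
                     " vs ", paste(dim(m2), collapse = "x"))
  m1 | m2
}

#' Full two-pronged hard-exudate detection
#'
#' Runs \code{\link{detect_step1}} (bright exudates) and
#' \code{\link{detect_step2}} (faint exudates) and combines them by union.
#'
#' @inheritParams detect_step1
#' @return H x W logical detection mask.
#' @export
detect_he <- function(img, p = detect_params()) {
  combine_masks(detect_step1(img, p), detect_step2(img, p))
}
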