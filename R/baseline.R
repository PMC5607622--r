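# The comparison method: green-plane maximum-entropy thresholding in the
# style of ImageJ's Auto Threshold "MaxEntropy" (Kapur-Sahoo-Wong), applied
# within the field of view so the dark camera matting does not dominate the
# background class.

#' 256-bin intensity histogram
#'
#' Bins \code{round(v * 255)} over the whole image or over a mask.
#'
#' @param img H x W numeric matrix in [0, 1].
#' @param mask optional H x W logical matrix restricting the tally.
#' @return Integer vector of length 256 (class \code{histogram256}); bin
#'   \code{i} counts level \code{i - 1}.
#' @export
intensity_histogram <- function(img, mask = NULL) {
  check_intensity(img)
  v <- img
  if (!is.null(mask)) {
    check_mask(mask)
    if (!identical(dim(mask), dim(img)))
      abort_validation("mask dimensions must match the image")
    if (!any(mask)) abort_validation("mask is empty: histogram undefined")
    v <- img[mask]
  }
  counts <- tabulate(as.integer(round(v * 255)) + 1L, nbins = 256L)
  structure(counts, class = "histogram256")
}

#' Maximum-entropy (Kapur) threshold
#'
#' Selects the 8-bit level t maximizing the sum of Shannon entropies of the
#' two normalized class histograms, background levels 0..t and foreground
#' levels t+1..255. Entropies use natural logarithms with 0 log 0 = 0;
#' candidate levels leaving either class empty are skipped; ties are broken
#' by the smallest level.
#'
#' @param h integer vector of length 256 (e.g. from
#'   \code{\link{intensity_histogram}}).
#' @return The selected threshold level as an integer in 0..254.
#' @export
max_entropy_threshold <- function(h) {
  h <- as.numeric(h)
  if (length(h) != 256 || anyNA(h) || any(h < 0))
    abort_validation("h must be 256 non-negative counts")
  nz <- which(h > 0)
  if (length(nz) < 2)
    abort_validation("histogram has fewer than two populated bins; no threshold separates one class")
  total <- sum(h)
  p <- h / total
  nb <- cumsum(h)                      # background class mass up to level t
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  Stot <- S[256]
  best_t <- -1L; best_crit <- -Inf
  for (t in 0:254) {
    # class emptiness decided on raw counts, not on float remainders
    if (nb[t + 1] == 0 || nb[t + 1] == total) next
    Pb <- nb[t + 1] / total; Pf <- 1 - Pb
    Hb <- log(Pb) - S[t + 1] / Pb
    Hf <- log(Pf) - (Stot - S[t + 1]) / Pf
    crit <- Hb + Hf
    if (crit > best_crit + 1e-12) { best_crit <- crit; best_t <- t }
  }
  as.integer(best_t)
}

#' Green-plane maximum-entropy detection (baseline method)
#'
#' The re-implemented comparison protocol: take the green plane, histogram
#' it within the FOV, threshold at the Kapur maximum-entropy level, and
#' return the pixels strictly above that level (exudates are the bright
#' class in the green plane), intersected with the FOV.
#'
#' @param img a \code{\link{fundus_image}}; the FOV is estimated if absent.
#' @return H x W logical detection mask.
#' @export
baseline_detect <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  fov <- fov_or_estimate(img)
  g <- extract_green(img)
  t <- max_entropy_threshold(intensity_histogram(g, fov))
  (round(g * 255) > t) & fov
}
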