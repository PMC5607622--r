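# Internal validation and raster helpers shared across modules.

abort_validation <- function(...) {
  cond <- structure(
    class = c("hequant_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  )
  stop(cond)
}

abort_io <- function(...) {
  cond <- structure(
    class = c("hequant_io_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  )
  stop(cond)
}

check_intensity <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    abort_validation(arg, " must be a numeric matrix (intensity image in [0,1])")
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    abort_validation(arg, " values must lie in [0,1] with no NAs")
  invisible(img)
}

check_mask <- function(m, arg = "mask") {
  if (!is.matrix(m) || !is.logical(m))
    abort_validation(arg, " must be a logical matrix")
  if (anyNA(m)) abort_validation(arg, " must not contain NAs")
  invisible(m)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Flat disc structuring element
#'
#' Builds the flat disc used by the morphological stages: the offset
#' \code{(di, dj)} belongs to the disc iff \code{di^2 + dj^2 <= radius^2}.
#' Note this is stricter than \code{EBImage::makeBrush}'s \code{"disc"},
#' which is why the kernel is constructed here explicitly.
#'
#' @param radius integer disc radius in pixels, at least 1.
#' @return A \code{(2 radius + 1)} square 0/1 integer matrix.
#' @examples
#' disc_kernel(1)  # the 5-pixel "plus" shape
#' @export
disc_kernel <- function(radius) {
  radius <- as.integer(round(radius))
  if (is.na(radius) || radius < 1)
    abort_validation("structuring element radius must be >= 1, got ", radius)
  d <- outer(-radius:radius, -radius:radius, function(a, b) a * a + b * b <= radius * radius)
  storage.mode(d) <- "integer"
  d
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# only touch diagonally are merged through an igraph component pass.
label_components <- function(mask, connectivity = 8L) {
  check_mask(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L || connectivity == 4L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  # pairs of distinct labels adjacent along the two diagonal directions
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # down-left
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::make_graph(as.vector(t(edges)), n = n, directed = FALSE)
  remap <- igraph::components(g)$membership
  # renumber compactly, keeping 0 for background
  remap <- match(remap, sort(unique(remap)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}
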