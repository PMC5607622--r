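# Independent oracles and shared fixtures.

# Brute-force grayscale morphology over a strict disc neighbourhood
# (di^2 + dj^2 <= r^2), window restricted to the image at borders.
bf_morph <- function(img, r, f) {
  H <- nrow(img); W <- ncol(img)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- i + off$di; jj <- j + off$dj
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out[i, j] <- f(img[cbind(ii[ok], jj[ok])])
  }
  out
}

bf_white_top_hat <- function(img, r) {
  opened <- bf_morph(bf_morph(img, r, min), r, max)
  pmax(img - opened, 0)
}

# Exhaustive Kapur criterion: evaluate both class entropies directly from
# sub-histogram sums for every candidate level, pick the smallest argmax.
kapur_exhaustive <- function(h) {
  total <- sum(h)
  best_crit <- -Inf; best_t <- -1L
  for (t in 0:254) {
    lo <- h[1:(t + 1)]; hi <- h[(t + 2):256]
    if (sum(lo) == 0 || sum(hi) == 0) next
    pb <- lo[lo > 0] / sum(lo); pf <- hi[hi > 0] / sum(hi)
    crit <- -sum(pb * log(pb)) - sum(pf * log(pf))
    if (crit > best_crit + 1e-12) { best_crit <- crit; best_t <- t }
  }
  as.integer(best_t)
}

# Brute-force 8-connected component labelling by repeated flood fill.
bf_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- q[1] + di; b <- q[2] + dj
        if (a >= 1 && a <= nrow(mask) && b >= 1 && b <= ncol(mask) &&
            mask[a, b] && lab[a, b] == 0) {
          lab[a, b] <- nxt
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# fraction of truth components touched by a detection mask
component_overlap <- function(mask, truth) {
  lab <- hequant:::label_components(truth)
  n <- max(lab)
  if (n == 0) return(NA_real_)
  hits <- vapply(seq_len(n), function(k) any(mask[lab == k]), logical(1))
  mean(hits)
}

# Scenes and detections are expensive; cache them across test files.
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(seed, ...) {
  key <- paste0("scene_", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(scene_spec(seed = seed, ...))
  .scene_cache[[key]]
}

# full set of detection products for a default scene
cached_run <- function(seed) {
  key <- paste0("run_", seed)
  if (is.null(.scene_cache[[key]])) {
    sc <- cached_scene(seed)
    p <- detect_params()
    m1 <- detect_step1(sc$image, p)
    m2 <- detect_step2(sc$image, p)
    .scene_cache[[key]] <- list(
      scene = sc, m1 = m1, m2 = m2, union = combine_masks(m1, m2),
      baseline = baseline_detect(sc$image))
  }
  .scene_cache[[key]]
}

acceptance_seeds <- 1:20
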