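# Seeded synthetic fundus scenes with per-class ground truth. The scene
# emulates the intensity taxonomy of a diabetic-retinopathy fundus
# photograph: a reddish retina inside a circular field of view on black
# matting, an optic disc near the nasal edge, a dark vessel tree with bright
# centerline reflections, bright and faint hard exudates in the macular
# half, and fuzzy cotton-wool spots. Per-class grayscale ranges follow the
# characterized distribution of such photographs: hard exudates 85-200,
# cotton-wool spots 80-130, optic disc 90-200, vessel reflections 80-110.
#
# Generation is split into two phases. sample_layout() consumes the RNG in
# normalized coordinates only (origin at the frame centre, unit = the
# shorter frame side), so a given seed describes the same retina at every
# resolution; render_layout() rasterizes it at the requested size. Pixel
# noise, the only raster-sized random draw, comes last.

#' Synthetic scene specification
#'
#' Parameters of \code{\link{generate_scene}}. Grayscale ranges are 8-bit
#' pairs (low, high). \code{faint_green_excess} is the green-plane contrast
#' of faint exudates over their local background, on the [0,1] scale; the
#' default 0.06 (about 15 of 255 levels) puts them well below the reach of
#' the bright-exudate prong.
#'
#' @param height,width scene size in pixels (default 512 x 512).
#' @param seed integer RNG seed; a spec is reproducible bit-for-bit.
#' @param n_bright_he number of bright hard-exudate clusters (default 5).
#' @param n_faint_he number of faint hard-exudate blobs (default 5).
#' @param n_cws number of cotton-wool spots (default 2).
#' @param he_gray_range grayscale range of hard exudates (default c(85, 200)).
#' @param cws_gray_range grayscale range of cotton-wool spots (default c(80, 130)).
#' @param disc_gray_range grayscale range of the optic disc (default c(90, 200)).
#' @param vessel_reflection_range grayscale range of vessel centerline
#'   reflections (default c(80, 110)).
#' @param faint_green_excess green-plane contrast of faint exudates in (0, 0.3)
#'   (default 0.06).
#' @param illumination_gradient relative amplitude of the smooth illumination
#'   field, in [0, 0.4] (default 0.35).
#' @param noise_sd additive Gaussian noise SD as a fraction of full scale
#'   (default 0.01).
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(height = 512L, width = 512L, seed = 1L,
                       n_bright_he = 5L, n_faint_he = 5L, n_cws = 2L,
                       he_gray_range = c(85, 200),
                       cws_gray_range = c(80, 130),
                       disc_gray_range = c(90, 200),
                       vessel_reflection_range = c(80, 110),
                       faint_green_excess = 0.06,
                       illumination_gradient = 0.35,
                       noise_sd = 0.01) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 64 || width < 64)
    abort_validation("scene must be at least 64 x 64")
  for (r in list(he_gray_range, cws_gray_range, disc_gray_range,
                 vessel_reflection_range)) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 255)
      abort_validation("gray ranges must be (low, high) pairs within [0, 255]")
  }
  if (any(c(n_bright_he, n_faint_he, n_cws) < 0))
    abort_validation("lesion counts must be >= 0")
  if (faint_green_excess <= 0 || faint_green_excess >= 0.3)
    abort_validation("faint_green_excess must lie in (0, 0.3)")
  if (illumination_gradient < 0 || illumination_gradient > 0.4)
    abort_validation("illumination_gradient must lie in [0, 0.4]")
  structure(list(height = height, width = width, seed = as.integer(seed),
                 n_bright_he = as.integer(n_bright_he),
                 n_faint_he = as.integer(n_faint_he),
                 n_cws = as.integer(n_cws),
                 he_gray_range = he_gray_range,
                 cws_gray_range = cws_gray_range,
                 disc_gray_range = disc_gray_range,
                 vessel_reflection_range = vessel_reflection_range,
                 faint_green_excess = faint_green_excess,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd),
            class = "scene_spec")
}

# Chroma directions: RGB triples scaled so the BT.601 gray of each equals 1;
# multiplying by a target gray level gives a pixel of exactly that grayscale.
norm_chroma <- function(v) v / sum(v * c(0.2989, 0.5870, 0.1140))
CHROMA <- list(
  background = norm_chroma(c(160, 80, 30)),
  he = norm_chroma(c(1.15, 1.08, 0.30)),      # yellow lipid deposit
  disc = norm_chroma(c(1.12, 1.02, 0.62)),    # pale yellow-white
  cws = norm_chroma(c(1.05, 1.00, 0.78)),     # whitish fluffy patch
  vessel = norm_chroma(c(1.85, 0.60, 0.35)),  # dark red column
  reflection = norm_chroma(c(0.95, 1.03, 1.00))
)
# paint grayscale level t with a chroma direction into an RGB array
paint <- function(px, mask, t, chroma) {
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- pmin(255, t * chroma[ch])
    px[, , ch] <- plane
  }
  px
}

BG_GRAY <- 98.25                       # background grayscale at unit field
SHEEN_W <- c(0.15, 1, 0.6)             # spectral weights of the sheen (R,G,B)
# grayscale gain of a unit of sheen relative to BG_GRAY
SHEEN_GRAY_COEF <- sum(c(0.2989, 0.5870, 0.1140) * BG_GRAY *
                         CHROMA$background * SHEEN_W) / BG_GRAY
FOV_RADIUS_FRAC <- 0.475               # FOV diameter = 0.95 * min(H, W)

# normalized-coordinate field evaluators (u = rows, v = cols, centre origin,
# unit = min(H, W)); vectorized over equal-length u, v
tilt_at <- function(layout, u, v)
  layout$tilt_amp * pmin(1, pmax(0, (cos(layout$theta) * u + sin(layout$theta) * v -
                                       layout$tilt_lo) / layout$tilt_span))
sheen_at <- function(layout, u, v) {
  s <- 0
  for (sp in layout$spots)
    s <- s + sp$amp * exp(-((u - sp$u)^2 + (v - sp$v)^2) / (2 * sp$sigma^2))
  layout$sheen_scale * s
}
illum_gray_at <- function(layout, u, v)
  1 - tilt_at(layout, u, v) + SHEEN_GRAY_COEF * sheen_at(layout, u, v)

# Phase 1: consume the RNG in normalized units only.
sample_layout <- function(spec) {
  aspH <- spec$height / min(spec$height, spec$width) / 2
  aspW <- spec$width / min(spec$height, spec$width) / 2
  g_amp <- spec$illumination_gradient
  layout <- list(g_amp = g_amp)

  # illumination: achromatic vignetting tilt spanning 0.55 * amplitude and
  # nasal-side green-dominant sheen spots peaking at the full amplitude
  layout$theta <- stats::runif(1, 0, 2 * pi)
  corners_u <- c(-aspH, -aspH, aspH, aspH)
  corners_v <- c(-aspW, aspW, -aspW, aspW)
  proj <- cos(layout$theta) * corners_u + sin(layout$theta) * corners_v
  layout$tilt_lo <- min(proj)
  layout$tilt_span <- max(diff(range(proj)), 1e-9)
  layout$tilt_amp <- 0.55 * g_amp
  n_spots <- sample(1:3, 1)
  spots <- vector("list", n_spots)
  for (k in seq_len(n_spots))
    spots[[k]] <- list(u = stats::runif(1, -0.6 * aspH, 0.6 * aspH),
                       v = stats::runif(1, 0, 0.7 * aspW),
                       sigma = stats::runif(1, 0.20, 0.30),
                       amp = stats::runif(1, 0.7, 1))
  peak <- max(vapply(seq_len(n_spots), function(k) {
    sp <- spots[[k]]
    sum(vapply(spots, function(o)
      o$amp * exp(-((sp$u - o$u)^2 + (sp$v - o$v)^2) / (2 * o$sigma^2)),
      numeric(1)))
  }, numeric(1)))
  layout$spots <- spots
  layout$sheen_scale <- g_amp / max(peak, 1e-9)

  # optic disc near the nasal (right) edge
  layout$disc <- list(u = stats::runif(1, -0.15, 0.15) * FOV_RADIUS_FRAC,
                      v = 0.72 * FOV_RADIUS_FRAC,
                      ru = 0.12 * FOV_RADIUS_FRAC,
                      rv = 0.10 * FOV_RADIUS_FRAC)

  # vessel tree: evenly fanned smooth arcs with one optional side branch;
  # all draws happen regardless of where a path leaves the field, so the
  # RNG stream is identical at every resolution
  step_len <- 3 / 512
  n_steps <- 300L
  n_paths <- sample(2:4, 1)
  fan <- seq(-0.85, 0.85, length.out = n_paths)
  trace_path <- function(u0, v0, ang, incs) {
    pts <- matrix(NA_real_, length(incs), 2)
    for (s in seq_along(incs)) {
      u0 <- u0 + step_len * sin(ang); v0 <- v0 + step_len * cos(ang)
      if (u0^2 + v0^2 > (0.92 * FOV_RADIUS_FRAC)^2) break
      pts[s, ] <- c(u0, v0)
      ang <- ang + incs[s]
    }
    pts[stats::complete.cases(pts), , drop = FALSE]
  }
  paths <- list()
  for (p in seq_len(n_paths)) {
    ang0 <- pi + fan[p] + stats::runif(1, -0.12, 0.12)
    width <- stats::runif(1, 2, 6) / 512
    curv <- stats::rnorm(1, 0, 0.006)
    incs <- curv + stats::rnorm(n_steps, 0, 0.04)
    vt <- stats::runif(1, 80, 90)
    refl_u <- stats::runif(1)          # start of the reflection strip
    refl_t <- stats::runif(n_steps, spec$vessel_reflection_range[1],
                           spec$vessel_reflection_range[2])
    pts <- trace_path(layout$disc$u, layout$disc$v, ang0, incs)
    paths[[length(paths) + 1]] <-
      list(pts = pts, width = width, vt = vt, refl_u = refl_u, refl_t = refl_t)
    # branch draws are consumed unconditionally
    br_go <- stats::runif(1) < 0.5
    br_k <- sample(150:295, 1)
    br_ang <- ang0 + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.8)
    br_curv <- stats::rnorm(1, 0, 0.006)
    br_incs <- br_curv + stats::rnorm(150L, 0, 0.04)
    br_vt <- stats::runif(1, 80, 90)
    br_refl_u <- stats::runif(1)
    br_refl_t <- stats::runif(150L, spec$vessel_reflection_range[1],
                              spec$vessel_reflection_range[2])
    if (br_go && nrow(pts) > 10) {
      k <- max(5L, round(nrow(pts) * br_k / 300))  # mid-to-distal attachment
      bpts <- trace_path(pts[k, 1], pts[k, 2], br_ang, br_incs)
      paths[[length(paths) + 1]] <-
        list(pts = bpts, width = max(2 / 512, width * 0.7), vt = br_vt,
             refl_u = br_refl_u, refl_t = br_refl_t)
    }
  }
  layout$paths <- paths

  dist_to_vessels <- function(u, v) {
    d <- Inf
    for (pa in paths)
      if (nrow(pa$pts) > 0)
        d <- min(d, sqrt(min((pa$pts[, 1] - u)^2 + (pa$pts[, 2] - v)^2)) -
                   pa$width / 2)
    d
  }
  dist_to_disc <- function(u, v, margin) {
    # conservative elliptical clearance
    du <- u - layout$disc$u; dv <- v - layout$disc$v
    sqrt(du^2 + dv^2) - max(layout$disc$ru, layout$disc$rv) - margin
  }
  reject_sample <- function(class_name, half_limit, clearance, extra_ok = NULL,
                            others = list(), max_attempts = 1000L) {
    for (a in seq_len(max_attempts)) {
      u <- stats::runif(1, -FOV_RADIUS_FRAC, FOV_RADIUS_FRAC)
      v <- stats::runif(1, -FOV_RADIUS_FRAC, half_limit)
      if (u^2 + v^2 > (FOV_RADIUS_FRAC - clearance)^2) next
      if (dist_to_disc(u, v, 8 / 512) < clearance) next
      if (dist_to_vessels(u, v) < clearance + 8 / 512) next
      ok <- TRUE
      for (o in others)
        if (sqrt((o$u - u)^2 + (o$v - v)^2) < clearance + o$clearance) {
          ok <- FALSE; break
        }
      if (ok && !is.null(extra_ok) && !extra_ok(u, v)) ok <- FALSE
      if (ok) return(list(u = u, v = v, clearance = clearance))
    }
    stop("failed to place a ", class_name, " after ", max_attempts,
         " attempts: scene spec is overcrowded", call. = FALSE)
  }

  he_lo <- spec$he_gray_range[1]; he_hi <- spec$he_gray_range[2]
  he_mid <- (he_lo + he_hi) / 2

  # bright hard-exudate clusters in the macular half
  bright <- list()
  for (k in seq_len(spec$n_bright_he)) {
    ctr <- reject_sample("bright hard exudate", half_limit = 0,
                         clearance = 22 / 512, others = bright)
    n_blobs <- sample(1:8, 1)
    blobs <- vector("list", n_blobs)
    for (b in seq_len(n_blobs))
      blobs[[b]] <- list(
        u = ctr$u + max(-15, min(15, stats::rnorm(1, 0, 6))) / 512,
        v = ctr$v + max(-15, min(15, stats::rnorm(1, 0, 6))) / 512,
        ru = stats::runif(1, 1, 6) / 512, rv = stats::runif(1, 1, 6) / 512,
        t = stats::runif(1, he_mid, he_hi))
    ctr$blobs <- blobs
    bright[[k]] <- ctr
  }
  layout$bright <- bright

  # faint hard exudates: single blobs on plain, adequately lit background
  # (the green-excess bump must keep their grayscale inside the exudate
  # range, so deeply shaded ground is rejected)
  min_bg_gray <- he_lo + 1 - 0.587 * spec$faint_green_excess * 255
  lit_ok <- function(u, v) BG_GRAY * illum_gray_at(layout, u, v) >= min_bg_gray
  faint <- list()
  for (k in seq_len(spec$n_faint_he)) {
    ctr <- reject_sample("faint hard exudate", half_limit = 0,
                         clearance = 10 / 512, extra_ok = lit_ok,
                         others = c(bright, faint))
    ctr$ru <- stats::runif(1, 2, 6) / 512
    ctr$rv <- stats::runif(1, 2, 6) / 512
    faint[[k]] <- ctr
  }
  layout$faint <- faint

  # cotton-wool spots: allowed slightly past the macular half
  aspW_cws <- 0.2 * aspW * 2
  cws <- list()
  for (k in seq_len(spec$n_cws)) {
    ctr <- reject_sample("cotton-wool spot", half_limit = aspW_cws,
                         clearance = 16 / 512, others = c(bright, faint, cws))
    ctr$ru <- stats::runif(1, 5, 11) / 512
    ctr$rv <- stats::runif(1, 5, 11) / 512
    ctr$t <- stats::runif(1, (spec$cws_gray_range[1] + spec$cws_gray_range[2]) / 2,
                          spec$cws_gray_range[2])
    cws[[k]] <- ctr
  }
  layout$cws <- cws
  layout
}

# Phase 2: rasterize a layout at the spec's resolution. Only the final
# pixel noise consumes the RNG here.
render_layout <- function(layout, spec) {
  H <- spec$height; W <- spec$width
  S <- min(H, W)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  U <- (matrix(seq_len(H), H, W) - cy) / S
  V <- (matrix(seq_len(W), H, W, byrow = TRUE) - cx) / S
  sf <- S / 512                        # pixels per normalized 1/512 unit

  nellipse <- function(u0, v0, ru, rv)
    ((U - u0) / ru)^2 + ((V - v0) / rv)^2 <= 1

  # (1) field of view on near-black matting
  fov <- (U^2 + V^2) <= FOV_RADIUS_FRAC^2
  px <- array(2, c(H, W, 3))

  # (2) background under the illumination field
  tiltm <- tilt_at(layout, U, V)
  sheenm <- sheen_at(layout, U, V)
  bg_gray <- 0
  for (ch in 1:3) {
    plane <- px[, , ch]
    chv <- BG_GRAY * CHROMA$background[ch] * (1 - tiltm + SHEEN_W[ch] * sheenm)
    plane[fov] <- chv[fov]
    px[, , ch] <- plane
    bg_gray <- bg_gray + c(0.2989, 0.5870, 0.1140)[ch] * chv
  }
  illum <- bg_gray / BG_GRAY

  # (3) optic disc with a bright centre and darker rim
  d <- layout$disc
  disc <- nellipse(d$u, d$v, d$ru, d$rv) & fov
  dlo <- spec$disc_gray_range[1]; dhi <- spec$disc_gray_range[2]
  rr2 <- ((U - d$u) / d$ru)^2 + ((V - d$v) / d$rv)^2
  disc_t <- dlo + (dhi - dlo) * (0.35 + 0.65 * pmax(0, 1 - rr2))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[disc] <- pmin(255, disc_t * CHROMA$disc[ch])[disc]
    px[, , ch] <- plane
  }

  # (4) vessel tree with centerline reflection strips
  vessel <- matrix(FALSE, H, W); reflection <- matrix(FALSE, H, W)
  # linear indices of the disc of radius r around (i, j), clipped to frame
  stamp_idx <- function(i, j, r) {
    a <- max(1, floor(i - r)):min(H, ceiling(i + r))
    b <- max(1, floor(j - r)):min(W, ceiling(j + r))
    aa <- rep(a, times = length(b)); bb <- rep(b, each = length(a))
    keep <- (aa - i)^2 + (bb - j)^2 <= r^2
    aa[keep] + (bb[keep] - 1L) * H
  }
  vt_gray <- matrix(0, H, W); rt_gray <- matrix(0, H, W)
  for (pa in layout$paths) {
    if (nrow(pa$pts) == 0) next
    n <- nrow(pa$pts)
    n_refl <- max(1, round(0.3 * n))
    r0 <- 1 + floor(pa$refl_u * (n - n_refl))
    for (s in seq_len(n)) {
      i <- pa$pts[s, 1] * S + cy; j <- pa$pts[s, 2] * S + cx
      idx <- stamp_idx(i, j, pa$width / 2 * S)
      vt_gray[idx[!vessel[idx]]] <- pa$vt
      vessel[idx] <- TRUE
      if (s >= r0 && s < r0 + n_refl) {
        idr <- stamp_idx(i, j, max(0.6 * sf, 0.6))
        rt_gray[idr[!reflection[idr]]] <- pa$refl_t[s]
        reflection[idr] <- TRUE
      }
    }
  }
  vessel <- vessel & fov & !disc
  reflection <- reflection & fov & !disc
  # vessel columns are strongly dark in green but only moderately darker
  # than background in grayscale (the red plane washes out their contrast);
  # like the background they follow the illumination field
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[vessel] <- pmin(255, vt_gray * illum * CHROMA$vessel[ch])[vessel]
    plane[reflection] <- pmin(255, rt_gray * CHROMA$reflection[ch])[reflection]
    px[, , ch] <- plane
  }

  # (5) bright hard exudates
  he_bright <- matrix(FALSE, H, W)
  keepout <- disc
  for (cl in layout$bright) {
    for (b in cl$blobs) {
      blob <- nellipse(b$u, b$v, b$ru, b$rv) & fov & !keepout
      px <- paint(px, blob & !he_bright, b$t, CHROMA$he)
      he_bright <- he_bright | blob
    }
  }

  # (6) faint hard exudates: green-channel excess over local background
  he_faint <- matrix(FALSE, H, W)
  for (fl in layout$faint) {
    blob <- nellipse(fl$u, fl$v, fl$ru, fl$rv) & fov & !keepout & !he_bright
    g <- px[, , 2]
    g[blob] <- pmin(255, g[blob] + spec$faint_green_excess * 255)
    px[, , 2] <- g
    he_faint <- he_faint | blob
  }

  # (7) cotton-wool spots, blended through a 2 px Gaussian edge profile
  cws <- matrix(FALSE, H, W)
  for (cw in layout$cws) {
    blob <- nellipse(cw$u, cw$v, cw$ru, cw$rv) & fov
    target <- paint(px, blob, cw$t, CHROMA$cws)
    soft <- pmin(1, as.matrix(EBImage::gblur(blob * 1, sigma = 2)))
    for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - soft) + target[, , ch] * soft
    cws <- cws | blob
  }

  # (8) additive Gaussian noise, clipped to [0, 255]
  noise <- array(stats::rnorm(H * W * 3, 0, spec$noise_sd * 255), c(H, W, 3))
  px <- pmin(pmax(round(px + noise), 0), 255)

  truth <- structure(list(he_bright = he_bright, he_faint = he_faint,
                          cws = cws, disc = disc, vessel = vessel,
                          reflection = reflection, fov = fov,
                          placed = c(he_bright = spec$n_bright_he,
                                     he_faint = spec$n_faint_he,
                                     cws = spec$n_cws)),
                     class = "scene_truth")
  list(image = fundus_image(px, fov = fov), truth = truth, spec = spec)
}

#' Generate a synthetic fundus scene
#'
#' Deterministically renders a colour fundus scene from a
#' \code{\link{scene_spec}} and returns the image together with per-class
#' ground-truth masks recorded before blurring and noise. Construction
#' order: circular FOV (diameter 0.95 of the shorter side) on near-black
#' matting; reddish background (base RGB about 160/80/30) under a smooth
#' illumination field -- an achromatic vignetting tilt plus nasal-side
#' green-dominant sheen patches; optic disc near the nasal (right) edge;
#' 2-4 gently arcing vessel paths with one optional branch each and bright
#' centerline reflection strips over about 30\% of their length; bright
#' hard-exudate clusters (1-8 elliptical blobs each) in the macular half
#' with grayscale in the upper half of the exudate range; faint
#' hard-exudate blobs whose green channel exceeds local background by
#' \code{faint_green_excess} and whose grayscale stays in the lower half of
#' the range; fuzzy cotton-wool spots (Gaussian-blurred boundary, sd 2 px);
#' additive Gaussian pixel noise. Lesion placement is rejection sampled
#' (1000 attempts per lesion, then an error naming the class) so exudates
#' never overlap the disc, the vessel tree or cotton-wool spots.
#'
#' Because the layout is sampled in resolution-independent normalized
#' coordinates, the same seed renders the same retina at any size: pixel
#' counts scale with resolution squared while mm^2 areas are stable.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @return A list with elements \code{image} (a \code{\link{fundus_image}}
#'   with FOV attached), \code{truth} (class \code{scene_truth}: logical
#'   masks \code{he_bright}, \code{he_faint}, \code{cws}, \code{disc},
#'   \code{vessel}, \code{reflection}, \code{fov}, and \code{placed} counts
#'   per class), and \code{spec}.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  render_layout(sample_layout(spec), spec)
}

#' Per-class census of a scene's ground truth
#'
#' @param truth a \code{scene_truth} from \code{\link{generate_scene}}.
#' @return A data.frame with one row per structure class: \code{n_placed}
#'   (lesions requested and placed; NA for anatomy), \code{n_components}
#'   (8-connected components of the truth mask) and \code{pixel_count}.
#' @export
scene_census <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  classes <- c("he_bright", "he_faint", "cws", "disc", "vessel", "reflection")
  n_comp <- vapply(classes, function(cl) {
    m <- truth[[cl]]
    if (!any(m)) 0L else max(label_components(m))
  }, integer(1))
  n_px <- vapply(classes, function(cl) sum(truth[[cl]]), integer(1))
  placed <- truth$placed[classes]
  data.frame(class = classes,
             n_placed = ifelse(classes %in% names(truth$placed),
                               unname(placed), NA_integer_),
             n_components = unname(n_comp),
             pixel_count = unname(n_px),
             row.names = NULL)
}
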