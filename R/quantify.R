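# Outlier exclusion, area measurement, method comparison, percentage
# detection binning and observer-agreement statistics.

#' Axis-aligned exclusion box
#'
#' Rectangular region used to excise outlier detections (optic disc, vessel
#' reflections, cotton-wool spots). Coordinates are 0-based pixel indices,
#' half-open: the box covers columns \code{x0 <= x < x1} and rows
#' \code{y0 <= y < y1}, with x running along image width and y along height.
#'
#' @param x0,y0,x1,y1 integer pixel coordinates with \code{x0 < x1},
#'   \code{y0 < y1}.
#' @return An object of class \code{exclusion_box}.
#' @export
exclusion_box <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (anyNA(v) || !is.numeric(v)) abort_validation("box coordinates must be numeric")
  v <- round(v)
  if (v["x0"] >= v["x1"] || v["y0"] >= v["y1"])
    abort_validation("exclusion box must satisfy x0 < x1 and y0 < y1")
  structure(as.list(v), class = "exclusion_box")
}

#' Read exclusion boxes from CSV or JSON
#'
#' CSV files need a header line \code{x0,y0,x1,y1}; JSON files hold a list
#' of objects with those fields.
#'
#' @param path CSV or JSON file of box coordinates.
#' @return A list of \code{\link{exclusion_box}} objects.
#' @export
read_exclusion_boxes <- function(path) {
  if (!file.exists(path)) abort_io("cannot read boxes: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(df)))
    abort_validation("box file '", path, "' must have columns x0, y0, x1, y1")
  lapply(seq_len(nrow(df)), function(i)
    exclusion_box(df$x0[i], df$y0[i], df$x1[i], df$y1[i]))
}

#' Remove mask pixels inside exclusion boxes
#'
#' Pixels inside any box are set to \code{FALSE}; boxes are clipped to the
#' image bounds and a box entirely outside the frame is skipped with a
#' warning. This is the scripted counterpart of drawing a rectangular
#' selection over an outlier and deleting it.
#'
#' @param mask H x W logical matrix.
#' @param boxes list of \code{\link{exclusion_box}} objects (possibly empty).
#' @return The mask with excluded pixels cleared.
#' @export
apply_exclusions <- function(mask, boxes) {
  check_mask(mask)
  if (inherits(boxes, "exclusion_box")) boxes <- list(boxes)
  H <- nrow(mask); W <- ncol(mask)
  for (b in boxes) {
    stopifnot(inherits(b, "exclusion_box"))
    x0 <- max(b$x0, 0); y0 <- max(b$y0, 0)
    x1 <- min(b$x1, W); y1 <- min(b$y1, H)
    if (x0 >= x1 || y0 >= y1) {
      warning(sprintf("exclusion box [%d,%d)x[%d,%d) lies outside the %dx%d frame; ignored",
                      b$x0, b$x1, b$y0, b$y1, H, W), call. = FALSE)
      next
    }
    mask[(y0 + 1):y1, (x0 + 1):x1] <- FALSE
  }
  mask
}

#' Measure detected area
#'
#' Converts a detection mask into physical area using the isotropic pixel
#' scale: \code{area_mm2 = pixel_count * mm_per_pixel^2}, with a connected
#' component breakdown (8-connected by default) giving per-lesion areas.
#'
#' @param mask H x W logical matrix.
#' @param cal a \code{\link{calibration}}.
#' @param connectivity 4 or 8 (default 8): neighbourhood used to separate
#'   lesions.
#' @return A list of class \code{area_report} with fields
#'   \code{pixel_count}, \code{area_mm2}, \code{calibration_source},
#'   \code{n_components} and \code{components} (a data.frame of per-lesion
#'   \code{pixel_count} and \code{area_mm2}).
#' @export
measure_area <- function(mask, cal, connectivity = 8L) {
  check_mask(mask)
  if (missing(cal) || is.null(cal))
    abort_validation("no calibration: supply --mm-per-pixel or a calibration object")
  stopifnot(inherits(cal, "fundus_calibration"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) abort_validation("connectivity must be 4 or 8")
  px2 <- cal$mm_per_pixel^2
  n_px <- sum(mask)
  comp_px <- if (n_px > 0) {
    lab <- label_components(mask, connectivity)
    tabulate(lab[lab > 0])
  } else integer(0)
  structure(list(
    pixel_count = n_px,
    area_mm2 = n_px * px2,
    calibration_source = cal$source,
    n_components = length(comp_px),
    components = data.frame(pixel_count = comp_px, area_mm2 = comp_px * px2)
  ), class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("<area_report %d px = %.4f mm^2 in %d component(s), calibration %s>\n",
              x$pixel_count, x$area_mm2, x$n_components, x$calibration_source))
  invisible(x)
}

#' Compare baseline and proposed area reports
#'
#' The signed difference is baseline minus proposed, so a negative value
#' means the baseline method underestimates relative to the two-pronged
#' pipeline. The ratio baseline/proposed is reported when the proposed area
#' is nonzero, otherwise flagged undefined.
#'
#' @param baseline,proposed \code{area_report}s measured under the same
#'   calibration.
#' @return A list with \code{difference_mm2}, \code{ratio} (NA when
#'   undefined), \code{ratio_defined}, and the two input areas.
#' @export
compare_methods <- function(baseline, proposed) {
  stopifnot(inherits(baseline, "area_report"), inherits(proposed, "area_report"))
  if (!identical(baseline$calibration_source, proposed$calibration_source))
    abort_validation("area reports use different calibrations (",
                     baseline$calibration_source, " vs ", proposed$calibration_source, ")")
  defined <- proposed$area_mm2 > 0
  list(difference_mm2 = baseline$area_mm2 - proposed$area_mm2,
       ratio = if (defined) baseline$area_mm2 / proposed$area_mm2 else NA_real_,
       ratio_defined = defined,
       baseline_mm2 = baseline$area_mm2,
       proposed_mm2 = proposed$area_mm2)
}

#' Percentage of reference area detected
#'
#' Against a ground-truth mask this is the pixel recall,
#' \code{100 * |mask & truth| / |truth|}.
#'
#' @param mask H x W logical detection mask.
#' @param truth H x W logical reference mask; must be non-empty.
#' @return A value in [0, 100].
#' @export
percent_detected <- function(mask, truth) {
  check_mask(mask); check_mask(truth, "truth")
  if (!identical(dim(mask), dim(truth)))
    abort_validation("mask and truth dimensions differ")
  n_truth <- sum(truth)
  if (n_truth == 0) abort_validation("reference mask is empty: percentage undefined")
  100 * sum(mask & truth) / n_truth
}

#' Bin percentage detections into grading classes
#'
#' Counts values over the grading bins [0,30), [30,60), [60,90) and
#' [90,100]; a boundary value belongs to the upper bin except 100, which
#' closes the last bin.
#'
#' @param values numeric vector of percentages in [0, 100].
#' @return Named integer vector of counts: \code{0-30}, \code{30-60},
#'   \code{60-90}, \code{90-100}.
#' @export
bin_percentages <- function(values) {
  if (length(values) == 0)
    return(c(`0-30` = 0L, `30-60` = 0L, `60-90` = 0L, `90-100` = 0L))
  if (anyNA(values) || any(values < 0) || any(values > 100))
    abort_validation("percentages must lie in [0, 100]")
  cuts <- cut(values, breaks = c(0, 30, 60, 90, 100), right = FALSE,
              include.lowest = FALSE)
  cuts[values >= 90] <- "[90,100)"  # close the top bin at 100
  out <- as.integer(table(cuts))
  names(out) <- c("0-30", "30-60", "60-90", "90-100")
  out
}

#' Uncentered correlation coefficient
#'
#' The agreement statistic as defined for two grading series x and y:
#' \deqn{CC = \sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2}}
#' Unlike Pearson's r the series are not mean-centered, so CC rewards
#' agreement in magnitude, not only in covariation. For the centered
#' variant use \code{\link{pearson_correlation}}.
#'
#' @param x,y numeric vectors of equal length, at least 2.
#' @return A value in [-1, 1].
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    abort_validation("x and y must have equal length >= 2")
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) abort_validation("correlation undefined: a series is all zero")
  max(-1, min(1, sum(x * y) / den))
}

#' Pearson correlation (centered variant)
#'
#' @inheritParams correlation_coefficient
#' @return Pearson's r.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    abort_validation("x and y must have equal length >= 2")
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences d = x - y summarized by their mean (bias) and the
#' 1.96 SD limits of agreement, with the per-pair (mean, difference) points
#' for plotting. The SD uses the sample (N - 1) denominator.
#'
#' @param x,y numeric vectors of equal length, at least 2.
#' @return A list of class \code{bland_altman} with \code{bias},
#'   \code{lower_loa}, \code{upper_loa}, \code{sd_diff} and \code{points}
#'   (data.frame of \code{mean} and \code{difference}).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    abort_validation("x and y must have equal length >= 2")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias,
                 lower_loa = bias - 1.96 * s,
                 upper_loa = bias + 1.96 * s,
                 sd_diff = s,
                 points = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman bias %.4f, LoA [%.4f, %.4f], n = %d>\n",
              x$bias, x$lower_loa, x$upper_loa, nrow(x$points)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param ba a \code{\link{bland_altman}} result.
#' @param title optional plot title.
#' @return A ggplot object: per-pair differences against per-pair means with
#'   bias and limits of agreement as horizontal lines.
#' @export
plot_bland_altman <- function(ba, title = "Bland-Altman agreement") {
  stopifnot(inherits(ba, "bland_altman"))
  ggplot2::ggplot(ba$points, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$lower_loa, ba$upper_loa),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired gradings (%)",
                  y = "Difference (%)", title = title) +
    ggplot2::theme_minimal()
}

# ICC(A,1): two-way mixed model, absolute agreement, single measure
# (McGraw & Wong). ratings: n subjects x k raters.
icc_a1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) abort_validation("ICC needs at least 2 subjects and 2 measurements")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((sweep(sweep(ratings, 1, row_m), 2, col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (den == 0) return(1)  # zero total variance: perfect, degenerate agreement
  (MSR - MSE) / den
}

#' Grading table
#'
#' Long-format table of observer gradings: one row per
#' (image, grader, session) holding the percentage of hard-exudate area the
#' grader judged the algorithm to have detected.
#'
#' @param image_id vector of image identifiers.
#' @param grader character vector, \code{"A"} or \code{"B"}.
#' @param session integer vector, 1 or 2.
#' @param percent_detected numeric vector in [0, 100].
#' @return A validated data.frame of class \code{grading_table}.
#' @export
grading_table <- function(image_id, grader, session, percent_detected) {
  df <- data.frame(image_id = as.character(image_id),
                   grader = as.character(grader),
                   session = as.integer(session),
                   percent_detected = as.numeric(percent_detected),
                   stringsAsFactors = FALSE)
  if (!all(df$grader %in% c("A", "B")))
    abort_validation("grader must be 'A' or 'B'")
  if (!all(df$session %in% c(1L, 2L)))
    abort_validation("session must be 1 or 2")
  if (anyNA(df$percent_detected) || any(df$percent_detected < 0) ||
      any(df$percent_detected > 100))
    abort_validation("percent_detected must lie in [0, 100]")
  key <- paste(df$image_id, df$grader, df$session)
  if (anyDuplicated(key))
    abort_validation("duplicate (image_id, grader, session) rows: ",
                     paste(unique(key[duplicated(key)]), collapse = "; "))
  class(df) <- c("grading_table", "data.frame")
  df
}

#' Read a grading table from CSV
#'
#' @param path CSV with columns image_id, grader, session, percent_detected.
#' @return A \code{\link{grading_table}}.
#' @export
read_grading_table <- function(path) {
  if (!file.exists(path)) abort_io("cannot read gradings: no such file '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "grader", "session", "percent_detected")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort_validation("grading table '", path, "' is missing column(s): ",
                     paste(miss, collapse = ", "))
  grading_table(df$image_id, df$grader, df$session, df$percent_detected)
}

# Extract the two paired columns for a requested agreement mode.
grading_pair <- function(table, mode) {
  stopifnot(inherits(table, "grading_table"))
  ids <- sort(unique(table$image_id))
  pick <- function(grader, session) {
    sub <- table[table$grader == grader & table$session == session, ]
    v <- sub$percent_detected[match(ids, sub$image_id)]
    if (anyNA(v))
      abort_validation("incomplete design for grader ", grader, " session ", session,
                       ": missing image(s) ", paste(ids[is.na(v)], collapse = ", "))
    v
  }
  switch(mode,
    intra_A = cbind(pick("A", 1), pick("A", 2)),
    intra_B = cbind(pick("B", 1), pick("B", 2)),
    inter = cbind((pick("A", 1) + pick("A", 2)) / 2,
                  (pick("B", 1) + pick("B", 2)) / 2),
    abort_validation("mode must be 'intra_A', 'intra_B' or 'inter'")
  )
}

#' Intraclass correlation of observer gradings
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC over the
#' requested pairing: the two sessions of one grader (repeatability) or the
#' session-averaged scores of the two graders (reproducibility).
#'
#' @param table a \code{\link{grading_table}}.
#' @param mode \code{"intra_A"}, \code{"intra_B"} or \code{"inter"}.
#' @return A list with \code{icc} on [-1, 1] and \code{icc_percent}.
#' @export
icc_agreement <- function(table, mode = c("intra_A", "intra_B", "inter")) {
  mode <- match.arg(mode)
  m <- grading_pair(table, mode)
  icc <- icc_a1(m)
  list(icc = icc, icc_percent = 100 * icc, mode = mode, n = nrow(m))
}

#' All agreement statistics for a grading pairing
#'
#' Convenience wrapper computing the uncentered correlation, Pearson's r,
#' the ICC and Bland-Altman limits for one pairing of a grading table.
#'
#' @inheritParams icc_agreement
#' @return A list with \code{cc}, \code{pearson}, \code{icc},
#'   \code{icc_percent} and \code{bland_altman}.
#' @export
agreement_stats <- function(table, mode = c("intra_A", "intra_B", "inter")) {
  mode <- match.arg(mode)
  m <- grading_pair(table, mode)
  list(mode = mode, n = nrow(m),
       cc = correlation_coefficient(m[, 1], m[, 2]),
       pearson = pearson_correlation(m[, 1], m[, 2]),
       icc = icc_a1(m),
       icc_percent = 100 * icc_a1(m),
       bland_altman = bland_altman(m[, 1], m[, 2]))
}

#' Bounding boxes of mask components
#'
#' One \code{\link{exclusion_box}} per connected component of a mask,
#' expanded by a margin. The scripted counterpart of drawing a rectangle
#' around every outlier structure: applied to the confounder masks of a
#' synthetic scene (optic disc, cotton-wool spots, vessel reflections), it
#' reproduces the manual outlier-removal step.
#'
#' @param mask H x W logical matrix.
#' @param margin pixels added on every side of each box (default 6).
#' @param connectivity 4 or 8 (default 8).
#' @return A list of \code{\link{exclusion_box}} objects (empty for an
#'   empty mask).
#' @export
mask_bounding_boxes <- function(mask, margin = 6, connectivity = 8L) {
  check_mask(mask)
  lab <- label_components(mask, as.integer(connectivity))
  lapply(seq_len(max(lab)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    exclusion_box(max(0, min(w[, 2]) - 1 - margin),
                  max(0, min(w[, 1]) - 1 - margin),
                  max(w[, 2]) + margin, max(w[, 1]) + margin)
  })
}

#' Boxes around detected components that miss a reference mask
#'
#' Emulates the manual outlier-removal step against synthetic ground truth:
#' an observer recognizes detections that are not hard exudates (optic
#' disc, vessel reflections, cotton-wool spots, artifacts) and boxes them.
#' Every 8-connected component of \code{mask} that shares no pixel with
#' \code{reference} gets a bounding \code{\link{exclusion_box}}.
#'
#' @param mask H x W logical detection mask.
#' @param reference H x W logical mask of true target pixels.
#' @param margin pixels added on every side of each box (default 2).
#' @return A list of \code{\link{exclusion_box}} objects.
#' @export
outlier_component_boxes <- function(mask, reference, margin = 2) {
  check_mask(mask); check_mask(reference, "reference")
  if (!identical(dim(mask), dim(reference)))
    abort_validation("mask and reference dimensions differ")
  lab <- label_components(mask)
  keep <- setdiff(unique(lab[reference]), 0L)
  out <- lab > 0L
  out[lab %in% keep] <- FALSE
  mask_bounding_boxes(out, margin = margin)
}
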