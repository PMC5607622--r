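test_that("exclusion boxes clear exactly their half-open pixel ranges", {
  m <- matrix(TRUE, 20, 20)
  expect_identical(apply_exclusions(m, list()), m)
  expect_equal(sum(apply_exclusions(m, list(exclusion_box(0, 0, 20, 20)))), 0)
  # brute-force check of two overlapping boxes on random masks
  set.seed(31)
  for (rep in 1:5) {
    mask <- matrix(runif(400) > 0.4, 20, 20)
    b1 <- exclusion_box(2, 3, 10, 12); b2 <- exclusion_box(7, 8, 15, 16)
    out <- apply_exclusions(mask, list(b1, b2))
    ref <- mask
    for (i in seq_len(20)) for (j in seq_len(20)) {
      x <- j - 1; y <- i - 1
      if ((x >= 2 && x < 10 && y >= 3 && y < 12) ||
          (x >= 7 && x < 15 && y >= 8 && y < 16)) ref[i, j] <- FALSE
    }
    expect_identical(out, ref)
  }
})

test_that("exclusion never adds pixels and is idempotent", {
  set.seed(32)
  mask <- matrix(runif(900) > 0.5, 30, 30)
  boxes <- list(exclusion_box(1, 1, 8, 9), exclusion_box(20, 5, 28, 25))
  once <- apply_exclusions(mask, boxes)
  expect_lte(sum(once), sum(mask))
  expect_identical(apply_exclusions(once, boxes), once)
})

test_that("a fully out-of-bounds box warns and is ignored", {
  mask <- matrix(TRUE, 10, 10)
  expect_warning(out <- apply_exclusions(mask, list(exclusion_box(50, 50, 60, 60))),
                 "ignored")
  expect_identical(out, mask)
})

test_that("box files round-trip through CSV and JSON", {
  b <- list(exclusion_box(1, 2, 10, 12), exclusion_box(5, 5, 6, 6))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x0 = c(1, 5), y0 = c(2, 5), x1 = c(10, 6), y1 = c(12, 6)),
            csv, row.names = FALSE)
  expect_equal(read_exclusion_boxes(csv), b)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(x0 = 1, y0 = 2, x1 = 10, y1 = 12), js)
  expect_equal(read_exclusion_boxes(js), b[1])
  expect_error(exclusion_box(5, 0, 5, 10), class = "hequant_validation_error")
})

test_that("measure_area converts pixel counts with the squared pixel scale", {
  mask <- matrix(FALSE, 30, 30); mask[seq_len(100)] <- TRUE
  rep <- measure_area(mask, calibration(0.01))
  expect_identical(rep$pixel_count, 100L)
  expect_identical(rep$area_mm2, 0.01)
  empty <- measure_area(matrix(FALSE, 10, 10), calibration(0.01))
  expect_identical(empty$pixel_count, 0L)
  expect_identical(empty$area_mm2, 0)
  expect_identical(empty$n_components, 0L)
  expect_error(measure_area(mask, NULL), "mm-per-pixel",
               class = "hequant_validation_error")
})

test_that("component counts agree with a flood-fill oracle", {
  set.seed(33)
  for (rep in 1:5) {
    mask <- matrix(runif(20 * 20) > 0.6, 20, 20)
    lab <- hequant:::label_components(mask)
    ref <- bf_components(mask)
    expect_equal(max(lab), max(ref))
    # same partition: every labelled region maps 1-1
    if (max(lab) > 0)
      expect_equal(length(unique(paste(lab[mask], ref[mask]))), max(ref))
  }
  two <- matrix(FALSE, 12, 12)
  two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  rep2 <- measure_area(two, calibration(0.02))
  expect_identical(rep2$n_components, 2L)
  expect_equal(rep2$components$pixel_count, c(9L, 9L))
  # diagonal touch merges under 8-connectivity, not under 4
  diagm <- matrix(FALSE, 6, 6); diagm[2, 2] <- TRUE; diagm[3, 3] <- TRUE
  expect_identical(measure_area(diagm, calibration(1))$n_components, 1L)
  expect_identical(measure_area(diagm, calibration(1), connectivity = 4)$n_components, 2L)
})

test_that("area is additive over disjoint masks", {
  set.seed(34)
  a <- matrix(runif(625) > 0.7, 25, 25)
  b <- matrix(runif(625) > 0.7, 25, 25) & !a
  cal <- calibration(0.013)
  expect_equal(measure_area(a | b, cal)$area_mm2,
               measure_area(a, cal)$area_mm2 + measure_area(b, cal)$area_mm2)
})

test_that("method comparison reports baseline minus proposed", {
  cal <- calibration(0.01)
  mk <- function(n) { m <- matrix(FALSE, 40, 40); m[seq_len(n)] <- TRUE; measure_area(m, cal) }
  cmp <- compare_methods(mk(100), mk(200))
  expect_equal(cmp$difference_mm2, (100 - 200) * 0.0001)
  expect_lt(cmp$difference_mm2, 0)  # baseline underestimates
  expect_equal(cmp$ratio, 0.5)
  eq <- compare_methods(mk(150), mk(150))
  expect_equal(eq$difference_mm2, 0)
  und <- compare_methods(mk(0), mk(0))
  expect_false(und$ratio_defined)
  expect_true(is.na(und$ratio))
})

test_that("percent_detected is the pixel recall against truth", {
  t <- matrix(FALSE, 10, 10); t[1:4, 1:5] <- TRUE
  expect_equal(percent_detected(t, t), 100)
  expect_equal(percent_detected(matrix(FALSE, 10, 10), t), 0)
  half <- t; half[1:2, ] <- FALSE
  expect_equal(percent_detected(half, t), 50)
  expect_error(percent_detected(t, matrix(FALSE, 10, 10)),
               class = "hequant_validation_error")
})

test_that("percentage binning uses half-open bins closed at 100", {
  expect_identical(bin_percentages(c(10, 45, 75, 95)),
                   c(`0-30` = 1L, `30-60` = 1L, `60-90` = 1L, `90-100` = 1L))
  expect_identical(unname(bin_percentages(c(30, 60, 90, 100))),
                   c(0L, 1L, 1L, 2L))
  expect_identical(unname(bin_percentages(numeric(0))), rep(0L, 4))
  expect_identical(unname(bin_percentages(0)), c(1L, 0L, 0L, 0L))
  expect_error(bin_percentages(c(50, 101)), class = "hequant_validation_error")
  set.seed(35)
  v <- runif(200, 0, 100)
  expect_equal(sum(bin_percentages(v)), 200)
})

test_that("the uncentered correlation follows its closed forms", {
  expect_equal(correlation_coefficient(c(2, 5, 9), c(2, 5, 9)), 1)
  expect_equal(correlation_coefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(correlation_coefficient(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  # scale invariance and boundedness
  set.seed(36)
  for (rep in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    cc <- correlation_coefficient(x, y)
    expect_lte(abs(cc), 1)
    expect_equal(correlation_coefficient(3.7 * x, 0.2 * y), cc)
  }
  expect_error(correlation_coefficient(c(0, 0), c(1, 2)),
               class = "hequant_validation_error")
  # the uncentered statistic differs from Pearson for offset series
  x <- c(1, 2, 3); y <- c(11, 12, 13.5)
  expect_false(isTRUE(all.equal(correlation_coefficient(x, y),
                                pearson_correlation(x, y))))
})

test_that("Bland-Altman bias and limits follow the sample-SD definition", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$bias, ba0$lower_loa, ba0$upper_loa), c(0, 0, 0))
  ba <- bland_altman(c(1, 0), c(0, 1))  # differences +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$upper_loa, 1.96 * sqrt(2))
  expect_equal(ba$lower_loa, -1.96 * sqrt(2))
  # translation equivariance
  set.seed(37)
  x <- runif(20, 0, 100); y <- runif(20, 0, 100)
  b1 <- bland_altman(x, y); b2 <- bland_altman(x + 5, y)
  expect_equal(b2$bias, b1$bias + 5)
  expect_equal(b2$upper_loa - b2$lower_loa, b1$upper_loa - b1$lower_loa)
  expect_equal(nrow(b1$points), 20)
  expect_error(bland_altman(1, 1), class = "hequant_validation_error")
})

test_that("ICC(A,1) behaves over the canonical designs", {
  set.seed(38)
  x <- runif(50, 0, 100)
  tbl <- grading_table(rep(sprintf("im%02d", 1:50), 4),
                       rep(c("A", "A", "B", "B"), each = 50),
                       rep(c(1, 2, 1, 2), each = 50),
                       c(x, x, x, x))
  expect_equal(icc_agreement(tbl, "intra_A")$icc, 1)
  expect_equal(icc_agreement(tbl, "inter")$icc, 1)
  # a column plus small noise stays nearly perfectly concordant
  noisy <- grading_table(rep(sprintf("im%02d", 1:50), 2),
                         rep("A", 100), rep(c(1, 2), each = 50),
                         pmin(100, pmax(0, c(x, x + rnorm(50, 0, 1)))))
  expect_gt(icc_agreement(noisy, "intra_A")$icc, 0.95)
  # independent columns have near-zero agreement
  ind <- grading_table(rep(sprintf("im%03d", 1:200), 2),
                       rep("A", 400), rep(c(1, 2), each = 200),
                       runif(400, 0, 100))
  expect_lt(abs(icc_agreement(ind, "intra_A")$icc), 0.2)
})

test_that("grading tables validate their design", {
  expect_error(grading_table("a", "C", 1, 50), class = "hequant_validation_error")
  expect_error(grading_table("a", "A", 3, 50), class = "hequant_validation_error")
  expect_error(grading_table("a", "A", 1, 150), class = "hequant_validation_error")
  expect_error(grading_table(c("a", "a"), c("A", "A"), c(1, 1), c(10, 20)),
               "duplicate", class = "hequant_validation_error")
  tbl <- grading_table(c("a", "b"), c("A", "A"), c(1, 1), c(10, 20))
  expect_error(icc_agreement(tbl, "intra_A"), "missing",
               class = "hequant_validation_error")
})

test_that("agreement_stats ties the statistics together", {
  set.seed(39)
  x <- runif(30, 20, 90)
  tbl <- grading_table(rep(sprintf("im%02d", 1:30), 4),
                       rep(c("A", "A", "B", "B"), each = 30),
                       rep(c(1, 2, 1, 2), each = 30),
                       pmin(100, pmax(0, c(x, x + rnorm(30, 0, 2),
                                           x + rnorm(30, 0, 2),
                                           x + rnorm(30, 0, 2)))))
  st <- agreement_stats(tbl, "inter")
  expect_gt(st$cc, 0.99)
  expect_gt(st$icc, 0.9)
  expect_equal(st$icc_percent, 100 * st$icc)
  expect_lte(st$bland_altman$lower_loa, st$bland_altman$bias)
  expect_gte(st$bland_altman$upper_loa, st$bland_altman$bias)
})
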