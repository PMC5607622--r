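test_that("white top-hat matches the sliding-window oracle on small rasters", {
  set.seed(11)
  for (r in 1:3) for (rep in 1:3) {
    x <- matrix(runif(15 * 15), 15, 15)
    expect_equal(white_top_hat(x, r), bf_white_top_hat(x, r), tolerance = 1e-12)
  }
})

test_that("white top-hat of a constant image is zero and a lone peak survives", {
  expect_equal(white_top_hat(matrix(0.6, 20, 20), 4), matrix(0, 20, 20))
  x <- matrix(0, 15, 15); x[8, 8] <- 1
  th <- white_top_hat(x, 3)
  expect_equal(th[8, 8], 1)
  expect_equal(sum(th), 1)
})

test_that("white top-hat flattens a ramp but keeps a small bright blob", {
  ramp <- matrix(seq(0, 0.5, length.out = 40), 40, 40)
  x <- ramp; x[20:22, 20:22] <- x[20:22, 20:22] + 0.4
  th <- white_top_hat(x, 10)
  expect_equal(th, bf_white_top_hat(x, 10), tolerance = 1e-12)
  expect_gt(min(th[20:22, 20:22]), 0.3)
  # away from the trailing border (where the restricted window leaves a
  # slope-proportional residual) the ramp is flattened far below the blob
  interior <- ramp == x & row(x) <= 30
  expect_lt(max(th[interior]), 0.05)
})

test_that("white top-hat is invariant to a constant background offset", {
  set.seed(12)
  x <- matrix(runif(20 * 20, 0, 0.5), 20, 20)
  expect_equal(white_top_hat(x + 0.3, 3), white_top_hat(x, 3), tolerance = 1e-12)
})

test_that("white top-hat validates the structuring element size", {
  expect_error(white_top_hat(matrix(0.5, 20, 20), 10),
               class = "hequant_validation_error")
  expect_error(white_top_hat(matrix(0.5, 20, 20), 0),
               class = "hequant_validation_error")
})

test_that("adaptive equalization maps a constant image to a constant", {
  out <- adaptive_hist_eq(matrix(0.31, 64, 64))
  expect_equal(diff(range(out)), 0)
})

test_that("adaptive equalization keeps outputs in [0,1] on random rasters", {
  set.seed(13)
  for (rep in 1:3) {
    x <- matrix(runif(100 * 72), 100, 72)  # non-divisible by the tile grid
    out <- adaptive_hist_eq(x)
    expect_identical(dim(out), dim(x))
    expect_true(min(out) >= 0 && max(out) <= 1)
  }
})

test_that("a 1x1 tile grid reduces to global histogram equalization", {
  set.seed(14)
  x <- matrix(runif(64 * 64), 64, 64)
  x[1] <- 0; x[2] <- 1  # pin the range so the global stretch is the identity
  out <- adaptive_hist_eq(x, tiles = c(1, 1), clip = 1)
  glob <- as.matrix(EBImage::equalize(x, range = c(0, 1), levels = 256))
  expect_equal(out, glob, tolerance = 1e-12)
})

test_that("equalization raises the contrast of a low-contrast blob", {
  set.seed(15)
  x <- matrix(0.3 + rnorm(128 * 128, 0, 0.003), 128, 128)
  blob <- matrix(FALSE, 128, 128); blob[60:68, 60:68] <- TRUE
  x[blob] <- x[blob] + 0.04
  x <- pmin(pmax(x, 0), 1)
  out <- adaptive_hist_eq(x)
  contrast_in <- mean(x[blob]) - mean(x[!blob])
  contrast_out <- mean(out[blob]) - mean(out[!blob])
  expect_gt(contrast_out, contrast_in)
})

test_that("binarize uses a strict inequality and is monotone in the threshold", {
  x <- matrix(c(0.5, 0.37, 0.1, 0.99), 2, 2)
  m <- binarize(x, 0.37)
  expect_true(m[1, 1])
  expect_false(m[2, 1])  # exactly at threshold
  set.seed(16)
  y <- matrix(runif(50 * 50), 50, 50)
  expect_true(all(binarize(y, 0.8) <= binarize(y, 0.4)))
  expect_error(binarize(y, 0), class = "hequant_validation_error")
  expect_error(binarize(y, 1), class = "hequant_validation_error")
})

test_that("combine_masks is union with the expected algebraic laws", {
  set.seed(17)
  a <- matrix(runif(30 * 30) > 0.5, 30, 30)
  b <- matrix(runif(30 * 30) > 0.5, 30, 30)
  c_ <- matrix(runif(30 * 30) > 0.5, 30, 30)
  empty <- matrix(FALSE, 30, 30)
  expect_identical(combine_masks(a, empty), a)
  expect_identical(combine_masks(a, a), a)
  expect_identical(combine_masks(a, b), combine_masks(b, a))
  expect_identical(combine_masks(combine_masks(a, b), c_),
                   combine_masks(a, combine_masks(b, c_)))
  expect_equal(sum(combine_masks(a, b)), sum(a) + sum(b) - sum(a & b))
  expect_error(combine_masks(a, matrix(FALSE, 10, 10)),
               class = "hequant_validation_error")
})

test_that("step masks are subsets of the field of view", {
  run <- cached_run(1)
  fov <- run$scene$truth$fov
  expect_true(all(fov[run$m1]))
  expect_true(all(fov[run$m2]))
})

test_that("step 1 alone finds every bright exudate component", {
  for (s in 1:2) {
    sc <- cached_scene(s, n_faint_he = 0L, n_cws = 0L)
    m1 <- detect_step1(sc$image)
    expect_equal(component_overlap(m1, sc$truth$he_bright), 1)
  }
})

test_that("step 2 finds faint exudates that step 1 misses", {
  for (s in 1:2) {
    sc <- cached_scene(s, n_bright_he = 0L, n_cws = 0L)
    m1 <- detect_step1(sc$image)
    m2 <- detect_step2(sc$image)
    expect_gte(component_overlap(m2, sc$truth$he_faint), 0.8)
    expect_lt(component_overlap(m1, sc$truth$he_faint), 0.5)
  }
})

test_that("step 2 also fires on bright exudates (the union never loses them)", {
  run <- cached_run(2)
  un <- run$union
  expect_true(all(un[run$m2]))
  expect_equal(component_overlap(un, run$scene$truth$he_bright), 1)
})

test_that("an all-black image yields an empty detection mask", {
  img <- fundus_image(array(0L, c(64, 64, 3)))
  expect_equal(sum(detect_step1(img)), 0)
  expect_equal(sum(detect_step2(img)), 0)
})

test_that("detection is deterministic end to end", {
  sc <- cached_scene(3)
  expect_identical(detect_he(sc$image), detect_he(sc$image))
})

test_that("detect_params validates its ranges", {
  expect_error(detect_params(step1_threshold = 0), class = "hequant_validation_error")
  expect_error(detect_params(step2_threshold = 1.2), class = "hequant_validation_error")
  expect_error(detect_params(step1_radius_frac = 0.7), class = "hequant_validation_error")
  expect_error(detect_params(clahe_clip = 0), class = "hequant_validation_error")
})
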