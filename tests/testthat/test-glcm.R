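test_that("quantization follows the equal-width binning definition", {
  v <- matrix(0:255, 16, 16)
  msk <- matrix(TRUE, 16, 16)
  lev <- quantize(v, msk, n_levels = 8L)
  expect_identical(lev, matrix(as.integer(pmin(floor(8 * (0:255) / 255), 7)), 16, 16))
  # affine rescaling leaves minmax levels unchanged
  lev2 <- quantize(2.5 * v + 11, msk, n_levels = 8L)
  expect_identical(lev, lev2)
  # constant region: all level 0 with a warning, not an error
  expect_warning(levc <- quantize(matrix(5, 4, 4), matrix(TRUE, 4, 4), 8L),
                 "constant")
  expect_true(all(levc == 0L))
  # unmasked pixels excluded
  msk[1, ] <- FALSE
  expect_true(all(is.na(quantize(v, msk, 8L)[1, ])))
})

test_that("GLCM on vertical stripes matches hand enumeration", {
  # columns alternate 0,1: horizontal neighbours always differ,
  # vertical neighbours never do
  lev <- matrix(rep(c(0L, 1L), 2), 4, 4, byrow = TRUE)
  g0 <- compute_glcm(lev, d = 1L, angle = 0, symmetric = TRUE, n_levels = 2L)
  expect_equal(g0$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  g90 <- compute_glcm(lev, d = 1L, angle = 90, symmetric = TRUE, n_levels = 2L)
  expect_equal(g90$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("a constant masked region gives the single-cell GLCM", {
  lev <- matrix(0L, 4, 4)
  for (a in c(0, 45, 90, 135)) {
    g <- compute_glcm(lev, d = 1L, angle = a, n_levels = 8L)
    expect_equal(g$p[1, 1], 1)
    expect_equal(sum(g$p), 1)
  }
})

test_that("GLCMs normalize to one and symmetric GLCMs equal their transpose", {
  set.seed(31)
  for (rep in 1:20) {
    lev <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
    lev[matrix(runif(144) < 0.3, 12, 12)] <- NA   # random mask holes
    a <- sample(c(0, 45, 90, 135), 1)
    g <- compute_glcm(lev, d = 1L, angle = a, symmetric = TRUE, n_levels = 8L)
    if (g$n_pairs > 0) {
      expect_equal(sum(g$p), 1, tolerance = 1e-12)
      expect_equal(g$p, t(g$p), tolerance = 1e-12)
      expect_true(all(g$p >= 0))
    }
  }
})

test_that("pairs straddling the mask boundary are excluded", {
  lev <- matrix(c(0L, 1L, NA, 0L), 1, 4)
  g <- compute_glcm(lev, d = 1L, angle = 0, symmetric = FALSE, n_levels = 2L)
  expect_equal(g$n_pairs, 1)          # only the (0,1) pair at columns 1-2
  expect_equal(g$p[1, 2], 1)
})

test_that("empty-GLCM sentinel arises when no pair exists and haralick_13 rejects it", {
  lev <- matrix(NA_integer_, 3, 3)
  lev[2, 2] <- 1L
  g <- compute_glcm(lev, d = 1L, angle = 0, n_levels = 2L)
  expect_equal(g$n_pairs, 0)
  expect_error(haralick_13(g), "no valid pixel pairs")
})

test_that("constant-image descriptors take their closed-form values", {
  lev <- matrix(0L, 6, 6)
  f <- haralick_13(compute_glcm(lev, 1L, 0, n_levels = 8L))
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["idm"]), 1)
  expect_equal(unname(f["sum_average"]), 0)
})

test_that("stripe GLCM descriptors match the hand computation", {
  # p(0,1) = p(1,0) = 0.5: contrast 1, ASM 0.5, entropy 1 bit
  g <- structure(list(p = matrix(c(0, 0.5, 0.5, 0), 2, 2), n_levels = 2L,
                      d = 1L, angle = 0, symmetric = TRUE, n_pairs = 24),
                 class = "glcm")
  f <- haralick_13(g)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["asm"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)
})

test_that("haralick_13 agrees with the brute-force double-sum oracle to 1e-10", {
  set.seed(99)
  for (rep in 1:100) {
    g <- random_glcm(G = 8L, symmetric = rep %% 2 == 0)
    expect_equal(haralick_13(g), brute_haralick(g$p), tolerance = 1e-10)
  }
})

test_that("descriptors respect their analytic bounds on random GLCMs", {
  set.seed(123)
  for (rep in 1:25) {
    f <- haralick_13(random_glcm(G = 8L))
    expect_gt(f["asm"], 0); expect_lte(f["asm"], 1)
    expect_gte(f["entropy"], 0)
    expect_gt(f["idm"], 0); expect_lte(f["idm"], 1)
    expect_gte(f["imc2"], 0)
    expect_true(all(is.finite(f)))
  }
})

test_that("the 26-vector is finite, range-nonnegative, and isotropy zeroes the ranges", {
  p <- generate_nucleus_image(tiny_panel()[[1]], 128L, seed = 8L)
  lm <- segment_pair(p)
  roi <- extract_rois(p, lm)[[1]]
  prof <- haralick_profile(roi$sc35, roi$mask)
  expect_length(prof, 26L)
  expect_true(all(is.finite(prof)))
  expect_true(all(prof[14:26] >= 0))
  expect_identical(names(prof), haralick_profile_names("range"))
  # constant ROI: every direction sees the same GLCM, so all ranges vanish
  suppressWarnings(
    prof0 <- haralick_profile(matrix(1, 10, 10), matrix(TRUE, 10, 10)))
  expect_true(all(abs(prof0[14:26]) < 1e-14))
})

test_that("horizontal stripes separate the 0- and 90-degree contrasts", {
  roi <- matrix(rep(c(0, 1), 6), 12, 12)   # value = row parity
  msk <- matrix(TRUE, 12, 12)
  lev <- quantize(roi, msk, 2L)
  c0 <- haralick_13(compute_glcm(lev, 1L, 0, n_levels = 2L))["contrast"]
  c90 <- haralick_13(compute_glcm(lev, 1L, 90, n_levels = 2L))["contrast"]
  expect_false(isTRUE(all.equal(c0, c90)))
  prof <- haralick_profile(roi, msk, n_levels = 2L)
  expect_gt(prof[["f02_range"]], 0)
})

test_that("rotating a nucleus by 90 degrees leaves the 26-vector unchanged", {
  p <- generate_nucleus_image(tiny_panel()[[2]], 128L, seed = 12L)
  lm <- segment_pair(p)
  roi <- extract_rois(p, lm)[[1]]
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  a <- haralick_profile(roi$sc35, roi$mask)
  b <- haralick_profile(rot90(roi$sc35), rot90(roi$mask))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("feature vectors are invariant to positive affine intensity rescaling under minmax", {
  p <- generate_nucleus_image(tiny_panel()[[1]], 128L, seed = 21L)
  lm <- segment_pair(p)
  roi <- extract_rois(p, lm)[[1]]
  a <- haralick_profile(roi$sc35, roi$mask, strategy = "minmax")
  b <- haralick_profile(1.7 * roi$sc35 + 0.3, roi$mask, strategy = "minmax")
  expect_equal(a, b, tolerance = 1e-10)
})
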