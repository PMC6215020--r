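test_that("Otsu matches exhaustive between-class-variance search", {
  # two-value image: 75% at 10, 25% at 200 -> foreground is the 200s
  v <- c(rep(10, 75), rep(200, 25))
  img <- matrix(v[sample.int(100)], 10, 10)
  res <- threshold_dna(img, method = "otsu")
  expect_identical(unname(res$mask), matrix(img == 200, 10, 10))
  # random gray images: package threshold classifies pixels exactly like the
  # brute-force exhaustive threshold
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    got <- threshold_dna(m, method = "otsu")
    want <- brute_otsu(as.numeric(m))
    expect_identical(got$mask, m > want)
  }
})

test_that("fixed thresholding and degenerate inputs behave as documented", {
  img <- matrix(runif(64, 1, 2), 8, 8)
  expect_true(all(threshold_dna(img, "fixed", fixed_value = 0)$mask))
  expect_error(threshold_dna(matrix(0, 4, 4), "otsu"), "degenerate")
  expect_error(threshold_dna(img, "fixed"), "fixed_value")
})

test_that("Otsu is invariant under positive affine intensity rescaling", {
  set.seed(7)
  m <- matrix(sample(0:100, 900, replace = TRUE), 30, 30)
  a <- threshold_dna(m, "otsu")$mask
  b <- threshold_dna(3.2 * m + 17, "otsu")$mask
  expect_identical(a, b)
})

disk_mask <- function(n, cr, cc, r) {
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

test_that("labeling filters small components and respects the border policy", {
  n <- 100L
  bin <- disk_mask(n, 25, 25, 9.8) | disk_mask(n, 25, 75, 9.8) |
    disk_mask(n, 75, 50, 2.4)
  # disk areas: ~301, ~301 and ~21 pixels (pi r^2); min_area 50 removes one
  lm <- label_nuclei(bin, min_area_px = 50L)
  expect_equal(lm$n_nuclei, 2L)
  expect_true(all(abs(lm$table$area_px - pi * 9.8^2) < 15))
  # labels are consecutive and raster-ordered
  expect_identical(sort(unique(as.vector(lm$labels[lm$labels > 0]))), 1:2)
  # border policy
  edge <- disk_mask(n, 3, 50, 6)
  expect_equal(label_nuclei(edge, 10L, border_policy = "discard")$n_nuclei, 0L)
  expect_equal(label_nuclei(edge, 10L, border_policy = "keep")$n_nuclei, 1L)
  # empty input is allowed
  expect_equal(label_nuclei(matrix(FALSE, 5, 5))$n_nuclei, 0L)
})

test_that("labeled areas conserve the cleaned foreground and holes fill", {
  n <- 60L
  ring <- disk_mask(n, 30, 30, 15) & !disk_mask(n, 30, 30, 6)
  filled <- label_nuclei(ring, min_area_px = 10L, fill_holes = TRUE)
  open <- label_nuclei(ring, min_area_px = 10L, fill_holes = FALSE)
  expect_equal(filled$table$area_px, sum(disk_mask(n, 30, 30, 15)))
  expect_equal(open$table$area_px, sum(ring))
  expect_equal(sum(filled$labels > 0), sum(filled$table$area_px))
})

test_that("components touching only diagonally merge into one 8-connected nucleus", {
  bin <- matrix(FALSE, 20, 20)
  bin[5:9, 5:9] <- TRUE
  bin[10:14, 10:14] <- TRUE   # touches the first block corner-to-corner
  lm <- label_nuclei(bin, min_area_px = 5L, fill_holes = FALSE,
                     border_policy = "keep")
  expect_equal(lm$n_nuclei, 1L)
  expect_equal(lm$table$area_px, 50L)
})

test_that("segmenting a generated image recovers one nucleus at the true area", {
  for (s in c(2L, 11L, 23L)) {
    p <- generate_nucleus_image(tiny_panel()[[1]], 256L, seed = s)
    lm <- segment_pair(p)
    expect_equal(lm$n_nuclei, 1L)
    expect_lt(abs(lm$table$area_px / p$geometry$area_px - 1), 0.10)
  }
})

test_that("ROI extraction conserves label areas and rejects mismatched shapes", {
  p <- generate_nucleus_image(tiny_panel()[[2]], 128L, seed = 4L)
  lm <- segment_pair(p)
  rois <- extract_rois(p, lm)
  expect_length(rois, lm$n_nuclei)
  expect_equal(sum(rois[[1]]$mask), lm$table$area_px[1])
  bad <- lm
  bad$labels <- bad$labels[1:64, 1:64]
  expect_error(extract_rois(p, bad), "shapes differ")
  # whole-image single label returns the full SC-35 channel
  whole <- label_nuclei(matrix(TRUE, 16, 16), min_area_px = 1L,
                        border_policy = "keep")
  fake <- structure(list(sc35 = matrix(1:256, 16, 16),
                         dna = matrix(1, 16, 16)),
                    class = "nucleus_image_pair")
  r <- extract_rois(fake, whole)
  expect_identical(r[[1]]$sc35, fake$sc35)
  expect_true(all(r[[1]]$mask))
})
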