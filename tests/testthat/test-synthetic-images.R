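test_that("spec validation names the offending field", {
  expect_error(texture_class_spec("a", speckle_count_mean = -1),
               "speckle_count_mean")
  expect_error(texture_class_spec("a", clustering_strength = 1.2),
               "clustering_strength")
  expect_error(texture_class_spec("a", speckle_radius_px = 0),
               "speckle_radius_px")
  expect_error(texture_class_spec("a", noise_sd = -0.1), "noise_sd")
  expect_error(texture_class_spec(""), "class_name")
})

test_that("image generation is bit-reproducible for a fixed seed and differs across seeds", {
  sp <- tiny_panel()[[1]]
  a <- generate_nucleus_image(sp, 128L, seed = 5L)
  b <- generate_nucleus_image(sp, 128L, seed = 5L)
  expect_identical(a$sc35, b$sc35)
  expect_identical(a$dna, b$dna)
  d <- generate_nucleus_image(sp, 128L, seed = 6L)
  expect_false(identical(a$sc35, d$sc35))
})

test_that("channels are co-registered, nonnegative, and the ellipse covers 20-60% of the field", {
  sp <- tiny_panel()[[2]]
  for (s in 1:5) {
    p <- generate_nucleus_image(sp, 128L, seed = s)
    expect_identical(dim(p$dna), dim(p$sc35))
    expect_gte(min(p$dna), 0)
    expect_gte(min(p$sc35), 0)
    frac <- p$geometry$area_px / p$size_px^2
    expect_gt(frac, 0.20)
    expect_lt(frac, 0.60)
  }
})

test_that("DNA interior is brighter than the exterior so masking is well posed", {
  p <- generate_nucleus_image(tiny_panel()[[1]], 128L, seed = 3L)
  g <- p$geometry
  n <- p$size_px
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  q <- speckletex:::ellipse_q(rows, cols, g$center[1], g$center[2],
                              g$semi_axes[1], g$semi_axes[2], g$orientation)
  expect_gt(min(p$dna[q < 0.8]), max(p$dna[q > 1.3]))
})

test_that("detected blob count on the truth map matches the Poisson intensity", {
  # 200 nuclei at density 50; blobs kept small and unclustered so the
  # unblurred truth map resolves them as distinct local maxima
  sp <- texture_class_spec("poisson_check", speckle_count_mean = 50,
                           speckle_radius_px = 1.2,
                           clustering_strength = 0, speckle_intensity = 1)
  counts <- vapply(1:200, function(s) {
    p <- generate_nucleus_image(sp, 320L, seed = 4000 + s,
                                keep_truth_map = TRUE)
    count_local_maxima(p$truth$speckle_map, 0.3)
  }, numeric(1))
  # the generator scales the Poisson mean by realized area / reference area;
  # that scaling averages to ~1 over nuclei, so E[count] ~= 50
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se + 1)
})

test_that("vanishing speckle density leaves a flat background inside the nucleus", {
  bg <- 0.4
  sp <- texture_class_spec("flat", speckle_count_mean = 1e-9,
                           background_level = bg, noise_sd = 0.02,
                           speckle_intensity = 1)
  p <- generate_nucleus_image(sp, 128L, seed = 2L)
  expect_identical(p$truth$n_speckles, 0L)
  g <- p$geometry
  n <- p$size_px
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  q <- speckletex:::ellipse_q(rows, cols, g$center[1], g$center[2],
                              g$semi_axes[1], g$semi_axes[2], g$orientation)
  inner <- p$sc35[q < 0.8]
  expect_lt(abs(mean(inner) - bg), 0.01)
  expect_lt(stats::sd(inner), 3 * sp$noise_sd)
})

test_that("dataset generation books n_per_class images per class with derived seeds", {
  ds <- generate_image_dataset(tiny_panel(), n_per_class = 5L, size_px = 128L,
                               seed = 7L)
  expect_length(ds$pairs, 10L)
  expect_equal(as.vector(table(ds$labels)), c(5L, 5L))
  expect_equal(anyDuplicated(ds$manifest$seed), 0L)
  dup <- tiny_panel(); dup[[2]]$class_name <- "fine"
  expect_error(generate_image_dataset(dup, 2L, 128L, 1L), "duplicate")
  expect_error(generate_image_dataset(tiny_panel()[1], 2L, 128L, 1L),
               "2 distinct")
})

test_that("reordering class specs permutes the dataset but leaves per-class images identical", {
  ds1 <- generate_image_dataset(tiny_panel(), 3L, 128L, seed = 9L)
  ds2 <- generate_image_dataset(rev(tiny_panel()), 3L, 128L, seed = 9L)
  pick <- function(ds, cl, i) ds$pairs[[which(ds$labels == cl)[i]]]$sc35
  for (cl in c("fine", "coarse")) for (i in 1:3) {
    expect_identical(pick(ds1, cl, i), pick(ds2, cl, i))
  }
})

test_that("a new master seed changes images but not the label structure", {
  ds1 <- generate_image_dataset(tiny_panel(), 2L, 128L, seed = 1L)
  ds2 <- generate_image_dataset(tiny_panel(), 2L, 128L, seed = 2L)
  expect_identical(ds1$labels, ds2$labels)
  expect_false(identical(ds1$pairs[[1]]$sc35, ds2$pairs[[1]]$sc35))
})

test_that("default panels are valid and pairwise distinct in at least two fields", {
  for (panel in list(enhancer_panel_specs(), inhibitor_panel_specs(),
                     os72_panel_specs())) {
    nms <- vapply(panel, `[[`, character(1), "class_name")
    expect_equal(anyDuplicated(nms), 0L)
    fields <- c("speckle_count_mean", "speckle_radius_px",
                "clustering_strength", "speckle_intensity",
                "background_level")
    for (i in seq_along(panel)[-1]) for (j in seq_len(i - 1)) {
      ndiff <- sum(vapply(fields, function(f)
        !isTRUE(all.equal(panel[[i]][[f]], panel[[j]][[f]])), logical(1)))
      expect_gte(ndiff, 2)
    }
  }
  expect_length(enhancer_panel_specs(), 6L)
  expect_length(inhibitor_panel_specs(), 6L)
  expect_length(os72_panel_specs(), 7L)
})

test_that("default enhancer panel separates every class pair in mean contrast", {
  # per-class mean Haralick contrast must differ between classes by more
  # than the within-class SD (24 nuclei/class keeps the check tractable;
  # gaps were designed against larger samples)
  stats_for <- function(sp) {
    v <- vapply(1:24, function(i) {
      p <- generate_nucleus_image(sp, 512L,
                                  seed = derive_seed_for_test(sp$class_name, i))
      roi <- extract_rois(p, segment_pair(p))[[1]]
      do.call(haralick_profile,
              c(list(roi$sc35, roi$mask), default_glcm_params()))[["f02_mean"]]
    }, numeric(1))
    c(mean(v), sd(v))
  }
  derive_seed_for_test <- function(key, i) speckletex:::derive_seed(777L, key, i)
  st <- vapply(enhancer_panel_specs(), stats_for, numeric(2))
  for (i in seq_len(ncol(st) - 1)) for (j in (i + 1):ncol(st)) {
    expect_gt(abs(st[1, i] - st[1, j]), max(st[2, i], st[2, j]))
  }
})
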