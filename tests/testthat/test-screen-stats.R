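make_screen_rows <- function(cond, assay, readings, day = 14L) {
  data.frame(well_id = sprintf("%s_w%02d", cond, seq_along(readings)),
             condition = cond, assay = assay, day = day, reading = readings,
             stringsAsFactors = FALSE)
}

test_that("ALP normalization is the per-well ratio and is scale invariant", {
  scr <- rbind(make_screen_rows("c", "ALP", c(10, 12)),
               make_screen_rows("c", "DNA", c(2, 3)))
  expect_equal(unname(normalize_alp(scr, "c")), c(5, 4))
  scr2 <- scr
  scr2$reading <- scr2$reading * 7
  expect_equal(normalize_alp(scr2, "c"), normalize_alp(scr, "c"))
  scr$reading[scr$assay == "DNA"][1] <- 0
  expect_error(normalize_alp(scr, "c"), "c_w01")
})

test_that("ALP wells lacking a DNA partner are dropped with a message", {
  scr <- rbind(make_screen_rows("c", "ALP", c(10, 12, 14)),
               make_screen_rows("c", "DNA", c(2, 3)))
  expect_message(v <- normalize_alp(scr, "c"), "dropped")
  expect_length(v, 2L)
})

test_that("fold change returns the mean ratio with a covering bootstrap CI", {
  expect_equal(fold_change(c(7, 7), c(2, 2))$fold, 3.5)
  expect_equal(fold_change(c(4, 5), c(4, 5))$fold, 1)
  expect_error(fold_change(c(1, 2), c(0, 0)), "zero")
  set.seed(3)
  fc <- fold_change(rnorm(12, 5, 0.3), rnorm(12, 2, 0.2))
  expect_lt(fc$ci[1], fc$fold)
  expect_gt(fc$ci[2], fc$fold)
  # deterministic given the fixed bootstrap seed
  expect_identical(fold_change(c(5, 5.2), c(2, 2.1))$ci,
                   fold_change(c(5, 5.2), c(2, 2.1))$ci)
})

test_that("viability percentages follow the mean-ratio definition", {
  scr <- rbind(make_screen_rows("t", "MTS", c(0.7, 0.7)),
               make_screen_rows("u", "MTS", c(1, 1)))
  expect_equal(viability_percent(scr, "t", "u", 14L), 70)
  expect_equal(viability_percent(scr, "u", "u", 14L), 100)
  expect_error(viability_percent(scr, "t", "u", 0L), "day 0")
})

test_that("Dunnett with one group reduces to the pooled two-sample t test", {
  set.seed(8)
  g <- rnorm(8, 1, 1); ctrl <- rnorm(8, 0, 1)
  dt <- dunnett_test(list(g = g), ctrl)
  tt <- t.test(g, ctrl, var.equal = TRUE)
  expect_equal(dt$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(dt$p_adjusted[1], tt$p.value, tolerance = 5e-4)
})

test_that("an overwhelming shift is flagged at the 1% level", {
  set.seed(9)
  groups <- lapply(1:5, function(i) rnorm(6))
  names(groups) <- paste0("g", 1:5)
  groups$g3 <- groups$g3 + 10
  dt <- dunnett_test(groups, rnorm(6))
  expect_true(dt$sig_01[dt$condition == "g3"])
  expect_lt(dt$p_adjusted[dt$condition == "g3"], 0.01)
})

test_that("adjusted p is monotone in |t|, bounded by the unadjusted p, and valid", {
  set.seed(10)
  groups <- lapply(c(0, 0.5, 1, 2, 4), function(d) rnorm(6, d))
  names(groups) <- paste0("g", 1:5)
  dt <- dunnett_test(groups, rnorm(6))
  ord <- order(abs(dt$t))
  expect_true(all(diff(dt$p_adjusted[ord]) <= 1e-6))
  expect_true(all(dt$p_adjusted >= dt$p_unadjusted - 1e-12))
  expect_true(all(dt$p_adjusted >= 0 & dt$p_adjusted <= 1))
  expect_error(dunnett_test(list(a = c(1, 2), b = 3), c(1, 2)), "n >= 2")
})

test_that("Dunnett adjusted p agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(11)
  k <- 4
  dat <- data.frame(
    y = c(rnorm(6, 0), rnorm(6, 0.8), rnorm(6, 0.3), rnorm(6, -0.9),
          rnorm(6, 1.5)),
    g = factor(rep(c("ctrl", "t1", "t2", "t3", "t4"), each = 6),
               levels = c("ctrl", "t1", "t2", "t3", "t4")))
  groups <- split(dat$y, dat$g)
  dt <- dunnett_test(groups[-1], groups$ctrl)
  gh <- multcomp::glht(stats::aov(y ~ g, dat),
                       linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(gh, test = multcomp::adjusted("single-step"))
  expect_equal(unname(dt$t), unname(ref$test$tstat), tolerance = 1e-10)
  expect_equal(unname(dt$p_adjusted), unname(as.numeric(ref$test$pvalues)),
               tolerance = 2e-3)
})

test_that("hit ranking applies the fold and significance rules with alphabetical ties", {
  summaries <- data.frame(
    condition = c("big", "mid", "flat", "down", "tie_b", "tie_a"),
    fold_change = c(3.5, 2.5, 1.0, 0.55, 2.0, 2.0))
  dunnett <- data.frame(
    condition = summaries$condition,
    p_adjusted = c(0.001, 0.01, 0.9, 0.02, 0.03, 0.03))
  h <- rank_hits(summaries, dunnett, top_k = 10L, alpha = 0.05)
  expect_identical(h$enhancers$condition, c("big", "mid", "tie_a", "tie_b"))
  expect_identical(h$inhibitors$condition, "down")
  h2 <- rank_hits(summaries, dunnett, top_k = 2L, alpha = 0.05)
  expect_identical(h2$enhancers$condition, c("big", "mid"))
  none <- rank_hits(summaries,
                    transform(dunnett, p_adjusted = 1), 10L, 0.05)
  expect_equal(nrow(none$enhancers), 0L)
  expect_equal(nrow(none$inhibitors), 0L)
})

test_that("screen summaries integrate normalization, folds and viability", {
  cfg <- enhancer_screen_effects(cv = 0)
  scr <- generate_screen(cfg$effects, cfg$controls, seed = 2L)
  s <- summarize_screen(scr)
  gem <- s[s$condition == "gemcitabine", ]
  expect_equal(gem$fold_change, 3.5)
  expect_equal(gem$viability_day14, 70)
  expect_equal(gem$viability_day0, 100)
  expect_equal(s$fold_change[s$condition == "os_untreated"], 1)
  chid <- s[s$condition == "chidamide", ]
  expect_equal(chid$adipo_fold, 0.75)
})
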