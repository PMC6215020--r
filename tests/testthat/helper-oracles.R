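# Independent oracles and shared fixtures for the test suite.

# --- brute-force Haralick descriptors -------------------------------------
# Literal double-sum implementations of f1-f13 straight from the defining
# formulas (no marginal shortcuts), used to cross-check haralick_13().
brute_haralick <- function(p) {
  G <- nrow(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sdx <- 0; sdy <- 0
  for (i in 1:G) {
    sdx <- sdx + (i - 1 - mux)^2 * px[i]
    sdy <- sdy + (i - 1 - muy)^2 * py[i]
  }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)
  psum <- numeric(2 * G - 1); pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  f1 <- 0; f2 <- 0; f3n <- 0; f4 <- 0; f5 <- 0; f9 <- 0
  for (i in 1:G) for (j in 1:G) {
    f1 <- f1 + p[i, j]^2
    f3n <- f3n + (i - 1) * (j - 1) * p[i, j]
    f4 <- f4 + (i - 1 - mux)^2 * p[i, j]
    f5 <- f5 + p[i, j] / (1 + (i - j)^2)
    f9 <- f9 - p[i, j] * lg(p[i, j])
  }
  for (k in 0:(G - 1)) f2 <- f2 + k^2 * pdiff[k + 1]
  f3 <- if (sdx * sdy > 0) (f3n - mux * muy) / (sdx * sdy) else 0
  f6 <- 0
  for (k in 0:(2 * G - 2)) f6 <- f6 + k * psum[k + 1]
  f7 <- 0; f8 <- 0
  for (k in 0:(2 * G - 2)) {
    f7 <- f7 + (k - f6)^2 * psum[k + 1]
    f8 <- f8 - psum[k + 1] * lg(psum[k + 1])
  }
  mud <- 0
  for (k in 0:(G - 1)) mud <- mud + k * pdiff[k + 1]
  f10 <- 0; f11 <- 0
  for (k in 0:(G - 1)) {
    f10 <- f10 + (k - mud)^2 * pdiff[k + 1]
    f11 <- f11 - pdiff[k + 1] * lg(pdiff[k + 1])
  }
  hx <- 0; hy <- 0
  for (i in 1:G) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    difference_variance = f10, difference_entropy = f11, imc1 = f12,
    imc2 = f13)
}

random_glcm <- function(G = 8L, symmetric = TRUE) {
  m <- matrix(stats::rexp(G * G), G, G)
  if (symmetric) m <- m + t(m)
  m <- m / sum(m)
  structure(list(p = m, n_levels = G, d = 1L, angle = 0, symmetric = symmetric,
                 n_pairs = 1000), class = "glcm")
}

# --- brute-force Otsu ------------------------------------------------------
# Exhaustive between-class variance over every observed intensity as a
# candidate threshold (foreground strictly above).
brute_otsu <- function(v) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  best <- cand[1]; best_bcv <- -Inf
  for (t in cand) {
    bg <- v[v <= t]; fg <- v[v > t]
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best_bcv + 1e-12) { best_bcv <- bcv; best <- t }
  }
  best
}

# --- brute-force gain ratio ------------------------------------------------
# Enumerates every midpoint threshold of every feature and returns the best
# (gain ratio, feature, threshold) by the documented tie-break.
brute_best_split <- function(X, y, min_leaf = 2L) {
  y <- factor(y)
  n <- length(y)
  ent <- function(yy) {
    pr <- table(yy) / length(yy); pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }
  H <- ent(y)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    vs <- sort(unique(X[, f]))
    if (length(vs) < 2) next
    for (m in seq_len(length(vs) - 1)) {
      thr <- (vs[m] + vs[m + 1]) / 2
      l <- X[, f] <= thr
      nl <- sum(l); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      gain <- H - (nl / n) * ent(y[l]) - (nr / n) * ent(y[!l])
      if (gain <= 1e-12) next
      si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
      ratio <- gain / si
      if (is.null(best) || ratio > best$ratio + 1e-12) {
        best <- list(feature = f, threshold = thr, ratio = ratio, gain = gain)
      }
    }
  }
  best
}

# --- misc fixtures ---------------------------------------------------------
# Tiny two-class panel for fast end-to-end runs.
tiny_panel <- function() {
  list(texture_class_spec("fine", speckle_count_mean = 70,
                          speckle_radius_px = 1.5,
                          clustering_strength = 0.05,
                          speckle_intensity = 1.3),
       texture_class_spec("coarse", speckle_count_mean = 20,
                          speckle_radius_px = 3.5,
                          clustering_strength = 0.5,
                          speckle_intensity = 0.85))
}

# Count strict 3x3-neighbourhood local maxima above `thresh` (used as the
# blob-count oracle on the generator's unblurred truth map).
count_local_maxima <- function(m, thresh) {
  nr <- nrow(m); nc <- ncol(m)
  core <- m[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thresh
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- m[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
    is_max <- is_max & core > nb
  }
  sum(is_max)
}

# Session-level cache so expensive panel runs are computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
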