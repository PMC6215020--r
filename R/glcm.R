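#' Quantize masked intensities to gray levels
#'
#' Maps masked pixels to integer levels 0..G-1 by equal-width binning, either
#' over the masked min-max range (`strategy = "minmax"`, which makes the
#' downstream texture descriptors invariant to positive affine rescaling of
#' the intensities) or over a caller-supplied `global_range`. Unmasked pixels
#' become `NA` and are excluded from co-occurrence counting.
#'
#' @param sc35_roi numeric matrix.
#' @param mask logical matrix, same shape.
#' @param n_levels number of gray levels G (>= 2).
#' @param strategy `"minmax"` or `"global"`.
#' @param global_range length-2 numeric range for `strategy = "global"`.
#' @return integer matrix of levels with `NA` outside the mask.
#' @export
quantize <- function(sc35_roi, mask, n_levels = 32L,
                     strategy = c("minmax", "global"), global_range = NULL) {
  strategy <- match.arg(strategy)
  if (!identical(dim(sc35_roi), dim(mask))) stop("roi and mask shapes differ")
  if (n_levels < 2L) stop_field("n_levels", "must be >= 2")
  v <- sc35_roi[mask]
  if (!length(v)) stop("mask selects no pixels")
  if (strategy == "global") {
    if (is.null(global_range) || length(global_range) != 2L)
      stop("'global_range' (length 2) required for strategy = 'global'")
    lo <- global_range[1]; hi <- global_range[2]
  } else {
    lo <- min(v); hi <- max(v)
  }
  out <- matrix(NA_integer_, nrow(sc35_roi), ncol(sc35_roi))
  if (hi <= lo) {
    warning("constant masked region: all pixels assigned level 0")
    out[mask] <- 0L
    return(out)
  }
  lev <- floor(n_levels * (v - lo) / (hi - lo))
  out[mask] <- as.integer(pmin(pmax(lev, 0), n_levels - 1L))
  out
}

# (row, col) pixel offsets of the four canonical GLCM directions at distance d
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs (p1, p2) at the given distance and direction
#' where both pixels lie inside the mask (pairs straddling the mask boundary
#' are excluded), optionally symmetrized by also counting each pair reversed,
#' and normalizes by the total pair count.
#'
#' @param levels integer level matrix from [quantize()] (`NA` = excluded).
#' @param d pair distance in pixels (>= 1).
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @param symmetric count each pair in both orders.
#' @param n_levels number of gray levels G; defaults to `max(levels) + 1`.
#' @return an object of class `glcm`: list with the normalized matrix `p`
#'   (G x G), `n_levels`, `d`, `angle`, `symmetric` and `n_pairs` (raw pair
#'   count; 0 signals the empty-GLCM sentinel).
#' @export
compute_glcm <- function(levels, d = 1L, angle = 0, symmetric = TRUE,
                         n_levels = NULL) {
  if (d < 1) stop_field("d", "must be >= 1")
  G <- as.integer(n_levels %||% (max(levels, na.rm = TRUE) + 1L))
  off <- glcm_offset(angle, as.integer(d))
  nr <- nrow(levels); nc <- ncol(levels)
  r0 <- max(1L, 1L - off[1]); r1 <- min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(nc, nc - off[2])
  counts <- numeric(G * G)
  if (r0 <= r1 && c0 <= c1) {
    A <- levels[r0:r1, c0:c1, drop = FALSE]
    B <- levels[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]),
                drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (any(ok)) {
      a <- A[ok]; b <- B[ok]
      counts <- tabulate(a * G + b + 1L, G * G)
      if (symmetric) counts <- counts + tabulate(b * G + a + 1L, G * G)
    }
  }
  total <- sum(counts)
  p <- matrix(if (total > 0) counts / total else 0, G, G, byrow = TRUE)
  structure(list(p = p, n_levels = G, d = as.integer(d), angle = angle,
                 symmetric = symmetric, n_pairs = total),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm: G=%d, d=%d, angle=%s, %s, %g pairs>\n", x$n_levels,
              x$d, x$angle, if (x$symmetric) "symmetric" else "asymmetric",
              x$n_pairs))
  invisible(x)
}

#' The 13 Haralick texture descriptors of a GLCM
#'
#' Computes Haralick's descriptors f1-f13 from a normalized co-occurrence
#' matrix: angular second moment, contrast, correlation, sum of squares
#' variance, inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance, difference entropy, and the two
#' information measures of correlation. Conventions: gray levels are indexed
#' 0..G-1; entropies use log base 2 with 0 log 0 := 0; correlation is 0 when
#' either marginal standard deviation is 0; the sum-variance centre is the
#' sum average; f13's radicand is clamped at 0. The maximal correlation
#' coefficient (f14) is not computed.
#'
#' @param glcm a `glcm` object with at least one valid pair.
#' @return named numeric vector of length 13 (`asm`, `contrast`,
#'   `correlation`, `variance`, `idm`, `sum_average`, `sum_variance`,
#'   `sum_entropy`, `entropy`, `difference_variance`, `difference_entropy`,
#'   `imc1`, `imc2`).
#' @export
haralick_13 <- function(glcm) {
  if (!inherits(glcm, "glcm")) stop("'glcm' must be a glcm object")
  if (glcm$n_pairs <= 0) stop("no valid pixel pairs")
  p <- glcm$p
  G <- glcm$n_levels
  i <- matrix(0:(G - 1L), G, G)       # row index (first pixel level)
  j <- t(i)
  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum((0:(G - 1)) * px)
  mu_y <- sum((0:(G - 1)) * py)
  sd_x <- sqrt(sum(((0:(G - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(G - 1)) - mu_y)^2 * py))

  # diagonal distributions p_{x+y}(k), k=0..2G-2 and p_{|x-y|}(k), k=0..G-1
  psum_full <- as.numeric(rowsum(as.numeric(p), as.numeric(i + j) + 1))
  psum_tmp <- numeric(2 * G - 1)
  psum_tmp[sort(unique(as.numeric(i + j))) + 1L] <- psum_full
  psum_full <- psum_tmp
  pdiff <- numeric(G)
  pdiff[sort(unique(as.numeric(abs(i - j)))) + 1L] <-
    as.numeric(rowsum(as.numeric(p), as.numeric(abs(i - j))))

  ks <- 0:(2 * G - 2)
  kd <- 0:(G - 1)

  f1 <- sum(p^2)
  f2 <- sum(kd^2 * pdiff)
  f3 <- if (sd_x * sd_y > 0) (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y) else 0
  f4 <- sum((i - mu_x)^2 * p)
  f5 <- sum(p / (1 + (i - j)^2))
  f6 <- sum(ks * psum_full)
  f7 <- sum((ks - f6)^2 * psum_full)
  f8 <- -sum(psum_full * log2z(psum_full))
  f9 <- -sum(p * log2z(p))
  mu_d <- sum(kd * pdiff)
  f10 <- sum((kd - mu_d)^2 * pdiff)
  f11 <- -sum(pdiff * log2z(pdiff))

  hx <- -sum(px * log2z(px))
  hy <- -sum(py * log2z(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxy))
  hxy2 <- -sum(pxy * log2z(pxy))
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - f9))))

  c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    difference_variance = f10, difference_entropy = f11, imc1 = f12,
    imc2 = f13)
}
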