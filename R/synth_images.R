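#' Texture class specification for synthetic SC-35 nuclei
#'
#' Describes one cell-state class of the synthetic image generator. Each
#' nucleus of the class carries a Poisson number of speckles (Gaussian blobs)
#' whose density, size, spatial clustering and brightness shape the SC-35
#' texture that the gray-level co-occurrence descriptors respond to.
#'
#' @param class_name class label.
#' @param speckle_count_mean expected number of speckles per nucleus (> 0).
#' @param speckle_radius_px mean blob scale (Gaussian sigma, pixels, > 0);
#'   per-blob radii are drawn with ~10\% lognormal dispersion.
#' @param clustering_strength fraction in \[0, 1\] of speckles placed near a
#'   previously placed speckle rather than uniformly in the nucleus.
#' @param speckle_intensity mean foreground amplitude (arbitrary units, >= 0);
#'   per-blob amplitudes carry ~10\% lognormal dispersion.
#' @param background_level diffuse nucleoplasmic SC-35 amplitude (>= 0).
#' @param psf_sigma_px Gaussian point-spread blur scale in pixels (>= 0).
#' @param noise_sd additive Gaussian read-noise standard deviation (>= 0).
#' @return an object of class `texture_class_spec`.
#' @export
texture_class_spec <- function(class_name,
                               speckle_count_mean = 40,
                               speckle_radius_px = 2.5,
                               clustering_strength = 0.2,
                               speckle_intensity = 1.0,
                               background_level = 0.15,
                               psf_sigma_px = 1.0,
                               noise_sd = 0.02) {
  if (!is.character(class_name) || length(class_name) != 1L || !nzchar(class_name))
    stop_field("class_name", "must be a non-empty string")
  if (!is.numeric(speckle_count_mean) || speckle_count_mean <= 0)
    stop_field("speckle_count_mean", "must be > 0")
  if (!is.numeric(speckle_radius_px) || speckle_radius_px <= 0)
    stop_field("speckle_radius_px", "must be > 0")
  if (!is.numeric(clustering_strength) || clustering_strength < 0 ||
      clustering_strength > 1)
    stop_field("clustering_strength", "must lie in [0, 1]")
  if (!is.numeric(speckle_intensity) || speckle_intensity < 0)
    stop_field("speckle_intensity", "must be >= 0")
  if (!is.numeric(background_level) || background_level < 0)
    stop_field("background_level", "must be >= 0")
  if (!is.numeric(psf_sigma_px) || psf_sigma_px < 0)
    stop_field("psf_sigma_px", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_field("noise_sd", "must be >= 0")
  structure(list(class_name = class_name,
                 speckle_count_mean = speckle_count_mean,
                 speckle_radius_px = speckle_radius_px,
                 clustering_strength = clustering_strength,
                 speckle_intensity = speckle_intensity,
                 background_level = background_level,
                 psf_sigma_px = psf_sigma_px,
                 noise_sd = noise_sd),
            class = "texture_class_spec")
}

#' @export
print.texture_class_spec <- function(x, ...) {
  cat(sprintf("<texture_class_spec '%s': count %.3g, radius %.3g px, clustering %.2f, intensity %.3g>\n",
              x$class_name, x$speckle_count_mean, x$speckle_radius_px,
              x$clustering_strength, x$speckle_intensity))
  invisible(x)
}

# Gaussian blur of a plain matrix via EBImage, preserving matrix type.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::gblur(EBImage::Image(m), sigma = sigma)
  matrix(EBImage::imageData(out), nrow = nrow(m))
}

# Add a Gaussian blob of scale `r` and amplitude `amp` centred at (cr, cc)
# into matrix `m` (in place value-wise; returns the updated matrix).
add_blob <- function(m, cr, cc, r, amp) {
  n <- nrow(m)
  w <- max(2L, ceiling(3 * r))
  r0 <- max(1L, floor(cr) - w); r1 <- min(n, floor(cr) + w)
  c0 <- max(1L, floor(cc) - w); c1 <- min(ncol(m), floor(cc) + w)
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1; cols <- c0:c1
  dr2 <- (rows - cr)^2
  dc2 <- (cols - cc)^2
  m[rows, cols] <- m[rows, cols] + amp * exp(-outer(dr2, dc2, "+") / (2 * r^2))
  m
}

#' Generate one synthetic two-channel nucleus image
#'
#' Draws an elliptical nucleus covering 20--60\% of the field. The DNA channel
#' is a smooth bright disk (radial falloff, PSF blur, read noise) suitable for
#' intensity-based masking; the SC-35 channel is the class's diffuse
#' background plus a Poisson number of Gaussian speckle blobs, placed
#' uniformly in the nucleus or, with probability `clustering_strength`, near a
#' previously placed speckle, then convolved with the PSF and degraded with
#' additive Gaussian noise (clipped at zero).
#'
#' The Poisson speckle count is `speckle_count_mean` for a nucleus at the
#' reference area (35\% of the field) and scales proportionally with the
#' realized nuclear area, making speckle density the class-level trait.
#'
#' @param spec a [texture_class_spec()].
#' @param size_px field edge length in pixels (>= 64).
#' @param seed integer RNG seed; the output is bit-reproducible in
#'   (spec, size_px, seed).
#' @param keep_truth_map keep the unblurred, noise-free speckle map in the
#'   `truth` slot (memory-heavy; used by generator diagnostics).
#' @return an object of class `nucleus_image_pair`: list with matrices `dna`
#'   and `sc35` (co-registered, intensities >= 0), `size_px`, `bit_depth`
#'   (16; storage quantization — computation is floating point),
#'   `geometry` (ellipse centre, semi-axes, orientation, area), `class_name`,
#'   `seed`, and `truth` (speckle count and centres; optionally the map).
#' @export
generate_nucleus_image <- function(spec, size_px = 512L, seed = 1L,
                                   keep_truth_map = FALSE) {
  if (!inherits(spec, "texture_class_spec"))
    stop("'spec' must be a texture_class_spec")
  if (size_px < 64) stop_field("size_px", "must be >= 64")
  with_seed(seed, {
    n <- as.integer(size_px)

    # nucleus ellipse: area fraction 0.25-0.50 of the field (inside the
    # 20-60% envelope), mild eccentricity and random orientation
    area_frac <- stats::runif(1, 0.25, 0.50)
    aspect <- stats::runif(1, 0.70, 1.00)
    a <- sqrt(area_frac * n^2 / (pi * aspect))   # semi-major (px)
    b <- a * aspect
    theta <- stats::runif(1, 0, pi)
    cr <- n / 2 + stats::runif(1, -0.04, 0.04) * n
    cc <- n / 2 + stats::runif(1, -0.04, 0.04) * n

    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    xr <- (rows - cr) * cos(theta) + (cols - cc) * sin(theta)
    yr <- -(rows - cr) * sin(theta) + (cols - cc) * cos(theta)
    q <- (xr / a)^2 + (yr / b)^2          # <= 1 inside the ellipse
    inside <- q <= 1

    # DNA channel: bright interior with gentle radial falloff over a dim
    # exterior, so threshold masking is well posed
    dna <- matrix(0.02, n, n)
    dna[inside] <- 0.70 + 0.30 * (1 - q[inside])
    dna <- gaussian_blur(dna, 2.0)
    dna <- dna + matrix(stats::rnorm(n * n, 0, 0.01), n, n)
    dna <- pmax(dna, 0)

    # SC-35 channel: diffuse background + clustered speckle blobs.
    # The expected count refers to a nucleus at the reference area (35% of
    # the field) and scales with the realized nuclear area, so speckle
    # density — not raw count — is the class-level trait.
    area_scale <- (pi * a * b) / (0.35 * n^2)
    n_speckles <- stats::rpois(1, spec$speckle_count_mean * area_scale)
    centers <- matrix(numeric(0), ncol = 2)
    truth_map <- matrix(0, n, n)
    if (n_speckles > 0) {
      centers <- matrix(NA_real_, n_speckles, 2)
      for (k in seq_len(n_speckles)) {
        clustered <- k > 1 && stats::runif(1) < spec$clustering_strength
        pos <- NULL
        if (clustered) {
          anchor <- centers[sample.int(k - 1L, 1L), ]
          for (try in 1:20) {
            cand <- anchor + stats::rnorm(2, 0, 2 * spec$speckle_radius_px)
            qq <- ellipse_q(cand[1], cand[2], cr, cc, a, b, theta)
            if (qq <= 1) { pos <- cand; break }
          }
        }
        if (is.null(pos)) {
          repeat {
            cand <- c(stats::runif(1, cr - a, cr + a),
                      stats::runif(1, cc - a, cc + a))
            if (ellipse_q(cand[1], cand[2], cr, cc, a, b, theta) <= 1) {
              pos <- cand; break
            }
          }
        }
        centers[k, ] <- pos
        amp <- spec$speckle_intensity * stats::rlnorm(1, -0.005, 0.1)
        rad <- spec$speckle_radius_px * stats::rlnorm(1, -0.005, 0.1)
        truth_map <- add_blob(truth_map, pos[1], pos[2], rad, amp)
      }
    }
    sc35 <- matrix(0.01, n, n)
    sc35[inside] <- spec$background_level
    sc35 <- sc35 + truth_map
    sc35 <- gaussian_blur(sc35, spec$psf_sigma_px)
    sc35 <- sc35 + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    sc35 <- pmax(sc35, 0)

    structure(list(dna = dna, sc35 = sc35,
                   size_px = n, bit_depth = 16L,
                   geometry = list(center = c(row = cr, col = cc),
                                   semi_axes = c(a = a, b = b),
                                   orientation = theta,
                                   area_px = pi * a * b),
                   class_name = spec$class_name,
                   seed = as.integer(seed),
                   truth = list(n_speckles = n_speckles,
                                centers = centers,
                                speckle_map = if (keep_truth_map) truth_map)),
              class = "nucleus_image_pair")
  })
}

ellipse_q <- function(r, c, cr, cc, a, b, theta) {
  xr <- (r - cr) * cos(theta) + (c - cc) * sin(theta)
  yr <- -(r - cr) * sin(theta) + (c - cc) * cos(theta)
  (xr / a)^2 + (yr / b)^2
}

#' @export
print.nucleus_image_pair <- function(x, ...) {
  cat(sprintf("<nucleus_image_pair '%s': %d x %d px, %d speckles, seed %d>\n",
              x$class_name, x$size_px, x$size_px, x$truth$n_speckles, x$seed))
  invisible(x)
}

#' Generate a labeled multi-class image dataset
#'
#' Produces `n_per_class` images for each class. Every image gets its own
#' seed derived from the master seed, the class *name* and the replicate
#' index, so reordering the spec list permutes the output but leaves each
#' class's images bit-identical (label equivariance).
#'
#' @param specs list of [texture_class_spec()] with >= 2 distinct class names.
#' @param n_per_class images per class (>= 1).
#' @param size_px field edge length.
#' @param seed master seed.
#' @return list with `pairs` (list of `nucleus_image_pair`), `labels`
#'   (character vector) and `manifest` (data.frame of class, replicate, seed).
#' @export
generate_image_dataset <- function(specs, n_per_class, size_px = 512L,
                                   seed = 1L) {
  nms <- vapply(specs, function(s) s$class_name, character(1))
  if (anyDuplicated(nms)) stop("duplicate class names in 'specs'")
  if (length(nms) < 2L) stop("need at least 2 distinct classes")
  if (n_per_class < 1L) stop_field("n_per_class", "must be >= 1")
  manifest <- data.frame(class = rep(nms, each = n_per_class),
                         replicate = rep(seq_len(n_per_class), length(nms)),
                         stringsAsFactors = FALSE)
  manifest$seed <- mapply(derive_seed, key = manifest$class,
                          index = manifest$replicate,
                          MoreArgs = list(master_seed = seed))
  pairs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sp <- specs[[match(manifest$class[i], nms)]]
    pairs[[i]] <- generate_nucleus_image(sp, size_px = size_px,
                                         seed = manifest$seed[i])
  }
  list(pairs = pairs, labels = manifest$class, manifest = manifest)
}

#' Default texture-class panels
#'
#' Parameter tables for the synthetic cell-state panels used throughout the
#' package. `enhancer_panel_specs()` is the default 6-class table: untreated
#' cells plus five analogs of osteogenesis-enhancing epigenetic drugs, with
#' pairwise differences in at least two generator fields (speckle density,
#' blob radius, clustering, amplitude). `inhibitor_panel_specs()` applies
#' offsets 1.5x those of the enhancer panel (clustering clipped to \[0, 1\]),
#' giving wider class separation, as analogs of the five
#' osteogenesis-inhibiting drugs. `os72_panel_specs()` is a 7-class panel for
#' the 72-hour post-induction comparison: a basal class plus six
#' osteogenic-context classes (untreated + five drug analogs) whose texture
#' baseline is shifted by the differentiation context.
#'
#' @return named list of [texture_class_spec()].
#' @export
enhancer_panel_specs <- function() {
  base <- list(count = 40, r = 2.5, clus = 0.20, amp = 1.0)
  offs <- enhancer_offsets()
  specs <- list(texture_class_spec("untreated",
                                   speckle_count_mean = base$count,
                                   speckle_radius_px = base$r,
                                   clustering_strength = base$clus,
                                   speckle_intensity = base$amp))
  for (nm in names(offs)) {
    o <- offs[[nm]]
    specs[[length(specs) + 1L]] <- texture_class_spec(
      nm,
      speckle_count_mean = base$count + o[1],
      speckle_radius_px = base$r + o[2],
      clustering_strength = min(1, max(0, base$clus + o[3])),
      speckle_intensity = base$amp + o[4])
  }
  names(specs) <- vapply(specs, `[[`, character(1), "class_name")
  specs
}

# offsets (d_count, d_radius, d_clustering, d_intensity) of the five
# enhancer-drug analogs relative to the untreated baseline; spaced so that
# mean Haralick contrast separates every class pair beyond one within-class
# SD under the pipeline's detector-referenced quantization
enhancer_offsets <- function() {
  list(gemcitabine_analog = c(+35, -0.8, -0.12, +0.30),
       decitabine_analog  = c(-14, +1.1, +0.10, -0.20),
       icbp112_analog     = c(+15, -0.4, +0.25, +0.15),
       chidamide_analog   = c(0, -1.0, -0.08, +0.45),
       sirt12iv_analog    = c(-10, +0.5, +0.60, -0.10))
}

#' @rdname enhancer_panel_specs
#' @export
inhibitor_panel_specs <- function() {
  base <- list(count = 40, r = 2.5, clus = 0.20, amp = 1.0)
  offs <- enhancer_offsets()
  nms <- c("iodosaha_analog", "scriptaid_analog", "agk2_analog",
           "clamidine_analog", "delphinidin_analog")
  specs <- list(texture_class_spec("untreated",
                                   speckle_count_mean = base$count,
                                   speckle_radius_px = base$r,
                                   clustering_strength = base$clus,
                                   speckle_intensity = base$amp))
  for (i in seq_along(nms)) {
    o <- 1.5 * offs[[i]]
    specs[[length(specs) + 1L]] <- texture_class_spec(
      nms[i],
      speckle_count_mean = max(5, base$count + o[1]),
      speckle_radius_px = max(0.9, base$r + o[2]),
      clustering_strength = min(1, max(0, base$clus + o[3])),
      speckle_intensity = max(0.3, base$amp + o[4]))
  }
  names(specs) <- vapply(specs, `[[`, character(1), "class_name")
  specs
}

#' @rdname enhancer_panel_specs
#' @export
os72_panel_specs <- function() {
  offs <- enhancer_offsets()
  # osteogenic context shifts the texture baseline: denser speckling and a
  # brighter diffuse background than basal culture
  ctx <- list(count = 48, r = 2.5, clus = 0.20, amp = 1.0, bg = 0.20)
  specs <- list(
    texture_class_spec("basal",
                       speckle_count_mean = 40, speckle_radius_px = 2.5,
                       clustering_strength = 0.20, speckle_intensity = 1.0,
                       background_level = 0.15),
    texture_class_spec("os_untreated",
                       speckle_count_mean = ctx$count, speckle_radius_px = ctx$r,
                       clustering_strength = ctx$clus, speckle_intensity = ctx$amp,
                       background_level = ctx$bg))
  for (nm in names(offs)) {
    o <- offs[[nm]]
    specs[[length(specs) + 1L]] <- texture_class_spec(
      paste0("os_", sub("_analog$", "", nm)),
      speckle_count_mean = ctx$count + o[1],
      speckle_radius_px = ctx$r + o[2],
      clustering_strength = min(1, max(0, ctx$clus + o[3])),
      speckle_intensity = ctx$amp + o[4],
      background_level = ctx$bg)
  }
  names(specs) <- vapply(specs, `[[`, character(1), "class_name")
  specs
}
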