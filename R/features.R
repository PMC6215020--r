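#' Descriptor names of the 26-feature Haralick profile
#'
#' Column order of the per-nucleus feature vector: 13 per-descriptor means
#' over the four GLCM directions (`f01_mean` .. `f13_mean`) followed by the
#' 13 per-descriptor ranges (or SDs) over the same directions
#' (`f01_range` .. `f13_range`).
#'
#' @param aggregation `"range"` or `"sd"` (affects the suffix only).
#' @return character vector of length 26.
#' @export
haralick_profile_names <- function(aggregation = "range") {
  base <- sprintf("f%02d", 1:13)
  c(paste0(base, "_mean"), paste0(base, "_", aggregation))
}

#' Descriptor key: fNN codes to descriptor names
#' @return data.frame mapping `code` to `descriptor`.
#' @export
haralick_descriptor_key <- function() {
  data.frame(code = sprintf("f%02d", 1:13),
             descriptor = c("asm", "contrast", "correlation", "variance",
                            "idm", "sum_average", "sum_variance",
                            "sum_entropy", "entropy", "difference_variance",
                            "difference_entropy", "imc1", "imc2"),
             stringsAsFactors = FALSE)
}

#' Per-nucleus 26-descriptor Haralick profile
#'
#' Quantizes the masked SC-35 region, computes the GLCM at the four canonical
#' directions (0, 45, 90, 135 degrees), evaluates the 13 Haralick descriptors
#' for each, and aggregates across directions as the per-descriptor mean plus
#' the per-descriptor range (max - min; the default) or standard deviation.
#'
#' @param sc35_roi numeric matrix (cropped SC-35 channel).
#' @param mask logical matrix flagging in-nucleus pixels.
#' @param n_levels gray levels G for quantization.
#' @param d pair distance in pixels.
#' @param symmetric symmetric GLCM.
#' @param aggregation `"range"` or `"sd"` across the four directions.
#' @param strategy,global_range passed to [quantize()].
#' @return named numeric vector of length 26 (see
#'   [haralick_profile_names()]), with attributes recording the quantization
#'   metadata.
#' @export
haralick_profile <- function(sc35_roi, mask, n_levels = 32L, d = 1L,
                             symmetric = TRUE,
                             aggregation = c("range", "sd"),
                             strategy = "minmax", global_range = NULL) {
  aggregation <- match.arg(aggregation)
  lev <- quantize(sc35_roi, mask, n_levels = n_levels, strategy = strategy,
                  global_range = global_range)
  per_angle <- sapply(c(0, 45, 90, 135), function(a) {
    g <- compute_glcm(lev, d = d, angle = a, symmetric = symmetric,
                      n_levels = n_levels)
    haralick_13(g)
  })                                   # 13 x 4
  means <- rowMeans(per_angle)
  spread <- if (aggregation == "range") {
    apply(per_angle, 1, max) - apply(per_angle, 1, min)
  } else {
    apply(per_angle, 1, stats::sd)
  }
  out <- c(means, spread)
  names(out) <- haralick_profile_names(aggregation)
  attr(out, "glcm_params") <- list(n_levels = n_levels, d = d,
                                   symmetric = symmetric,
                                   aggregation = aggregation)
  out
}

#' Build the labeled per-nucleus feature matrix
#'
#' Segments each image pair (unless masks are supplied), extracts per-nucleus
#' SC-35 regions, and computes the 26-descriptor profile for every nucleus.
#' Rows carrying any non-finite descriptor are dropped with a message.
#'
#' @param pairs list of `nucleus_image_pair`.
#' @param masks optional list of `labeled_mask` matching `pairs`; if `NULL`
#'   each pair is segmented with [segment_pair()] and `seg_params`.
#' @param glcm_params list of [haralick_profile()] parameters.
#' @param seg_params list of [segment_pair()] parameters.
#' @return data.frame with `nucleus_id` (image index + in-image label),
#'   `class`, and the 26 feature columns.
#' @export
build_feature_matrix <- function(pairs, masks = NULL,
                                 glcm_params = list(), seg_params = list()) {
  if (!length(pairs)) stop("empty dataset")
  rows <- vector("list", length(pairs))
  for (ii in seq_along(pairs)) {
    pair <- pairs[[ii]]
    msk <- if (is.null(masks)) {
      do.call(segment_pair, c(list(pair), seg_params))
    } else masks[[ii]]
    if (msk$n_nuclei == 0L) next
    rois <- extract_rois(pair, msk)
    feats <- lapply(rois, function(roi)
      do.call(haralick_profile, c(list(roi$sc35, roi$mask), glcm_params)))
    rows[[ii]] <- data.frame(
      nucleus_id = sprintf("img%04d_n%02d", ii,
                           vapply(rois, `[[`, integer(1), "nucleus_id")),
      class = pair$class_name,
      do.call(rbind, feats),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no nuclei found in any image")
  rownames(out) <- NULL
  finite <- apply(as.matrix(out[, -(1:2)]), 1, function(r) all(is.finite(r)))
  if (any(!finite)) {
    message(sum(!finite), " nuclei dropped for non-finite descriptors")
    out <- out[finite, , drop = FALSE]
  }
  out
}

#' Write / read a feature matrix as CSV
#'
#' Plain-text round trip of the labeled feature table
#' (`nucleus_id,class,f01_mean,...,f13_range`).
#'
#' @param features data.frame from [build_feature_matrix()].
#' @param path file path.
#' @return `read_feature_csv` returns the data.frame.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export a feature matrix as ARFF
#'
#' Writes the labeled feature table in ARFF so external decision-tree
#' implementations can cross-check the classifier. Requires the `foreign`
#' package.
#'
#' @param features data.frame from [build_feature_matrix()].
#' @param path output path.
#' @export
write_feature_arff <- function(features, path) {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop("package 'foreign' required for ARFF export")
  df <- features
  df$class <- factor(df$class)
  df$nucleus_id <- NULL
  foreign::write.arff(df, path)
  invisible(path)
}
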