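#' Threshold the DNA channel to a nuclear foreground mask
#'
#' Intensity-based thresholding of the DNA (Hoechst) channel, the first step
#' of the image pipeline. With `method = "otsu"` the threshold maximizes the
#' between-class variance of the intensity distribution by exhaustive search
#' over every boundary between consecutive distinct values (ties resolved to
#' the lowest threshold). With `method = "fixed"` the caller supplies the
#' threshold. Foreground is strictly above the threshold.
#'
#' @param dna_channel numeric matrix of DNA intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold for `method = "fixed"`.
#' @return list with `mask` (logical matrix) and `threshold` (numeric).
#' @export
threshold_dna <- function(dna_channel, method = c("otsu", "fixed"),
                          fixed_value = NULL) {
  method <- match.arg(method)
  if (!is.matrix(dna_channel) || length(dna_channel) == 0L)
    stop("'dna_channel' must be a non-empty matrix")
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("'fixed_value' required for method = 'fixed'")
    thr <- fixed_value
  } else {
    thr <- otsu_threshold(as.numeric(dna_channel))
  }
  list(mask = dna_channel > thr, threshold = thr)
}

# Otsu's method, exact: exhaustive maximization of the between-class
# variance w0*w1*(mu0 - mu1)^2 over every boundary between consecutive
# distinct sorted intensities; ties resolve to the lowest threshold.
otsu_threshold <- function(v) {
  if (min(v) == max(v)) stop("degenerate histogram: constant image")
  vs <- sort(v)
  n <- length(vs)
  cs <- cumsum(vs)
  i <- which(vs[-n] < vs[-1])           # last index of each lower group
  w0 <- i / n
  w1 <- 1 - w0
  mu0 <- cs[i] / i
  mu1 <- (cs[n] - cs[i]) / (n - i)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(bcv)                # ties -> lowest threshold
  vs[i[best]]
}

#' Label nuclei in a binary mask
#'
#' Extracts 8-connected components, optionally fills interior holes, removes
#' components smaller than `min_area_px`, and with
#' `border_policy = "discard"` removes components touching the image edge.
#' Surviving labels are re-indexed 1..n consecutively in raster-scan order
#' (row-major) of each component's first pixel. Coordinates are 0-based
#' (row, col); bounding boxes are half-open.
#'
#' @param binary logical matrix.
#' @param min_area_px minimum component area in pixels.
#' @param fill_holes fill interior holes before labeling.
#' @param border_policy `"discard"` (default) or `"keep"` components touching
#'   the image border.
#' @return an object of class `labeled_mask`: list with `labels` (integer
#'   matrix, 0 background), `n_nuclei` and `table`
#'   (`nucleus_id, area_px, centroid_row, centroid_col,
#'   bbox_row0, bbox_row1, bbox_col0, bbox_col1`).
#' @export
label_nuclei <- function(binary, min_area_px = 200L, fill_holes = TRUE,
                         border_policy = c("discard", "keep")) {
  border_policy <- match.arg(border_policy)
  if (!is.matrix(binary)) stop("'binary' must be a matrix")
  bw <- matrix(as.numeric(binary), nrow(binary))
  if (fill_holes && any(bw > 0))
    bw <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(bw))),
                 nrow(bw))
  lab <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))),
                nrow(bw))
  lab <- merge_diagonal_labels(lab)

  if (!any(lab > 0L))
    return(empty_labeled_mask(dim(binary)))

  areas <- tabulate(lab[lab > 0L])
  keep <- areas >= min_area_px
  if (border_policy == "discard") {
    nr <- nrow(lab); nc <- ncol(lab)
    border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    keep[border_labels[border_labels > 0L]] <- FALSE
  }
  if (!any(keep)) return(empty_labeled_mask(dim(binary)))

  # re-index survivors by raster-scan (row-major) order of first pixel
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows0 <- (idx - 1L) %% nr          # 0-based row
  cols0 <- (idx - 1L) %/% nr         # 0-based col
  raster <- rows0 * ncol(lab) + cols0
  first_pix <- tapply(raster, l, min)
  old_ids <- as.integer(names(first_pix))
  surv <- old_ids[keep[old_ids]]
  surv <- surv[order(first_pix[as.character(surv)])]
  remap <- integer(max(old_ids))
  remap[surv] <- seq_along(surv)
  new_lab <- matrix(0L, nr, ncol(lab))
  in_keep <- remap[l] > 0L & l %in% surv
  new_lab[idx[in_keep]] <- remap[l[in_keep]]

  tab <- do.call(rbind, lapply(seq_along(surv), function(k) {
    pix <- which(new_lab == k)
    r0 <- (pix - 1L) %% nr
    c0 <- (pix - 1L) %/% nr
    data.frame(nucleus_id = k, area_px = length(pix),
               centroid_row = mean(r0), centroid_col = mean(c0),
               bbox_row0 = min(r0), bbox_row1 = max(r0) + 1L,
               bbox_col0 = min(c0), bbox_col1 = max(c0) + 1L)
  }))
  structure(list(labels = new_lab, n_nuclei = length(surv), table = tab),
            class = "labeled_mask")
}

empty_labeled_mask <- function(dm) {
  structure(list(labels = matrix(0L, dm[1], dm[2]), n_nuclei = 0L,
                 table = data.frame(nucleus_id = integer(0),
                                    area_px = integer(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0),
                                    bbox_row0 = integer(0),
                                    bbox_row1 = integer(0),
                                    bbox_col0 = integer(0),
                                    bbox_col1 = integer(0))),
            class = "labeled_mask")
}

# EBImage::bwlabel is 4-connected; merge label pairs that touch diagonally
# (union-find over the label adjacency graph) to obtain 8-connectivity.
merge_diagonal_labels <- function(lab) {
  mx <- max(lab)
  if (mx < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(mx)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(mx), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask: %d nuclei in %d x %d raster>\n",
              x$n_nuclei, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Segment a nucleus image pair
#'
#' Convenience wrapper: Otsu-threshold the DNA channel and label nuclei.
#'
#' @param pair a `nucleus_image_pair`.
#' @param min_area_px,fill_holes,border_policy passed to [label_nuclei()].
#' @param method,fixed_value passed to [threshold_dna()].
#' @return a `labeled_mask`.
#' @export
segment_pair <- function(pair, min_area_px = 200L, fill_holes = TRUE,
                         border_policy = "discard", method = "otsu",
                         fixed_value = NULL) {
  thr <- threshold_dna(pair$dna, method = method, fixed_value = fixed_value)
  label_nuclei(thr$mask, min_area_px = min_area_px, fill_holes = fill_holes,
               border_policy = border_policy)
}

#' Extract per-nucleus SC-35 regions of interest
#'
#' Crops the SC-35 channel to each labeled nucleus's bounding box together
#' with the boolean in-nucleus mask; pixels outside the nucleus are excluded
#' from downstream co-occurrence counting.
#'
#' @param pair a `nucleus_image_pair`.
#' @param mask a `labeled_mask` co-registered with `pair`.
#' @return list of entries `nucleus_id`, `sc35` (cropped matrix), `mask`
#'   (logical matrix of the same shape).
#' @export
extract_rois <- function(pair, mask) {
  if (!identical(dim(pair$sc35), dim(mask$labels)))
    stop("image and mask shapes differ")
  lapply(seq_len(mask$n_nuclei), function(k) {
    b <- mask$table[mask$table$nucleus_id == k, ]
    rows <- (b$bbox_row0 + 1L):b$bbox_row1
    cols <- (b$bbox_col0 + 1L):b$bbox_col1
    list(nucleus_id = k,
         sc35 = pair$sc35[rows, cols, drop = FALSE],
         mask = mask$labels[rows, cols, drop = FALSE] == k)
  })
}
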