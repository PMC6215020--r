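#' Fit a PCA reduction to the minimal components for a variance target
#'
#' Columns are z-scored first (the descriptors live on wildly different
#' scales, so this is correlation-matrix PCA); components come from the
#' covariance of the standardized data. The number of retained components is
#' the smallest k whose cumulative explained-variance fraction reaches
#' `variance_target`. Constant columns are dropped with a warning.
#'
#' @param features numeric matrix or data.frame (n x p), n >= 3.
#' @param variance_target fraction in (0, 1], default 0.95.
#' @return an object of class `pca_model`: list with `center`, `scale`,
#'   `rotation` (orthonormal loadings), `explained` (nonincreasing
#'   explained-variance fractions), `n_retained`, `kept_cols` and
#'   `variance_target`.
#' @export
fit_pca <- function(features, variance_target = 0.95) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("'features' must be numeric")
  if (nrow(X) < 3L) stop("need at least 3 rows to fit PCA")
  if (variance_target <= 0 || variance_target > 1)
    stop_field("variance_target", "must lie in (0, 1]")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all columns are constant")
  if (any(!keep))
    warning(sum(!keep), " constant column(s) dropped: ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  # minimal k with cumulative explained variance >= target
  k <- which(cumsum(expl) >= variance_target - 1e-12)[1]
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation, explained = expl,
                 n_retained = as.integer(k),
                 kept_cols = colnames(X),
                 variance_target = variance_target),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d/%d components retained, %.2f%% variance (target %.0f%%)>\n",
              x$n_retained, length(x$explained),
              100 * sum(x$explained[seq_len(x$n_retained)]),
              100 * x$variance_target))
  invisible(x)
}

#' Project features onto retained principal components
#'
#' Standardizes new rows with the training means/SDs and rotates onto the
#' retained components.
#'
#' @param model a `pca_model`.
#' @param features matrix/data.frame containing at least the model's columns.
#' @return numeric score matrix (n x n_retained).
#' @export
project <- function(model, features) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$kept_cols))
      stop("feature columns do not match the PCA model")
    colnames(X) <- model$kept_cols
  }
  if (!all(model$kept_cols %in% colnames(X)))
    stop("feature columns do not match the PCA model")
  X <- X[, model$kept_cols, drop = FALSE]
  Z <- scale(X, center = model$center, scale = model$scale)
  S <- Z %*% model$rotation[, seq_len(model$n_retained), drop = FALSE]
  colnames(S) <- sprintf("PC%d", seq_len(model$n_retained))
  S
}
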