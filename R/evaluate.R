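#' Confusion matrix and precision/recall report
#'
#' Builds the true-by-predicted confusion matrix and reports per-class
#' precision TP/(TP+FP), recall TP/(TP+FN), their weighted averages (weights
#' are the true class shares), and the percent of correctly classified
#' instances (trace / total). A class never predicted gets precision 0.
#'
#' @param true true labels.
#' @param predicted predicted labels.
#' @param scheme evaluation scheme annotation (free text).
#' @return an object of class `classification_report`: list with `confusion`,
#'   `per_class` (data.frame of n, precision, recall), `weighted_precision`,
#'   `weighted_recall`, `percent_correct`, `scheme`.
#' @export
classification_report <- function(true, predicted, scheme = "resubstitution") {
  lev <- union(levels(factor(true)), levels(factor(predicted)))
  true <- factor(true, levels = lev)
  predicted <- factor(predicted, levels = lev)
  cm <- table(true = true, predicted = predicted)
  tp <- diag(cm)
  col_tot <- colSums(cm)
  row_tot <- rowSums(cm)
  precision <- ifelse(col_tot > 0, tp / col_tot, 0)
  recall <- ifelse(row_tot > 0, tp / row_tot, 0)
  w <- row_tot / sum(row_tot)
  structure(list(confusion = cm,
                 per_class = data.frame(class = lev, n = as.integer(row_tot),
                                        precision = as.numeric(precision),
                                        recall = as.numeric(recall)),
                 weighted_precision = sum(w * precision),
                 weighted_recall = sum(w * recall),
                 percent_correct = 100 * sum(tp) / sum(cm),
                 scheme = scheme),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report (%s): %.1f%% correct, weighted precision %.3f, recall %.3f>\n",
              x$scheme, x$percent_correct, x$weighted_precision,
              x$weighted_recall))
  print(x$confusion)
  invisible(x)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin over k folds.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Evaluate the PCA + C4.5 pipeline
#'
#' Fits the variance-targeted PCA reduction and the pruned C4.5 tree, and
#' reports a [classification_report()] either by resubstitution (training set
#' evaluated on itself) or by stratified k-fold cross-validation. Under
#' cross-validation the PCA and the tree are re-fit inside every training
#' fold, so no information leaks from held-out nuclei.
#'
#' @param X numeric feature matrix/data.frame.
#' @param y class labels.
#' @param variance_target PCA explained-variance target.
#' @param confidence_factor,min_leaf,prune C4.5 hyperparameters.
#' @param scheme `"resubstitution"` or `"kfold"`.
#' @param k folds for `scheme = "kfold"`.
#' @param seed fold-assignment seed.
#' @return a `classification_report`; for k-fold the report pools the
#'   held-out predictions of all folds and carries the per-fold PCA sizes in
#'   attribute `n_retained`.
#' @export
evaluate_pipeline <- function(X, y, variance_target = 0.95,
                              confidence_factor = 0.25, min_leaf = 2L,
                              prune = TRUE,
                              scheme = c("resubstitution", "kfold"),
                              k = 10L, seed = 13L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (scheme == "resubstitution") {
    pca <- fit_pca(X, variance_target)
    S <- project(pca, X)
    tree <- fit_c45(S, y, confidence_factor, min_leaf, prune)
    rep <- classification_report(y, predict(tree, S), "resubstitution")
    attr(rep, "n_retained") <- pca$n_retained
    return(rep)
  }
  if (k < 2L) stop("k must be >= 2 for k-fold CV")
  fold <- stratified_folds(y, k, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  nret <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < nlevels(y))
      stop("a class is absent from a training fold; use larger n or smaller k")
    pca <- fit_pca(X[tr, , drop = FALSE], variance_target)
    tree <- fit_c45(project(pca, X[tr, , drop = FALSE]), y[tr],
                    confidence_factor, min_leaf, prune)
    pred[!tr] <- predict(tree, project(pca, X[!tr, , drop = FALSE]))
    nret[f] <- pca$n_retained
  }
  rep <- classification_report(y, pred, sprintf("stratified %d-fold CV", k))
  attr(rep, "n_retained") <- nret
  rep
}
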