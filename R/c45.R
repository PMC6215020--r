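# C4.5-style decision tree: gain-ratio splits on numeric features with
# pessimistic-error (Clopper-Pearson upper bound) subtree-replacement pruning.

xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  log2(n) - sum(xlog2(counts)) / n
}

# Pessimistic error rate: one-sided upper confidence limit of a binomial
# error rate given E observed errors out of N, at confidence factor CF
# (C4.5's U_CF(E, N); for E = 0 this is 1 - CF^(1/N)).
pessimistic_error <- function(E, N, cf) {
  if (N <= 0) return(0)
  if (E >= N) return(1)
  stats::qbeta(1 - cf, E + 1, N - E)
}

# Evaluate all candidate splits of one node; returns the best split or NULL.
# Candidates sit at midpoints between sorted distinct values; a split is
# valid when both branches hold >= min_leaf instances and has positive
# information gain. The winner maximizes gain ratio; ties go to the lowest
# feature index, then the lowest threshold.
best_split <- function(X, yint, K, min_leaf) {
  n <- length(yint)
  tot <- tabulate(yint, K)
  H <- entropy_counts(tot)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    v <- X[, f]
    ord <- order(v)
    vs <- v[ord]
    ys <- yint[ord]
    cuts <- which(vs[-n] < vs[-1])            # boundary after position i
    cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
    if (!length(cuts)) next
    Ymat <- matrix(0L, n, K)
    Ymat[cbind(seq_len(n), ys)] <- 1L
    csum <- apply(Ymat, 2, cumsum)            # n x K cumulative class counts
    L <- csum[cuts, , drop = FALSE]
    nl <- cuts
    nr <- n - nl
    R <- matrix(tot, length(cuts), K, byrow = TRUE) - L
    cond <- (nl * log2(nl) - rowSums(xlog2(L)) +
             nr * log2(nr) - rowSums(xlog2(R))) / n
    gain <- H - cond
    split_info <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
    ratio <- ifelse(gain > 1e-12, gain / split_info, -Inf)
    bi <- which.max(ratio)                    # thresholds ascend: tie -> lowest
    if (is.finite(ratio[bi]) &&
        (is.null(best) || ratio[bi] > best$ratio + 1e-12)) {
      thr <- (vs[cuts[bi]] + vs[cuts[bi] + 1L]) / 2
      best <- list(feature = f, threshold = thr, ratio = ratio[bi],
                   gain = gain[bi], split_info = split_info[bi])
    }
  }
  best
}

grow_tree <- function(X, yint, K, min_leaf) {
  counts <- tabulate(yint, K)
  node <- list(leaf = TRUE, counts = counts, n = length(yint),
               class = which.max(counts))    # tie -> lowest class index
  if (sum(counts > 0) <= 1L || length(yint) < 2L * min_leaf) return(node)
  sp <- best_split(X, yint, K, min_leaf)
  if (is.null(sp)) return(node)
  go_left <- X[, sp$feature] <= sp$threshold
  node$leaf <- FALSE
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- grow_tree(X[go_left, , drop = FALSE], yint[go_left], K, min_leaf)
  node$right <- grow_tree(X[!go_left, , drop = FALSE], yint[!go_left], K, min_leaf)
  node
}

# Bottom-up subtree replacement: a subtree collapses to a leaf when the
# leaf's pessimistic error count does not exceed the sum over its leaves.
prune_tree <- function(node, cf) {
  E_here <- node$n - max(node$counts)
  leaf_err <- node$n * pessimistic_error(E_here, node$n, cf)
  if (node$leaf) {
    node$pess_err <- leaf_err
    return(node)
  }
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  subtree_err <- node$left$pess_err + node$right$pess_err
  if (leaf_err <= subtree_err + 1e-9) {
    node <- list(leaf = TRUE, counts = node$counts, n = node$n,
                 class = which.max(node$counts), pess_err = leaf_err)
  } else {
    node$pess_err <- subtree_err
  }
  node
}

count_nodes <- function(node) {
  if (node$leaf) return(c(nodes = 1L, leaves = 1L))
  l <- count_nodes(node$left); r <- count_nodes(node$right)
  c(nodes = 1L + unname(l["nodes"]) + unname(r["nodes"]),
    leaves = unname(l["leaves"]) + unname(r["leaves"]))
}

#' Fit a C4.5-style pruned decision tree
#'
#' Grows a binary decision tree on numeric features. Splits are chosen to
#' maximize the gain ratio (information gain divided by split information)
#' over candidate thresholds at midpoints between sorted distinct values;
#' both branches must hold at least `min_leaf` instances, and growth stops at
#' class purity or when no candidate has positive gain. With `prune = TRUE`,
#' subtrees are replaced bottom-up by leaves whenever the leaf's pessimistic
#' error count (binomial upper confidence bound at `confidence_factor`) does
#' not exceed the subtree's. Ties in gain ratio resolve to the lowest feature
#' index, then the lowest threshold, making the fit deterministic. Instances
#' with a feature value exactly at a threshold follow the left
#' (less-or-equal) branch.
#'
#' @param X numeric matrix/data.frame of features.
#' @param y class labels (coerced to factor; its level order breaks
#'   majority-vote ties).
#' @param confidence_factor pruning confidence factor (default 0.25).
#' @param min_leaf minimum instances per branch (default 2).
#' @param prune apply pessimistic-error subtree replacement.
#' @return an object of class `c45_model`.
#' @export
fit_c45 <- function(X, y, confidence_factor = 0.25, min_leaf = 2L,
                    prune = TRUE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("'X' must be numeric")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  y <- factor(y)
  K <- nlevels(y)
  if (K >= 2L && nrow(X) < 2L * min_leaf)
    stop("too few instances: need at least 2 * min_leaf")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  yint <- as.integer(y)
  root <- grow_tree(X, yint, K, as.integer(min_leaf))
  unpruned_nodes <- count_nodes(root)
  if (prune) root <- prune_tree(root, confidence_factor)
  nn <- count_nodes(root)
  structure(list(root = root, classes = levels(y), features = colnames(X),
                 confidence_factor = confidence_factor,
                 min_leaf = as.integer(min_leaf), pruned = prune,
                 n_nodes = unname(nn["nodes"]), n_leaves = unname(nn["leaves"]),
                 n_nodes_unpruned = unname(unpruned_nodes["nodes"])),
            class = "c45_model")
}

#' @export
print.c45_model <- function(x, ...) {
  cat(sprintf("<c45_model: %d classes, %d nodes (%d leaves)%s, CF %.2f, min leaf %d>\n",
              length(x$classes), x$n_nodes, x$n_leaves,
              if (x$pruned) sprintf(", pruned from %d", x$n_nodes_unpruned) else "",
              x$confidence_factor, x$min_leaf))
  invisible(x)
}

#' Predict classes with a fitted C4.5 tree
#'
#' Routes each row to a leaf (values equal to a threshold take the
#' less-or-equal branch) and returns the leaf's majority class; majority ties
#' resolve to the class earliest in training level order.
#'
#' @param object a `c45_model`.
#' @param newdata numeric matrix/data.frame with the training feature columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.c45_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (anyNA(X)) stop("missing values are not supported")
  if (!is.null(colnames(X)) && all(object$features %in% colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  } else if (ncol(X) != length(object$features)) {
    stop("feature columns do not match the trained model")
  }
  route <- function(node, x) {
    while (!node$leaf) {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    }
    node$class
  }
  idx <- vapply(seq_len(nrow(X)), function(i) route(object$root, X[i, ]),
                integer(1))
  factor(object$classes[idx], levels = object$classes)
}
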