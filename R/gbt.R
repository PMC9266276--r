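## Gradient-boosted trees for binary bag-of-words classification.
##
## Self-contained boosting engine (second-order logistic loss, shallow
## trees). Splits are presence splits (word count >= 1), the natural
## candidate set for sparse count features: split search over all
## features at a node then reduces to two sparse matrix-vector products
## (gradient and hessian column sums over the documents containing each
## word). Training is fully deterministic: no subsampling, ties in gain
## broken by the lowest feature index.

osw_binarize <- function(X) {
  X <- methods::as(X, "CsparseMatrix")
  if (length(X@x)) X@x[] <- 1
  X
}

osw_grow_tree <- function(Xb, g, h, idx, depth, max_depth, lambda, min_child_weight) {
  G <- sum(g[idx]); H <- sum(h[idx])
  make_leaf <- function() list(leaf = TRUE, value = -G / (H + lambda))
  if (depth >= max_depth || length(idx) < 2L) return(make_leaf())
  GR <- as.numeric(Matrix::crossprod(Xb[idx, , drop = FALSE], g[idx]))
  HR <- as.numeric(Matrix::crossprod(Xb[idx, , drop = FALSE], h[idx]))
  GL <- G - GR; HL <- H - HR
  gain <- GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - G^2 / (H + lambda)
  gain[HL < min_child_weight | HR < min_child_weight] <- -Inf
  j <- which.max(gain)            # first max: deterministic tie-break
  if (!is.finite(gain[j]) || gain[j] <= 1e-10) return(make_leaf())
  xj <- Xb[idx, j]
  right <- idx[xj > 0]; left <- idx[xj == 0]
  if (!length(right) || !length(left)) return(make_leaf())
  list(leaf = FALSE, feature = j,
       left = osw_grow_tree(Xb, g, h, left, depth + 1L, max_depth, lambda, min_child_weight),
       right = osw_grow_tree(Xb, g, h, right, depth + 1L, max_depth, lambda, min_child_weight))
}

osw_tree_predict <- function(tree, Xb, idx, out) {
  if (isTRUE(tree$leaf)) {
    out[idx] <- tree$value
    return(out)
  }
  xj <- Xb[idx, tree$feature]
  out <- osw_tree_predict(tree$left, Xb, idx[xj == 0], out)
  osw_tree_predict(tree$right, Xb, idx[xj > 0], out)
}

#' Fit a gradient-boosted tree classifier on count features
#'
#' @param X document-term count matrix (`dgCMatrix` or dense), documents
#'   in rows.
#' @param y binary response (0/1 or logical).
#' @param n_trees number of boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth maximum tree depth (presence splits).
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum hessian sum per child.
#' @return an object of class `sweet_gbt`.
#' @export
fit_gbt <- function(X, y, n_trees = 100L, learning_rate = 0.3, max_depth = 3L,
                    lambda = 1, min_child_weight = 1) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y), n_trees >= 1L)
  Xb <- osw_binarize(X)
  n <- length(y)
  base <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  f <- rep(base, n)
  trees <- vector("list", n_trees)
  idx_all <- seq_len(n)
  for (t in seq_len(n_trees)) {
    p <- plogis(f)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-12)
    tree <- osw_grow_tree(Xb, g, h, idx_all, 0L, max_depth, lambda, min_child_weight)
    delta <- osw_tree_predict(tree, Xb, idx_all, numeric(n))
    f <- f + learning_rate * delta
    trees[[t]] <- tree
  }
  structure(list(trees = trees, base_score = base,
                 learning_rate = learning_rate, n_features = ncol(X),
                 max_depth = max_depth, lambda = lambda),
            class = "sweet_gbt")
}

#' Predict class probabilities from a fitted `sweet_gbt`
#'
#' @param object a `sweet_gbt` model.
#' @param X count matrix with the same columns as at fit time.
#' @param ... unused.
#' @return numeric vector of probabilities of the positive class.
#' @export
predict.sweet_gbt <- function(object, X, ...) {
  stopifnot(ncol(X) == object$n_features)
  Xb <- osw_binarize(X)
  n <- nrow(Xb)
  f <- rep(object$base_score, n)
  idx_all <- seq_len(n)
  for (tree in object$trees) {
    f <- f + object$learning_rate * osw_tree_predict(tree, Xb, idx_all, numeric(n))
  }
  plogis(f)
}
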