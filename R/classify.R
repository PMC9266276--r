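## classify: distinguish reviews whose oversweet phrase refers to the
## purchased product from those where it does not, via a bag-of-words
## gradient-boosted classifier with grid-searched hyperparameters.

#' Split labeled reviews into train and test sets
#'
#' Exact, disjoint, exhaustive partition with a floor-then-remainder
#' size rule (`n_train = floor(train_fraction * n)`), reproducible under
#' the seed: 5590 labeled reviews at 0.75 split into 4192 + 1398.
#'
#' @param labeled a data.frame/data.table of labeled reviews.
#' @param train_fraction fraction assigned to the training set, in (0,1).
#' @param seed integer seed controlling the random assignment.
#' @return list with elements `train` and `test`.
#' @export
split_labeled <- function(labeled, train_fraction = 0.75, seed = 1L) {
  labeled <- data.table::as.data.table(labeled)
  n <- nrow(labeled)
  if (n < 2L) stop("need at least 2 labeled reviews to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = labeled[sort(idx)], test = labeled[setdiff(seq_len(n), sort(idx))])
}

#' Build a frequency-ordered vocabulary
#'
#' Words are sorted by descending corpus frequency (ties broken
#' lexicographically). Under the default `"mass"` rule the vocabulary is
#' the smallest prefix whose cumulative token frequency reaches
#' `mass_fraction` (the common reading of "the 99.5% most frequent
#' words"); `"type_quantile"` instead keeps the most frequent
#' `mass_fraction` share of word types.
#'
#' @param texts character vector of documents.
#' @param mass_fraction cutoff in (0, 1].
#' @param method `"mass"` (cumulative frequency prefix) or
#'   `"type_quantile"`.
#' @return ordered character vector of vocabulary words.
#' @export
build_vocabulary <- function(texts, mass_fraction = 0.995,
                             method = c("mass", "type_quantile")) {
  method <- match.arg(method)
  stopifnot(mass_fraction > 0, mass_fraction <= 1)
  flat <- unlist(osw_tokenize_all(texts), use.names = FALSE)
  if (!length(flat)) stop("empty corpus: no tokens to build a vocabulary from")
  tab <- data.table(word = flat)[, .(count = .N), by = word]
  data.table::setorder(tab, -count, word)
  k <- if (method == "mass") {
    which(cumsum(tab$count) / sum(tab$count) >= mass_fraction)[1L]
  } else {
    max(1L, ceiling(mass_fraction * nrow(tab)))
  }
  tab$word[seq_len(k)]
}

#' Bag-of-words document-term count matrix
#'
#' Entry (d, w) is the count of vocabulary word w in document d;
#' out-of-vocabulary words are ignored, so all-OOV or empty documents
#' give zero rows.
#'
#' @param texts character vector of documents.
#' @param vocabulary ordered word list from [build_vocabulary()].
#' @return a sparse `dgCMatrix` (documents x vocabulary).
#' @export
featurize <- function(texts, vocabulary) {
  stopifnot(length(vocabulary) > 0L)
  toks <- osw_tokenize_all(texts)
  len <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  d <- rep.int(seq_along(texts), len)
  j <- match(flat, vocabulary)
  keep <- !is.na(j)
  cc <- data.table(doc = d[keep], j = j[keep])[, .(count = .N), by = .(doc, j)]
  Matrix::sparseMatrix(i = cc$doc, j = cc$j, x = cc$count,
                       dims = c(length(texts), length(vocabulary)),
                       dimnames = list(NULL, vocabulary))
}

osw_f1 <- function(pred, truth, positive = .osw_pos) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

osw_label_text <- function(labeled) {
  if ("title" %in% names(labeled)) {
    osw_combine_text(labeled, c("title", "text"))
  } else {
    as.character(labeled$text)
  }
}

#' Default hyperparameter grid
#'
#' Artifact default: tree depth 3 or 6, learning rate 0.1 or 0.3, 100 or
#' 300 trees, in deterministic order.
#'
#' @return a data.frame of hyperparameter combinations.
#' @export
default_grid <- function() {
  expand.grid(max_depth = c(3L, 6L), learning_rate = c(0.1, 0.3),
              n_trees = c(100L, 300L), KEEP.OUT.ATTRS = FALSE)
}

#' Train the oversweet-reference classifier
#'
#' Grid search over boosted-tree hyperparameters by k-fold
#' cross-validated F1 (positive class `oversweet-product`); the best
#' combination (first in grid order on ties) is refit on the full
#' training set. All randomness (fold assignment) flows from `seed`.
#'
#' @param train labeled training set: columns `text` (plus optional
#'   `title`) and `label` with values `oversweet-product` /
#'   `not-oversweet-product`; both classes must be present.
#' @param grid data.frame with columns `max_depth`, `learning_rate`,
#'   `n_trees`; defaults to [default_grid()].
#' @param k_folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @param mass_fraction vocabulary cutoff passed to [build_vocabulary()].
#' @param vocabulary optional pre-built vocabulary (overrides
#'   `mass_fraction`).
#' @return an object of class `sweet_classifier` with elements
#'   `vocabulary`, `model`, `hyperparameters` and `metrics`
#'   (`cv_f1_mean`, `cv_accuracy_mean`, `cv_accuracy_sd`).
#' @export
train_classifier <- function(train, grid = default_grid(), k_folds = 10L,
                             seed = 1L, mass_fraction = 0.995,
                             vocabulary = NULL) {
  train <- data.table::as.data.table(train)
  stopifnot(all(c("text", "label") %in% names(train)), nrow(grid) >= 1L)
  y <- as.numeric(train$label == .osw_pos)
  if (length(unique(y)) < 2L) {
    stop("single-class training set: both labels must be present")
  }
  txt <- osw_label_text(train)
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(txt, mass_fraction)
  X <- featurize(txt, vocabulary)
  n <- nrow(X)
  k_folds <- min(k_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))

  cv <- lapply(seq_len(nrow(grid)), function(gi) {
    f1s <- accs <- numeric(k_folds)
    for (k in seq_len(k_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) {
        f1s[k] <- NA_real_; accs[k] <- NA_real_
        next
      }
      m <- fit_gbt(X[tr, , drop = FALSE], y[tr],
                   n_trees = grid$n_trees[gi],
                   learning_rate = grid$learning_rate[gi],
                   max_depth = grid$max_depth[gi])
      p <- predict(m, X[!tr, , drop = FALSE])
      pred <- ifelse(p > 0.5, .osw_pos, .osw_neg)
      truth <- ifelse(y[!tr] == 1, .osw_pos, .osw_neg)
      f1s[k] <- osw_f1(pred, truth)
      accs[k] <- mean(pred == truth)
    }
    list(f1 = mean(f1s, na.rm = TRUE),
         acc_mean = mean(accs, na.rm = TRUE),
         acc_sd = stats::sd(accs, na.rm = TRUE))
  })
  f1_means <- vapply(cv, `[[`, numeric(1L), "f1")
  best <- which.max(f1_means)    # first max: deterministic
  model <- fit_gbt(X, y, n_trees = grid$n_trees[best],
                   learning_rate = grid$learning_rate[best],
                   max_depth = grid$max_depth[best])
  structure(list(
    vocabulary = vocabulary,
    model = model,
    hyperparameters = as.list(grid[best, , drop = FALSE]),
    metrics = list(cv_f1_mean = f1_means[best],
                   cv_accuracy_mean = cv[[best]]$acc_mean,
                   cv_accuracy_sd = cv[[best]]$acc_sd),
    grid = grid, k_folds = k_folds, seed = seed),
    class = "sweet_classifier")
}

#' Predict oversweet-reference labels for reviews
#'
#' A pure function of (model, text): every input review receives exactly
#' one label, with `source = "model"`.
#'
#' @param object a `sweet_classifier`.
#' @param reviews review table with `review_id`, `text` (and optional
#'   `title`), or a character vector of texts.
#' @param ... unused.
#' @return a `data.table` with columns `review_id`, `label`, `source`.
#' @export
predict.sweet_classifier <- function(object, reviews, ...) {
  if (is.character(reviews)) {
    reviews <- data.table(review_id = as.character(seq_along(reviews)),
                          text = reviews)
  }
  reviews <- data.table::as.data.table(reviews)
  if (nrow(reviews) == 0L) {
    return(data.table(review_id = character(), label = character(),
                      source = character()))
  }
  p <- predict(object$model, featurize(osw_label_text(reviews), object$vocabulary))
  data.table(review_id = reviews$review_id,
             label = ifelse(p > 0.5, .osw_pos, .osw_neg),
             source = "model")
}

#' Evaluate a classifier against an independently labeled set
#'
#' @param classifier a `sweet_classifier`.
#' @param labeled labeled review table (columns `text`, `label`).
#' @return list with `accuracy`, `f1` and `n`.
#' @export
evaluate_classifier <- function(classifier, labeled) {
  labeled <- data.table::as.data.table(labeled)
  if (nrow(labeled) == 0L) stop("empty evaluation set")
  pred <- predict(classifier, labeled)$label
  list(accuracy = mean(pred == labeled$label),
       f1 = osw_f1(pred, labeled$label),
       n = nrow(labeled))
}

## tree -> plain list (for JSON round-trip)
osw_tree_to_list <- function(tree) {
  if (isTRUE(tree$leaf)) return(list(leaf = TRUE, value = tree$value))
  list(leaf = FALSE, feature = tree$feature,
       left = osw_tree_to_list(tree$left), right = osw_tree_to_list(tree$right))
}

osw_tree_from_list <- function(x) {
  if (isTRUE(x$leaf)) return(list(leaf = TRUE, value = as.numeric(x$value)))
  list(leaf = FALSE, feature = as.integer(x$feature),
       left = osw_tree_from_list(x$left), right = osw_tree_from_list(x$right))
}

#' Save / load a trained classifier as JSON
#'
#' Versioned plain-text archive holding the vocabulary, hyperparameters,
#' metrics and the boosted trees.
#'
#' @param classifier a `sweet_classifier`.
#' @param path output `.json` path.
#' @return `path` (save) or the restored `sweet_classifier` (load).
#' @export
save_classifier <- function(classifier, path) {
  payload <- list(
    format = "sweet_classifier", format_version = 1L,
    vocabulary = classifier$vocabulary,
    hyperparameters = classifier$hyperparameters,
    metrics = classifier$metrics,
    model = list(base_score = classifier$model$base_score,
                 learning_rate = classifier$model$learning_rate,
                 n_features = classifier$model$n_features,
                 max_depth = classifier$model$max_depth,
                 lambda = classifier$model$lambda,
                 trees = lapply(classifier$model$trees, osw_tree_to_list)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$format, "sweet_classifier")) {
    stop("not a sweet_classifier archive: ", path)
  }
  model <- structure(list(
    trees = lapply(payload$model$trees, osw_tree_from_list),
    base_score = as.numeric(payload$model$base_score),
    learning_rate = as.numeric(payload$model$learning_rate),
    n_features = as.integer(payload$model$n_features),
    max_depth = as.integer(payload$model$max_depth),
    lambda = as.numeric(payload$model$lambda)), class = "sweet_gbt")
  structure(list(
    vocabulary = unlist(payload$vocabulary),
    model = model,
    hyperparameters = payload$hyperparameters,
    metrics = payload$metrics), class = "sweet_classifier")
}
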