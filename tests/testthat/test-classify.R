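make_labeled <- function(n_pos, n_neg, seed = 1) {
  # planted deterministic signal: genuine complaints carry "cloying"
  # or disposal words; decoys carry brand-comparison words
  set.seed(seed)
  pos <- paste("way too sweet",
               sample(c("cloying", "sickly", "nasty"), n_pos, replace = TRUE),
               sample(c("trash", "tossed", "inedible"), n_pos, replace = TRUE),
               sample(c("syrup", "candy", "soda"), n_pos, replace = TRUE))
  neg <- paste("other brands are too sweet but this is",
               sample(c("great", "fine", "balanced"), n_neg, replace = TRUE),
               sample(c("granola", "tea", "mix"), n_neg, replace = TRUE))
  data.table::data.table(
    review_id = sprintf("L%04d", seq_len(n_pos + n_neg)),
    text = c(pos, neg),
    label = c(rep("oversweet-product", n_pos),
              rep("not-oversweet-product", n_neg)))
}

test_that("split_labeled partitions exactly and reproducibly", {
  lab <- make_labeled(60, 40)
  sp <- split_labeled(lab, 0.75, seed = 7)
  expect_equal(nrow(sp$train), 75L)
  expect_equal(nrow(sp$test), 25L)
  expect_equal(sort(c(sp$train$review_id, sp$test$review_id)),
               sort(lab$review_id))
  expect_length(intersect(sp$train$review_id, sp$test$review_id), 0L)
  sp2 <- split_labeled(lab, 0.75, seed = 7)
  expect_identical(sp$train$review_id, sp2$train$review_id)
  expect_error(split_labeled(lab[1], 0.75), "at least 2")
})

test_that("the 75/25 split reproduces the floor-then-remainder sizes", {
  lab <- data.table::data.table(review_id = as.character(1:5590),
                                text = "x", label = "oversweet-product")
  sp <- split_labeled(lab, 0.75, seed = 1)
  expect_equal(nrow(sp$train), 4192L)
  expect_equal(nrow(sp$test), 1398L)
})

test_that("build_vocabulary keeps the smallest frequency-mass prefix", {
  # one word carries 99.6% of the token mass
  texts <- c(paste(rep("tea", 996), collapse = " "), "bitter sweet bitter sweet")
  expect_identical(build_vocabulary(texts, 0.995), "tea")
  v <- build_vocabulary(texts, 1.0)
  expect_setequal(v, c("tea", "bitter", "sweet"))
  # equal counts at the boundary: lexicographically smaller first
  expect_identical(v, c("tea", "bitter", "sweet"))
  expect_error(build_vocabulary(c("", ""), 0.995), "empty corpus")
  # type-quantile alternative keeps a share of word types instead
  expect_length(build_vocabulary(texts, 2 / 3, method = "type_quantile"), 2L)
})

test_that("featurize counts vocabulary words and ignores OOV", {
  X <- featurize(c("sweet sweet tea", "zebra only", ""), c("sweet", "tea"))
  expect_equal(dim(X), c(3L, 2L))
  expect_equal(as.numeric(X[1, ]), c(2, 1))
  expect_equal(as.numeric(X[2, ]), c(0, 0))
  expect_equal(as.numeric(X[3, ]), c(0, 0))
})

test_that("grid search selects by CV F1 and is deterministic", {
  lab <- make_labeled(50, 40)
  one <- data.frame(max_depth = 2L, learning_rate = 0.3, n_trees = 30L)
  clf <- train_classifier(lab, grid = one, k_folds = 5, seed = 3)
  expect_equal(clf$hyperparameters$max_depth, 2L)
  expect_equal(clf$hyperparameters$n_trees, 30L)

  grid <- expand.grid(max_depth = c(1L, 2L), learning_rate = 0.3, n_trees = 30L)
  a <- train_classifier(lab, grid = grid, k_folds = 5, seed = 9)
  b <- train_classifier(lab, grid = grid, k_folds = 5, seed = 9)
  expect_identical(a$hyperparameters, b$hyperparameters)
  expect_identical(predict(a, lab)$label, predict(b, lab)$label)

  single <- data.table::copy(lab)[, label := "oversweet-product"]
  expect_error(train_classifier(single, grid = one), "single-class")
})

test_that("a planted deterministic signal is learned almost perfectly", {
  lab <- make_labeled(120, 90)
  sp <- split_labeled(lab, 0.75, seed = 2)
  clf <- train_classifier(sp$train,
                          grid = data.frame(max_depth = 2L, learning_rate = 0.3,
                                            n_trees = 40L),
                          k_folds = 5, seed = 2)
  expect_gte(clf$metrics$cv_accuracy_mean, 0.95)
  ev <- evaluate_classifier(clf, sp$test)
  expect_gte(ev$accuracy, 0.95)
})

test_that("predict labels every input, and none on empty input", {
  lab <- make_labeled(40, 30)
  clf <- train_classifier(lab, grid = data.frame(max_depth = 2L,
                                                 learning_rate = 0.3,
                                                 n_trees = 30L),
                          k_folds = 5, seed = 1)
  out <- predict(clf, lab)
  expect_equal(nrow(out), nrow(lab))
  expect_true(all(out$source == "model"))
  expect_equal(nrow(predict(clf, lab[0])), 0L)

  # the classic non-referring example: an oversweet phrase about OTHER mixes
  waffle <- paste("i have had waffles from other mixes that are too sweet",
                  "this mix is very good and easy to prepare")
  complaint <- "way too sweet, could not finish it, tossed the rest"
  pred <- predict(clf, c(waffle, complaint))
  expect_identical(pred$label,
                   c("not-oversweet-product", "oversweet-product"))
})

test_that("evaluate_classifier computes accuracy on labeled sets", {
  lab <- make_labeled(30, 30)
  clf <- train_classifier(lab, grid = data.frame(max_depth = 2L,
                                                 learning_rate = 0.3,
                                                 n_trees = 30L),
                          k_folds = 5, seed = 1)
  ev <- evaluate_classifier(clf, lab)
  expect_equal(ev$accuracy, 1.0)
  flipped <- data.table::copy(lab)[, label := rev(sort(unique(label)))[
    match(label, sort(unique(label)))]]
  expect_equal(evaluate_classifier(clf, flipped)$accuracy, 0.0)
  expect_error(evaluate_classifier(clf, lab[0]), "empty")
})

test_that("classifier archives round-trip through JSON", {
  lab <- make_labeled(40, 30)
  clf <- train_classifier(lab, grid = data.frame(max_depth = 2L,
                                                 learning_rate = 0.3,
                                                 n_trees = 25L),
                          k_folds = 5, seed = 4)
  path <- tempfile(fileext = ".json")
  save_classifier(clf, path)
  back <- load_classifier(path)
  expect_identical(predict(back, lab)$label, predict(clf, lab)$label)
  expect_identical(back$vocabulary, clf$vocabulary)
})
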