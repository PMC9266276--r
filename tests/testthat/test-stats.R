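test_that("prop_test_two_sided matches prop.test and the hand formula", {
  expect_equal(prop_test_two_sided(50, 100, 50, 100), 1)
  expect_equal(prop_test_two_sided(9, 10, 1, 10), yates_oracle(9, 10, 1, 10))
  expect_equal(prop_test_two_sided(9, 10, 1, 10),
               suppressWarnings(prop.test(c(9, 1), c(10, 10))$p.value))
  expect_message(p <- prop_test_two_sided(0, 10, 0, 10), "degenerate")
  expect_equal(p, 1)
  expect_message(p <- prop_test_two_sided(10, 10, 10, 10), "degenerate")
  expect_equal(p, 1)
  expect_error(prop_test_two_sided(1, 0, 1, 5))

  # grid of tables vs both routes; symmetry under group swap
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:80, 1); n2 <- sample(2:80, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if ((k1 + k2) %in% c(0, n1 + n2)) next
    p <- prop_test_two_sided(k1, n1, k2, n2)
    expect_equal(p, yates_oracle(k1, n1, k2, n2))
    expect_equal(p, suppressWarnings(prop.test(c(k1, k2), c(n1, n2))$p.value))
    expect_equal(p, prop_test_two_sided(k2, n2, k1, n1))
  }
})

test_that("wilcoxon exact branch equals exhaustive enumeration", {
  expect_equal(wilcoxon_one_sided(c(1, 2, 3), c(4, 5, 6)), 0.05)
  expect_gte(wilcoxon_one_sided(c(3, 3, 3), c(3, 3, 3)), 0.5)
  expect_error(wilcoxon_one_sided(numeric(), 1:3), "empty")

  set.seed(5)
  for (N in 4:10) {
    for (m in 1:(N - 1)) {
      v <- sample(100, N)           # no ties
      x <- v[seq_len(m)]; y <- v[-seq_len(m)]
      expect_equal(wilcoxon_one_sided(x, y), wilcox_enum_oracle(x, y))
    }
  }
})

test_that("wilcoxon approximate branch matches the tie-corrected normal", {
  set.seed(6)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(2:5, 40, replace = TRUE)
    expect_equal(
      wilcoxon_one_sided(x, y),
      suppressWarnings(wilcox.test(x, y, alternative = "less",
                                   exact = FALSE, correct = TRUE)$p.value))
  }
})

test_that("bh_adjust implements the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
    expect_true(all(bh_adjust(p) >= p))          # dominance
    expect_true(all(bh_adjust(p) <= 1))
  }
})

test_that("bonferroni_adjust multiplies and caps at 1", {
  set.seed(32)
  for (i in 1:10) {
    p <- runif(sample(1:8, 1))
    expect_equal(bonferroni_adjust(p), pmin(1, p * length(p)))
    expect_equal(bonferroni_adjust(p), p.adjust(p, method = "bonferroni"))
  }
  expect_error(bonferroni_adjust(-0.1), "\\[0, 1\\]")
})

test_that("enrichment joins reviews to sweeteners with multi-membership", {
  products <- annotate_products(data.table::data.table(
    product_id = c("P1", "P2"),
    name = c("soda", "bar"), category = "snacks",
    raw_ingredients = c("Ingredients: water, sucralose.",
                        "Ingredients: cane sugar, erythritol.")))
  rv <- make_reviews(rep("x", 8), product_ids = rep(c("P1", "P2"), each = 4),
                     customer_ids = sprintf("C%d", 1:8))
  labels <- data.table::data.table(review_id = rv$review_id,
                                   label = c(rep("oversweet-product", 3),
                                             rep("not-oversweet-product", 5)))
  enr <- enrichment_by_sweetener(rv, labels, products)
  expect_setequal(enr$sweetener, c("sucralose", "sucrose", "erythritol"))
  # P2's reviews count toward both of its sweeteners
  expect_equal(enr[sweetener == "sucrose"]$n_reviews, 4L)
  expect_equal(enr[sweetener == "erythritol"]$n_reviews, 4L)
  expect_true(all(enr$p_adjusted >= enr$p_raw))

  # single-sweetener catalog: Bonferroni m = 1 leaves p unchanged
  cat1 <- sweetener_catalog()[canonical_name == "sucralose"]
  enr1 <- enrichment_by_sweetener(rv, labels, products, catalog = cat1)
  expect_equal(enr1$p_adjusted, enr1$p_raw)

  orphan <- make_reviews("x", product_ids = "P9")
  expect_error(enrichment_by_sweetener(orphan, labels, products),
               "unknown product_id.*P9")
})

test_that("caloric-class pooling counts a product once per class", {
  products <- annotate_products(data.table::data.table(
    product_id = "P1", name = "bar", category = "snacks",
    raw_ingredients = "Ingredients: cane sugar, erythritol."))
  rv <- make_reviews(rep("x", 6), product_ids = "P1")
  labels <- data.table::data.table(review_id = rv$review_id[1],
                                   label = "oversweet-product")
  encl <- enrichment_by_caloric_class(rv, labels, products)
  expect_setequal(encl$caloric_class, c("caloric", "sugar alcohol"))
  expect_true(all(encl$n_reviews == 6L))
})

test_that("rating-comparison filters use strict > and >= thresholds", {
  # 51 reviews, 6 oversweet (11.8%): passes both filters
  rv <- make_reviews(rep("x", 51), ratings = rep(c(1L, 5L), length.out = 51),
                     product_ids = "P1", customer_ids = sprintf("C%d", 1:51))
  labels <- data.table::data.table(review_id = rv$review_id[1:6],
                                   label = "oversweet-product")
  cmp <- suppressWarnings(compare_product_ratings(rv, labels))
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$n_oversweet + cmp$n_other, 51L)

  # exactly 50 reviews: excluded by the strict "over 50" rule
  rv50 <- rv[1:50]
  expect_warning(cmp50 <- compare_product_ratings(rv50, labels), "no product")
  expect_equal(nrow(cmp50), 0L)

  # 9.8% oversweet: below the >= 10% rule
  labels5 <- labels[1:5]
  expect_warning(cmp5 <- compare_product_ratings(rv, labels5), "no product")
  expect_equal(nrow(cmp5), 0L)
})

test_that("missing ratings are excluded from comparisons but logged", {
  rv <- make_reviews(rep("x", 60), ratings = c(rep(NA_integer_, 5),
                                               rep(c(2L, 5L), length.out = 55)),
                     product_ids = "P1", customer_ids = sprintf("C%d", 1:60))
  labels <- data.table::data.table(review_id = rv$review_id[1:10],
                                   label = "oversweet-product")
  cmp <- compare_product_ratings(rv, labels)
  expect_equal(cmp$n_oversweet + cmp$n_other, 55L)
  expect_equal(attr(cmp, "n_excluded_missing_rating"), 5L)
})

test_that("product-driven oversweetness leaves heavy reviewers dispersed", {
  ## at the review-level oversweet rate (~2%), a heavy reviewer rarely
  ## exceeds 10% oversweet reviews when labels are product-driven
  cfg <- simulation_config(n_products = 40L, n_customers = 400L,
                           n_reviews = 20000L, base_oversweet_rate = 0.02,
                           per_sweetener_log_odds = numeric(), seed = 55L)
  corp <- generate_corpus(cfg)
  disp <- customer_dispersion(corp$reviews, truth_labels(corp))
  expect_gt(disp$summary$n_customers, 20L)
  expect_lte(disp$summary$n_above_10pct / disp$summary$n_customers, 0.05)
  expect_lt(abs(disp$summary$mean_pct - 2), 1)
})

test_that("customer dispersion uses the strict over-30 threshold", {
  rv <- make_reviews(rep("x", 61),
                     product_ids = "P1",
                     customer_ids = c(rep("C1", 31), rep("C2", 30)))
  labels <- data.table::data.table(review_id = rv$review_id[1:4],
                                   label = "oversweet-product")
  disp <- customer_dispersion(rv, labels)
  expect_identical(disp$customers$customer_id, "C1")   # C2 has exactly 30
  expect_equal(disp$customers$n_reviews, 31L)
  expect_equal(disp$summary$n_customers, 1L)

  none <- customer_dispersion(rv, labels, min_reviews = 100L)
  expect_equal(nrow(none$customers), 0L)
  expect_null(none$summary)
})
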