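## stats: per-sweetener oversweet enrichment (two-sided proportion tests,
## Bonferroni), product-level rating comparison (one-sided Wilcoxon
## rank-sum, Benjamini-Hochberg), caloric-class grouping, per-customer
## dispersion.

#' Two-sided test of equal proportions (continuity-corrected chi-square)
#'
#' Closed-form 2x2 chi-square with Yates continuity correction (the
#' correction is capped so that identical proportions give a statistic
#' of exactly 0), matching `stats::prop.test` defaults. Degenerate
#' tables (all successes or all failures on both sides) return p = 1 by
#' convention, with a message.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return the two-sided p-value.
#' @export
prop_test_two_sided <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if ((k1 + k2 == 0) || (k1 + k2 == n1 + n2)) {
    message("degenerate 2x2 table: returning p = 1 by convention")
    return(1)
  }
  k1 <- as.numeric(k1); n1 <- as.numeric(n1)
  k2 <- as.numeric(k2); n2 <- as.numeric(n2)
  a <- k1; b <- n1 - k1; cc <- k2; d <- n2 - k2; N <- n1 + n2
  stat <- N * max(0, abs(a * d - b * cc) - N / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

## exact null distribution of the rank-sum: number of m-subsets of
## ranks 1..N with each possible sum (dynamic programming)
osw_ranksum_counts <- function(m, N) {
  maxsum <- sum((N - m + 1L):N)
  f <- matrix(0, nrow = m + 1L, ncol = maxsum + 1L)  # [j+1, s+1]
  f[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (j in seq(min(r, m), 1L)) {
      s <- seq(r, maxsum)
      f[j + 1L, s + 1L] <- f[j + 1L, s + 1L] + f[j, s - r + 1L]
    }
  }
  f[m + 1L, ]
}

#' One-sided Wilcoxon rank-sum test (x stochastically smaller than y)
#'
#' Exact enumeration of the rank-sum null distribution when
#' `length(x) + length(y) <= 12` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (e.g. star ratings); both non-empty.
#' @param exact_max maximum combined sample size for the exact branch.
#' @return the one-sided p-value for the alternative `x < y`.
#' @export
wilcoxon_one_sided <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("empty group in rank-sum comparison")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (N <= exact_max && !ties) {
    cnt <- osw_ranksum_counts(m, N)
    return(sum(cnt[seq_len(W + 1L)]) / choose(N, m))  # P(rank-sum <= W)
  }
  U <- W - m * (m + 1) / 2
  t <- table(r)
  sigma <- sqrt(m * n / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1))))
  if (sigma == 0) return(1)   # all values tied: no evidence either way
  z <- (U - m * n / 2 + 0.5) / sigma
  pnorm(z)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p(i) * m / i` with cumulative minimum from the largest p-value,
#' capped at 1; order-preserving with the input positions.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric())
  o <- order(p_values, decreasing = TRUE)
  i <- m:1L
  adj <- pmin(1, cummin(m / i * p_values[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m number of tests (defaults to `length(p_values)`).
#' @return `min(1, p * m)` for each p-value.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, p_values * m)
}

osw_oversweet_flags <- function(reviews, labels) {
  labels <- data.table::as.data.table(labels)
  reviews$review_id %in% labels[label == .osw_pos]$review_id
}

osw_join_product_sweeteners <- function(reviews, products, catalog) {
  products <- data.table::as.data.table(products)
  if (!"sweeteners" %in% names(products)) {
    products <- annotate_products(products, catalog)
  }
  orphan <- setdiff(unique(reviews$product_id), products$product_id)
  if (length(orphan)) {
    stop("review(s) with unknown product_id: ",
         paste(utils::head(orphan, 10L), collapse = ", "))
  }
  products
}

#' Per-sweetener oversweet enrichment
#'
#' For each catalog sweetener present in at least one product, compares
#' the proportion of oversweet reviews among reviews of products
#' containing that sweetener to the dataset-wide proportion, with a
#' two-sided proportion test and Bonferroni correction (m = number of
#' sweeteners actually tested). Reviews of products with several
#' sweeteners count toward each (multi-membership).
#'
#' @param reviews review table; every `product_id` must join to
#'   `products`.
#' @param labels label table (`review_id`, `label`); reviews labeled
#'   `oversweet-product` are the oversweet set.
#' @param products product table (annotated, or with `raw_ingredients`).
#' @param catalog sweetener catalog.
#' @param alpha significance level for the `significant` flag.
#' @return a `data.table`, one row per tested sweetener, sorted by
#'   `n_reviews` descending: `sweetener`, `n_reviews`, `n_oversweet`,
#'   `proportion`, `baseline_proportion`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
enrichment_by_sweetener <- function(reviews, labels, products,
                                    catalog = sweetener_catalog(),
                                    alpha = 0.05) {
  reviews <- data.table::as.data.table(reviews)
  products <- osw_join_product_sweeteners(reviews, products, catalog)
  over <- osw_oversweet_flags(reviews, labels)
  k_all <- sum(over); n_all <- nrow(reviews)
  stopifnot(n_all > 0L)
  pmap <- products$sweeteners
  names(pmap) <- products$product_id
  rows <- list()
  for (sw in catalog$canonical_name) {
    pids <- products$product_id[vapply(pmap, function(s) sw %in% s, logical(1L))]
    if (!length(pids)) next
    sel <- reviews$product_id %in% pids
    ns <- sum(sel)
    if (ns == 0L) next
    ks <- sum(over & sel)
    rows[[length(rows) + 1L]] <- data.table(
      sweetener = sw, n_reviews = ns, n_oversweet = ks,
      proportion = ks / ns, baseline_proportion = k_all / n_all,
      p_raw = suppressMessages(prop_test_two_sided(ks, ns, k_all, n_all)))
  }
  if (!length(rows)) {
    return(data.table(sweetener = character(), n_reviews = integer(),
                      n_oversweet = integer(), proportion = numeric(),
                      baseline_proportion = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  }
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := bonferroni_adjust(p_raw, m = .N)]
  out[, significant := p_adjusted < alpha]
  data.table::setorder(out, -n_reviews, sweetener)
  out[]
}

#' Oversweet enrichment by caloric class
#'
#' Same machinery as [enrichment_by_sweetener()] with sweeteners pooled
#' by caloric class (caloric, non-caloric, sugar alcohol, sugar fiber);
#' a product whose sweeteners span two classes contributes its reviews
#' once per class. Bonferroni m = number of classes tested.
#'
#' @inheritParams enrichment_by_sweetener
#' @return a `data.table`, one row per tested caloric class.
#' @export
enrichment_by_caloric_class <- function(reviews, labels, products,
                                        catalog = sweetener_catalog(),
                                        alpha = 0.05) {
  reviews <- data.table::as.data.table(reviews)
  products <- osw_join_product_sweeteners(reviews, products, catalog)
  over <- osw_oversweet_flags(reviews, labels)
  k_all <- sum(over); n_all <- nrow(reviews)
  stopifnot(n_all > 0L)
  class_of <- catalog$caloric_class
  names(class_of) <- catalog$canonical_name
  pclasses <- lapply(products$sweeteners, function(s) unique(unname(class_of[s])))
  rows <- list()
  for (cl in .osw_caloric_classes) {
    pids <- products$product_id[vapply(pclasses, function(s) cl %in% s, logical(1L))]
    if (!length(pids)) next
    sel <- reviews$product_id %in% pids
    ns <- sum(sel)
    if (ns == 0L) next
    ks <- sum(over & sel)
    rows[[length(rows) + 1L]] <- data.table(
      caloric_class = cl, n_reviews = ns, n_oversweet = ks,
      proportion = ks / ns, baseline_proportion = k_all / n_all,
      p_raw = suppressMessages(prop_test_two_sided(ks, ns, k_all, n_all)))
  }
  if (!length(rows)) {
    return(data.table(caloric_class = character(), n_reviews = integer(),
                      n_oversweet = integer(), proportion = numeric(),
                      baseline_proportion = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  }
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := bonferroni_adjust(p_raw, m = .N)]
  out[, significant := p_adjusted < alpha]
  data.table::setorder(out, -n_reviews, caloric_class)
  out[]
}

#' Product-level rating comparison of oversweet vs other reviews
#'
#' Products with more than `min_reviews` reviews (strict) and at least
#' `min_oversweet_frac` oversweet reviews are retained; per product, a
#' one-sided Wilcoxon rank-sum test of the alternative "oversweet
#' ratings are lower", Benjamini-Hochberg adjusted across the retained
#' products. Reviews with missing ratings are excluded from the rating
#' comparison (their count is reported in the
#' `n_excluded_missing_rating` attribute) but still count toward the
#' retention filters.
#'
#' @param reviews review table with `rating`.
#' @param labels label table (`review_id`, `label`).
#' @param min_reviews retention threshold on total reviews (strict `>`).
#' @param min_oversweet_frac retention threshold on the oversweet
#'   fraction (`>=`).
#' @param alpha significance level.
#' @return a `data.table`, one row per compared product: `product_id`,
#'   `n_oversweet`, `n_other` (rated reviews), `mean_oversweet`,
#'   `mean_other`, `p_raw`, `p_adjusted`, `significant`.
#' @export
compare_product_ratings <- function(reviews, labels, min_reviews = 50L,
                                    min_oversweet_frac = 0.10, alpha = 0.05) {
  reviews <- data.table::as.data.table(reviews)
  over <- osw_oversweet_flags(reviews, labels)
  rv <- copy(reviews)[, oversweet := over]
  filt <- rv[, .(n_total = .N, n_over = sum(oversweet)), by = product_id]
  keep <- filt[n_total > min_reviews & n_over / n_total >= min_oversweet_frac]
  if (nrow(keep) == 0L) {
    warning("no product passes the rating-comparison filters")
    return(data.table(product_id = character(), n_oversweet = integer(),
                      n_other = integer(), mean_oversweet = numeric(),
                      mean_other = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  }
  n_missing <- 0L
  rows <- list()
  for (pid in keep$product_id) {
    sub <- rv[product_id == pid]
    n_missing <- n_missing + sum(is.na(sub$rating))
    x <- sub[oversweet == TRUE & !is.na(rating)]$rating
    y <- sub[oversweet == FALSE & !is.na(rating)]$rating
    if (!length(x) || !length(y)) next   # cannot test without both groups rated
    rows[[length(rows) + 1L]] <- data.table(
      product_id = pid, n_oversweet = length(x), n_other = length(y),
      mean_oversweet = mean(x), mean_other = mean(y),
      p_raw = wilcoxon_one_sided(x, y))
  }
  if (!length(rows)) {
    warning("no retained product has rated reviews in both groups")
    return(data.table(product_id = character(), n_oversweet = integer(),
                      n_other = integer(), mean_oversweet = numeric(),
                      mean_other = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  }
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := bh_adjust(p_raw)]
  out[, significant := p_adjusted < alpha]
  data.table::setattr(out, "n_excluded_missing_rating", n_missing)
  out[]
}

#' Per-customer oversweet dispersion
#'
#' For customers with more than `min_reviews` reviews (strict), the
#' percentage of their reviews labeled oversweet; the summary reports
#' mean +- sd of that percentage and how many heavy reviewers exceed
#' 10%.
#'
#' @param reviews review table.
#' @param labels label table (`review_id`, `label`).
#' @param min_reviews heavy-reviewer threshold (strict `>`).
#' @return list with `customers` (a `data.table`: `customer_id`,
#'   `n_reviews`, `n_oversweet`, `oversweet_pct`) and `summary` (list
#'   with `mean_pct`, `sd_pct`, `n_customers`, `n_above_10pct`; `NULL`
#'   when no customer qualifies).
#' @export
customer_dispersion <- function(reviews, labels, min_reviews = 30L) {
  reviews <- data.table::as.data.table(reviews)
  over <- osw_oversweet_flags(reviews, labels)
  rv <- copy(reviews)[, oversweet := over]
  cust <- rv[, .(n_reviews = .N, n_oversweet = sum(oversweet)), by = customer_id]
  cust <- cust[n_reviews > min_reviews]
  cust[, oversweet_pct := 100 * n_oversweet / n_reviews]
  data.table::setorder(cust, -n_reviews, customer_id)
  summary <- if (nrow(cust)) {
    list(mean_pct = mean(cust$oversweet_pct),
         sd_pct = if (nrow(cust) > 1L) stats::sd(cust$oversweet_pct) else NA_real_,
         n_customers = nrow(cust),
         n_above_10pct = sum(cust$oversweet_pct > 10))
  } else NULL
  list(customers = cust[], summary = summary)
}
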