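## synthetic_data: generate review corpora with planted, fully-known
## structure (oversweet prevalence, per-sweetener effects, rating
## penalty, heavy reviewers) so every pipeline stage is testable
## without any download.

#' Packaged review-text templates
#'
#' @param path optional path to a template TSV (columns `kind`, `text`).
#' @return a `data.table` of templates, `{product}` as placeholder.
#' @export
default_phrase_templates <- function(path = NULL) {
  dt <- read_commented_tsv(path %||% osw_extdata("phrase_templates.tsv"))
  stopifnot(all(c("kind", "text") %in% names(dt)))
  dt
}

.osw_sim_kinds <- c("decoy", "under-sweet", "neutral", "sweet_only", "none")

#' Construct a simulation configuration
#'
#' Defaults are the paper-like stated world: planted review-level
#' oversweet prevalence 0.10 (between the reported 7.1% and 16.1%
#' oversweet shares of sweetness mentions), a 0.9-star rating penalty
#' for oversweet-perceiving reviewers, a positive sucralose log-odds
#' effect, sucrose as the dominant (baseline-setting) sweetener, and a
#' heavy-reviewer mixture so the customer-dispersion analysis has a
#' populated denominator. Among reviews containing an oversweet phrase,
#' the default decoy share is ~42%, echoing the near-balanced
#' manual-label split (57%/43%) between genuine and non-referring
#' oversweet phrases.
#'
#' Ratings are drawn from a latent normal (per-product mean
#' `rating_mean` + product jitter, sd `rating_sd`), minus the penalty
#' for oversweet reviews, then clamped to \[1, 5\] and rounded. With the
#' default mean 3.5 / sd 0.8 the realized mean star gap after
#' discretization is 0.89 for a planted 0.9-star penalty.
#'
#' @param n_products,n_customers,n_reviews corpus dimensions.
#' @param sweetener_catalog a sweetener catalog.
#' @param sweetener_assignment list with `sets` (list of canonical-name
#'   vectors) and `probs`; per-product distribution over sweetener sets.
#' @param base_oversweet_rate planted baseline probability that a review
#'   perceives the product as oversweet.
#' @param per_sweetener_log_odds named numeric: additive log-odds effect
#'   of each sweetener on the oversweet probability.
#' @param rating_mean,rating_sd latent rating distribution.
#' @param product_rating_sd sd of the per-product rating-mean jitter.
#' @param oversweet_rating_penalty planted star penalty (>= 0).
#' @param missing_rating_rate fraction of ratings left missing.
#' @param heavy_reviewer_fraction fraction of customers that are heavy
#'   reviewers.
#' @param heavy_reviewer_weight relative review-sampling weight of a
#'   heavy reviewer.
#' @param nonoversweet_mixture named probabilities over the
#'   non-oversweet review kinds (decoy, under-sweet, neutral,
#'   sweet_only, none); must sum to 1.
#' @param phrase_templates template table, see
#'   [default_phrase_templates()].
#' @param seed integer seed; the corpus is byte-reproducible under it.
#' @return an object of class `sweet_sim_config`.
#' @export
simulation_config <- function(n_products = 40L,
                              n_customers = 400L,
                              n_reviews = 4000L,
                              sweetener_catalog = oversweet::sweetener_catalog(),
                              sweetener_assignment = NULL,
                              base_oversweet_rate = 0.10,
                              per_sweetener_log_odds = c(
                                "sucralose" = 0.8,
                                "high fructose corn syrup" = 0.5,
                                "corn syrup" = 0.5,
                                "fructose" = 0.2),
                              rating_mean = 3.5,
                              rating_sd = 0.8,
                              product_rating_sd = 0.15,
                              oversweet_rating_penalty = 0.9,
                              missing_rating_rate = 0.02,
                              heavy_reviewer_fraction = 0.05,
                              heavy_reviewer_weight = 12,
                              nonoversweet_mixture = c(
                                decoy = 0.08, "under-sweet" = 0.12,
                                neutral = 0.25, sweet_only = 0.25, none = 0.30),
                              phrase_templates = default_phrase_templates(),
                              seed = 1L) {
  if (is.null(sweetener_assignment)) {
    sweetener_assignment <- list(
      sets = list("sucrose", c("sucrose", "corn syrup"),
                  "high fructose corn syrup", "sucralose",
                  "steviol glycosides", "erythritol", "honey",
                  "fructose", "glucose", "lactose"),
      probs = c(0.30, 0.10, 0.08, 0.12, 0.10, 0.08, 0.08, 0.06, 0.04, 0.04))
  }
  cfg <- structure(list(
    n_products = as.integer(n_products),
    n_customers = as.integer(n_customers),
    n_reviews = as.integer(n_reviews),
    sweetener_catalog = sweetener_catalog,
    sweetener_assignment = sweetener_assignment,
    base_oversweet_rate = base_oversweet_rate,
    per_sweetener_log_odds = per_sweetener_log_odds,
    rating_mean = rating_mean, rating_sd = rating_sd,
    product_rating_sd = product_rating_sd,
    oversweet_rating_penalty = oversweet_rating_penalty,
    missing_rating_rate = missing_rating_rate,
    heavy_reviewer_fraction = heavy_reviewer_fraction,
    heavy_reviewer_weight = heavy_reviewer_weight,
    nonoversweet_mixture = nonoversweet_mixture,
    phrase_templates = phrase_templates,
    seed = as.integer(seed)), class = "sweet_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' The default paper-like configuration
#'
#' A documented configuration whose planted parameters echo the headline
#' magnitudes of the analysis this package reimplements: 0.9-star
#' oversweet rating penalty, 0.10 oversweet prevalence, positive
#' sucralose effect.
#'
#' @param ... overrides forwarded to [simulation_config()].
#' @return a `sweet_sim_config`.
#' @export
default_paper_like_config <- function(...) simulation_config(...)

#' Validate a simulation configuration
#'
#' @param config a `sweet_sim_config`.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    stopifnot(n_products >= 1L, n_customers >= 1L, n_reviews >= n_products)
    stopifnot(base_oversweet_rate >= 0, base_oversweet_rate <= 1,
              missing_rating_rate >= 0, missing_rating_rate <= 1,
              heavy_reviewer_fraction >= 0, heavy_reviewer_fraction <= 1,
              oversweet_rating_penalty >= 0,
              rating_sd > 0, heavy_reviewer_weight > 0)
    if (abs(sum(nonoversweet_mixture) - 1) > 1e-8) {
      stop("nonoversweet_mixture must sum to 1")
    }
    if (!all(names(nonoversweet_mixture) %in% .osw_sim_kinds)) {
      stop("unknown review kind in nonoversweet_mixture")
    }
    bad <- setdiff(names(per_sweetener_log_odds), sweetener_catalog$canonical_name)
    if (length(bad)) stop("log-odds effect for unknown sweetener: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(unlist(sweetener_assignment$sets), sweetener_catalog$canonical_name)
    if (length(bad)) stop("sweetener_assignment names unknown sweetener: ",
                          paste(bad, collapse = ", "))
    stopifnot(length(sweetener_assignment$sets) == length(sweetener_assignment$probs),
              abs(sum(sweetener_assignment$probs) - 1) < 1e-8)
    need <- c("oversweet", names(nonoversweet_mixture)[nonoversweet_mixture > 0])
    miss <- setdiff(need, unique(phrase_templates$kind))
    if (length(miss)) stop("no phrase template for kind(s): ",
                           paste(miss, collapse = ", "))
  })
  invisible(TRUE)
}

## ingredient spelling used in generated products: must detect back to
## exactly the planted canonical set (no embedded other-synonym)
osw_ingredient_spelling <- function(canonical) {
  pick <- c("high fructose corn syrup" = "hfcs",
            "sucrose" = "cane sugar",
            "glucose" = "dextrose",
            "steviol glycosides" = "stevia extract")
  unname(ifelse(canonical %in% names(pick), pick[canonical], canonical))
}

.osw_name_adjectives <- c("crunchy", "golden", "classic", "morning", "double",
                          "toasted", "frosted", "fruity", "dark", "creamy",
                          "original", "berry", "vanilla", "chocolate", "honeyed",
                          "spiced", "tropical", "roasted", "zesty", "hearty")
.osw_name_nouns <- c("granola", "cookies", "cereal", "lemonade", "yogurt",
                     "trail mix", "protein bar", "iced tea", "muffin mix",
                     "waffle mix", "fruit snacks", "oatmeal", "soda",
                     "energy drink", "pudding", "crackers", "jam",
                     "chocolate bar", "syrup", "candy")

#' Generate a synthetic review corpus with planted ground truth
#'
#' Per review: a product and customer are sampled; the oversweet
#' indicator is drawn with probability
#' `plogis(qlogis(base_rate) + sum of sweetener effects)`; the text is
#' assembled from a template of the matching kind (oversweet reviews
#' embed an oversweet phrase; non-oversweet reviews draw a kind from
#' the configured mixture, including decoy templates whose oversweet
#' phrase refers to other products); the rating is a latent normal
#' minus the penalty if oversweet, clamped to \[1, 5\] and rounded.
#' Fully reproducible under the config seed.
#'
#' @param config a `sweet_sim_config`.
#' @param out_dir optional directory; when given, writes `reviews.csv`,
#'   `products.csv`, `truth_reviews.tsv`, `truth_products.tsv` and
#'   `config.json`.
#' @return an object of class `sweet_corpus`: list with `reviews`,
#'   `products`, `truth` (planted ground truth) and `config`.
#' @export
generate_corpus <- function(config = default_paper_like_config(), out_dir = NULL) {
  validate_sim_config(config)
  out <- with_seed(config$seed, osw_generate_corpus_impl(config))
  if (!is.null(out_dir)) write_corpus(out, out_dir)
  out
}

osw_generate_corpus_impl <- function(config) {
  np <- config$n_products; nc <- config$n_customers; n <- config$n_reviews

  ## products
  set_idx <- sample.int(length(config$sweetener_assignment$sets), np,
                        replace = TRUE, prob = config$sweetener_assignment$probs)
  sweeteners <- config$sweetener_assignment$sets[set_idx]
  pname <- paste(sample(.osw_name_adjectives, np, replace = TRUE),
                 sample(.osw_name_nouns, np, replace = TRUE))
  raw_ing <- vapply(sweeteners, function(s) {
    paste0("Ingredients: ",
           paste(c("water", osw_ingredient_spelling(s), "sea salt"),
                 collapse = ", "), ".")
  }, character(1L))
  eff <- vapply(sweeteners, function(s) {
    sum(config$per_sweetener_log_odds[intersect(s, names(config$per_sweetener_log_odds))])
  }, numeric(1L))
  p_over <- plogis(qlogis(config$base_oversweet_rate) + eff)
  mu_p <- config$rating_mean + rnorm(np, 0, config$product_rating_sd)
  products <- data.table(
    product_id = sprintf("P%05d", seq_len(np)),
    name = pname,
    category = sample(c("snacks", "beverages", "baking", "breakfast",
                        "condiments"), np, replace = TRUE),
    raw_ingredients = raw_ing)

  ## customers: two-component review-count mixture (heavy reviewers get
  ## a larger sampling weight, populating the >30-review stratum)
  n_heavy <- round(config$heavy_reviewer_fraction * nc)
  heavy <- sample.int(nc, n_heavy)
  w <- rep(1, nc); w[heavy] <- config$heavy_reviewer_weight
  cust <- sample.int(nc, n, replace = TRUE, prob = w)

  ## reviews
  prod <- sample.int(np, n, replace = TRUE)
  over <- runif(n) < p_over[prod]
  kind <- rep("oversweet", n)
  n_other <- sum(!over)
  if (n_other) {
    kind[!over] <- sample(names(config$nonoversweet_mixture), n_other,
                          replace = TRUE, prob = config$nonoversweet_mixture)
  }
  tpl <- config$phrase_templates
  ti <- integer(n)
  for (k in unique(kind)) {
    pool <- which(tpl$kind == k)
    rows <- which(kind == k)
    ti[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
  }
  ## fill {product} per template (vectorized per template id)
  text <- character(n)
  for (t in unique(ti)) {
    rows <- which(ti == t)
    parts <- strsplit(tpl$text[t], "{product}", fixed = TRUE)[[1L]]
    text[rows] <- if (length(parts) == 2L) {
      paste0(parts[1L], pname[prod[rows]], parts[2L])
    } else if (grepl("{product}", tpl$text[t], fixed = TRUE)) {
      paste0(parts[1L], pname[prod[rows]])
    } else {
      tpl$text[t]
    }
  }
  titles <- c("honest review", "quick review", "my thoughts",
              "repeat purchase", "for the family", "pantry staple",
              "weekly order", "as described")
  title <- titles[sample.int(length(titles), n, replace = TRUE)]
  latent <- rnorm(n, mu_p[prod], config$rating_sd) -
    config$oversweet_rating_penalty * over
  rating <- as.integer(pmin(5, pmax(1, round(latent))))
  rating[runif(n) < config$missing_rating_rate] <- NA_integer_
  date <- as.Date("2015-01-01") + sample.int(2500L, n, replace = TRUE)

  reviews <- data.table(
    review_id = sprintf("R%07d", seq_len(n)),
    product_id = products$product_id[prod],
    customer_id = sprintf("C%05d", cust),
    title = title, text = text, rating = rating, date = date)

  truth <- structure(list(
    reviews = data.table(review_id = reviews$review_id,
                         oversweet = over, kind = kind,
                         is_decoy = kind == "decoy"),
    products = data.table(product_id = products$product_id,
                          p_oversweet = p_over,
                          rating_mu = mu_p,
                          sweeteners = vapply(sweeteners, paste,
                                              character(1L), collapse = "|")),
    penalty = config$oversweet_rating_penalty,
    effects = config$per_sweetener_log_odds,
    base_oversweet_rate = config$base_oversweet_rate,
    seed = config$seed), class = "sweet_ground_truth")

  structure(list(reviews = reviews, products = products,
                 truth = truth, config = config),
            class = "sweet_corpus")
}

#' Write a generated corpus to disk
#'
#' Emits the same CSV schemas [read_reviews()] and [read_products()]
#' read, plus the ground truth as TSV and the scalar configuration as
#' JSON. Output is byte-stable for a fixed config.
#'
#' @param corpus a `sweet_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rv <- copy(corpus$reviews)
  rv[, date := format(date, "%Y-%m-%d")]
  data.table::fwrite(rv, file.path(dir, "reviews.csv"))
  data.table::fwrite(corpus$products, file.path(dir, "products.csv"))
  data.table::fwrite(corpus$truth$reviews, file.path(dir, "truth_reviews.tsv"),
                     sep = "\t")
  data.table::fwrite(corpus$truth$products, file.path(dir, "truth_products.tsv"),
                     sep = "\t")
  cfg <- corpus$config
  scal <- cfg[setdiff(names(cfg), c("sweetener_catalog", "phrase_templates",
                                    "sweetener_assignment"))]
  jsonlite::write_json(scal, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
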