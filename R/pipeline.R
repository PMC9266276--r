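## pipeline: orchestrate simulate -> tally -> label/train/predict ->
## stats, with a deterministic run manifest.

osw_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Label the oversweet-eligible reviews of a corpus
#'
#' Reviews with at least one oversweet-resolved mention are eligible.
#' A seeded subsample of size `labeled_fraction * n_eligible` receives
#' "manual" labels taken from the corpus ground truth (emulating manual
#' curation); a classifier trained on those labels predicts the rest.
#'
#' @param corpus a `sweet_corpus`.
#' @param lexicon a `sweet_lexicon`.
#' @param labeled_fraction fraction of eligible reviews labeled manually.
#' @param grid,k_folds,seed forwarded to [train_classifier()].
#' @return list with `labels` (all eligible reviews:
#'   `review_id`, `label`, `source`), `classifier`, `n_eligible`.
#' @export
label_corpus <- function(corpus, lexicon = default_lexicon(),
                         labeled_fraction = 0.4,
                         grid = data.frame(max_depth = c(2L, 3L),
                                           learning_rate = 0.3,
                                           n_trees = 60L),
                         k_folds = 5L, seed = 1L) {
  mentions <- resolve_mentions(corpus$reviews, lexicon)
  eligible_ids <- unique(mentions[resolved == "oversweet"]$review_id)
  rv <- corpus$reviews[review_id %in% eligible_ids]
  truth <- corpus$truth$reviews
  truth_lab <- ifelse(truth$oversweet, .osw_pos, .osw_neg)
  names(truth_lab) <- truth$review_id
  n_manual <- max(2L, ceiling(labeled_fraction * nrow(rv)))
  n_manual <- min(n_manual, nrow(rv))
  man_idx <- with_seed(seed + 1L, sample.int(nrow(rv), n_manual))
  manual <- rv[sort(man_idx)]
  manual_labels <- data.table(review_id = manual$review_id,
                              label = unname(truth_lab[manual$review_id]),
                              source = "manual")
  train_set <- cbind(manual[, .(review_id, title, text)],
                     label = manual_labels$label)
  clf <- train_classifier(train_set, grid = grid, k_folds = k_folds,
                          seed = seed + 2L)
  rest <- rv[-sort(man_idx)]
  model_labels <- predict(clf, rest)
  list(labels = rbind(manual_labels, model_labels),
       classifier = clf, n_eligible = nrow(rv))
}

#' Estimate the dataset-wide oversweet prevalence via the pipeline
#'
#' Matches the lexicon against every review, then filters the
#' oversweet-phrase reviews through the classifier so that decoy
#' mentions (oversweet phrases not about the purchased product) do not
#' count. The estimate is the fraction of all reviews classified
#' `oversweet-product`.
#'
#' @param reviews review table.
#' @param classifier a trained `sweet_classifier`.
#' @param lexicon a `sweet_lexicon`.
#' @return the estimated prevalence (fraction of all reviews).
#' @export
estimate_prevalence <- function(reviews, classifier,
                                lexicon = default_lexicon()) {
  reviews <- data.table::as.data.table(reviews)
  stopifnot(nrow(reviews) > 0L)
  mentions <- resolve_mentions(reviews, lexicon)
  eligible_ids <- unique(mentions[resolved == "oversweet"]$review_id)
  if (!length(eligible_ids)) return(0)
  lab <- predict(classifier, reviews[review_id %in% eligible_ids])
  sum(lab$label == .osw_pos) / nrow(reviews)
}

#' Run the full analysis pipeline on a synthetic corpus
#'
#' simulate -> tally -> categories -> label/train/predict -> stats.
#' All stage outputs plus a run manifest are written to `out_dir`;
#' outputs are byte-identical across reruns with the same seed (the
#' manifest deliberately records no wall-clock timing).
#'
#' @param config a `sweet_sim_config`.
#' @param out_dir output directory.
#' @param seed optional integer overriding `config$seed`.
#' @param lexicon a `sweet_lexicon`.
#' @param labeled_fraction fraction of eligible reviews labeled manually.
#' @param min_reviews,min_oversweet_frac,customer_min_reviews stats
#'   thresholds, see [compare_product_ratings()] and
#'   [customer_dispersion()].
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_paper_like_config(), out_dir,
                         seed = NULL, lexicon = default_lexicon(),
                         labeled_fraction = 0.4, min_reviews = 50L,
                         min_oversweet_frac = 0.10,
                         customer_min_reviews = 30L) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  corpus <- osw_stage("simulate", generate_corpus(config, out_dir = out_dir))

  tl <- osw_stage("tally", tally(corpus$reviews, lexicon))
  data.table::fwrite(tl$by_level, file.path(out_dir, "tally.tsv"), sep = "\t")
  data.table::fwrite(tl$two_row, file.path(out_dir, "tally_two_row.tsv"), sep = "\t")
  audit <- osw_stage("audit", resolve_mentions(corpus$reviews, lexicon))
  data.table::fwrite(audit, file.path(out_dir, "mentions_audit.tsv"), sep = "\t")

  cats <- osw_stage("categories",
                    suppressWarnings(category_frequencies(corpus$reviews)))
  data.table::fwrite(cats, file.path(out_dir, "categories.tsv"), sep = "\t")

  lab <- osw_stage("label", label_corpus(corpus, lexicon, labeled_fraction,
                                         seed = seed))
  data.table::fwrite(lab$labels, file.path(out_dir, "labels.tsv"), sep = "\t")

  products <- annotate_products(corpus$products)
  enr <- osw_stage("enrichment",
                   enrichment_by_sweetener(corpus$reviews, lab$labels, products))
  data.table::fwrite(enr, file.path(out_dir, "enrichment_sweetener.tsv"), sep = "\t")
  encl <- osw_stage("enrichment_caloric",
                    enrichment_by_caloric_class(corpus$reviews, lab$labels, products))
  data.table::fwrite(encl, file.path(out_dir, "enrichment_caloric_class.tsv"),
                     sep = "\t")
  cmp <- osw_stage("rating_comparison",
                   suppressWarnings(compare_product_ratings(
                     corpus$reviews, lab$labels,
                     min_reviews = min_reviews,
                     min_oversweet_frac = min_oversweet_frac)))
  data.table::fwrite(cmp, file.path(out_dir, "rating_comparison.tsv"), sep = "\t")
  disp <- osw_stage("dispersion",
                    customer_dispersion(corpus$reviews, lab$labels,
                                        min_reviews = customer_min_reviews))
  data.table::fwrite(disp$customers, file.path(out_dir, "customer_dispersion.tsv"),
                     sep = "\t")

  manifest <- list(
    tool = "oversweet",
    version = as.character(utils::packageVersion("oversweet")),
    seed = seed,
    lexicon_version = lexicon$version,
    thresholds = list(min_reviews = min_reviews,
                      min_oversweet_frac = min_oversweet_frac,
                      customer_min_reviews = customer_min_reviews,
                      alpha = 0.05),
    input_digests = as.list(tools::md5sum(
      file.path(out_dir, c("reviews.csv", "products.csv")))),
    counts = list(n_reviews = nrow(corpus$reviews),
                  n_products = nrow(corpus$products),
                  n_eligible = lab$n_eligible,
                  n_manual = sum(lab$labels$source == "manual"),
                  n_model = sum(lab$labels$source == "model"),
                  n_sweeteners_tested = nrow(enr),
                  n_classes_tested = nrow(encl),
                  n_products_compared = nrow(cmp),
                  n_heavy_customers = nrow(disp$customers)),
    classifier = list(hyperparameters = lab$classifier$hyperparameters,
                      metrics = lab$classifier$metrics),
    dispersion_summary = disp$summary,
    stages = list(simulate = "ok", tally = "ok", categories = "ok",
                  label = "ok", stats = "ok"))
  names(manifest$input_digests) <- c("reviews.csv", "products.csv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
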