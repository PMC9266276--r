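## word_categories: percentage of reviews mentioning each word category
## (taste, texture, price, customer service, health, olfaction,
## chemesthesis).

#' Packaged default word-category lists
#'
#' Editable defaults curated for this artifact; the taste category
#' includes the sweet-family words plus flavor, flavour, saltish, tart,
#' tangy and biter.
#'
#' @param path optional path to a TSV with columns `category`, `word`.
#' @return named list of lowercase word vectors, one per category.
#' @export
default_word_categories <- function(path = NULL) {
  dt <- read_commented_tsv(path %||% osw_extdata("word_categories.tsv"))
  stopifnot(all(c("category", "word") %in% names(dt)))
  cats <- unique(dt$category)
  out <- lapply(cats, function(cc) unique(tolower(dt$word[dt$category == cc])))
  names(out) <- cats
  out
}

#' Percentage of reviews mentioning each word category
#'
#' A review counts for a category iff at least one of its tokens is in
#' that category's word set (review-level counting: multiple hits count
#' once). Also reports, as the attribute `sweet_within_taste`, the share
#' of reviews containing a sweet-family word.
#'
#' @param reviews deduplicated review table.
#' @param category_lexicons named list of word vectors; overlapping
#'   categories trigger a warning, not an error.
#' @param text_fields text columns scanned.
#' @return a `data.table` with columns `category`, `n_reviews`, `pct`,
#'   with attribute `sweet_within_taste` (percent of reviews containing
#'   a sweet-family word).
#' @export
category_frequencies <- function(reviews,
                                 category_lexicons = default_word_categories(),
                                 text_fields = c("title", "text")) {
  reviews <- data.table::as.data.table(reviews)
  n <- nrow(reviews)
  if (n == 0L) stop("empty review set: category percentages are undefined")
  stopifnot(length(category_lexicons) > 0L, all(lengths(category_lexicons) > 0L))
  cats <- names(category_lexicons)
  if (length(cats) > 1L) {
    for (i in seq_len(length(cats) - 1L)) {
      for (k in seq(i + 1L, length(cats))) {
        ov <- intersect(category_lexicons[[i]], category_lexicons[[k]])
        if (length(ov)) {
          warning("categories '", cats[i], "' and '", cats[k],
                  "' overlap: ", paste(ov, collapse = ", "))
        }
      }
    }
  }
  toks <- osw_tokenize_all(osw_combine_text(reviews, text_fields))
  len <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  d <- rep.int(seq_len(n), len)
  hits <- function(words) {
    if (!length(flat)) return(0L)
    data.table::uniqueN(d[flat %in% words])
  }
  cnt <- vapply(category_lexicons, hits, integer(1L))
  out <- data.table(category = cats, n_reviews = cnt, pct = 100 * cnt / n)
  data.table::setattr(out, "sweet_within_taste", 100 * hits(sweet_family()) / n)
  out[]
}
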