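## sweetmatch: tokenize review text, extract one-word environments around
## sweet-family words, resolve each mention against the lexicon, and
## tally reviews per sweetness level.

osw_tokenize_all <- function(texts) {
  texts <- ifelse(is.na(texts), "", as.character(texts))
  low <- tolower(texts)
  low <- gsub("’", "'", low, fixed = TRUE)
  low <- gsub("[^a-z0-9']+", " ", low)
  toks <- strsplit(trimws(low), " +")
  lenv <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (!length(flat)) return(rep(list(character()), length(texts)))
  flat <- gsub("^'+|'+$", "", flat)
  keep <- nzchar(flat)
  d <- rep.int(seq_along(texts), lenv)
  unname(split(flat[keep], factor(d[keep], levels = seq_along(texts))))
}

#' Tokenize review text
#'
#' Lowercases and strips punctuation except intra-word apostrophes
#' (preserving "isn't"); deterministic.
#'
#' @param text a single character string.
#' @return character vector of lowercase word tokens.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  osw_tokenize_all(text)[[1L]]
}

osw_combine_text <- function(reviews, text_fields = c("title", "text")) {
  text_fields <- intersect(text_fields, names(reviews))
  stopifnot(length(text_fields) > 0L)
  parts <- lapply(text_fields, function(f) {
    v <- as.character(reviews[[f]])
    ifelse(is.na(v), "", v)
  })
  trimws(do.call(paste, parts))
}

#' Extract one-word environments around sweet-family words
#'
#' One window per token whose form is in [sweet_family()]; the window is
#' (previous word, matched word, next word) with `NA` at text boundaries.
#'
#' @param text a single character string.
#' @return a `data.table` with columns `token_index` (1-based), `prev`,
#'   `word`, `nxt`.
#' @export
extract_environments <- function(text) {
  tt <- tokenize(text)
  idx <- which(tt %in% sweet_family())
  data.table(
    token_index = idx,
    prev = ifelse(idx > 1L, tt[pmax(idx - 1L, 1L)], NA_character_),
    word = tt[idx],
    nxt = ifelse(idx < length(tt), tt[pmin(idx + 1L, length(tt))], NA_character_))
}

#' Resolve all sweetness mentions in a review corpus
#'
#' Scans the concatenation of the `text_fields` of every review for
#' sweet-family tokens and resolves each mention against the lexicon.
#' Precedence at a mention: an `excluded` surface suppresses any level
#' match; otherwise the longest covering surface wins, ties between
#' equal-length surfaces broken by level order oversweet > under-sweet >
#' neutral, then lexicographically; a mention covered by no surface is
#' `sweet-only`.
#'
#' This is also the per-mention audit log: one row per sweet-family
#' token with its window, the matched surface and the resolved level.
#'
#' @param reviews review table with at least `review_id` and the
#'   `text_fields` columns.
#' @param lexicon a `sweet_lexicon`.
#' @param text_fields character vector of text columns scanned, in order.
#' @return a `data.table` with columns `review_id`, `token_index`,
#'   `prev`, `word`, `nxt`, `resolved`, `matched_surface`.
#' @export
resolve_mentions <- function(reviews, lexicon = default_lexicon(),
                             text_fields = c("title", "text")) {
  rv <- data.table::as.data.table(reviews)
  txt <- osw_combine_text(rv, text_fields)
  toks <- osw_tokenize_all(txt)
  len <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  empty <- data.table(review_id = character(), token_index = integer(),
                      prev = character(), word = character(),
                      nxt = character(), resolved = character(),
                      matched_surface = character())
  if (!length(flat)) return(empty)
  doc <- rep.int(seq_along(len), len)
  docfirst <- cumsum(c(1L, len[-length(len)]))
  midx <- which(flat %in% sweet_family())
  if (!length(midx)) return(empty)
  mdoc <- doc[midx]
  dstart <- docfirst[mdoc]
  dend <- dstart + len[mdoc] - 1L

  surf <- lexicon$entries$surface
  slev <- lexicon$entries$level
  maxlen <- if (length(surf)) {
    max(lengths(strsplit(surf, " ", fixed = TRUE)))
  } else 0L

  cand <- list()
  for (L in seq_len(maxlen)) {
    for (s in seq_len(L) - 1L) {
      st <- midx - s
      ok <- which(st >= dstart & st + L - 1L <= dend)
      if (!length(ok)) next
      ii <- st[ok]
      cs <- flat[ii]
      if (L > 1L) for (jj in seq_len(L - 1L)) cs <- paste(cs, flat[ii + jj])
      hit <- match(cs, surf)
      h <- which(!is.na(hit))
      if (length(h)) {
        cand[[length(cand) + 1L]] <- data.table(m = ok[h], sid = hit[h], len = L)
      }
    }
  }

  res <- rep("sweet-only", length(midx))
  msurf <- rep(NA_character_, length(midx))
  if (length(cand)) {
    cd <- data.table::rbindlist(cand)
    cd[, level := slev[sid]]
    cd[, is_excl := level == "excluded"]
    cd[, lrank := ifelse(is_excl, 0L,
                         match(level, c("oversweet", "under-sweet", "neutral")))]
    cd[, surface := surf[sid]]
    best <- cd[order(m, -is_excl, -len, lrank, surface)][!duplicated(m)]
    res[best$m] <- ifelse(best$is_excl, "excluded", best$level)
    msurf[best$m] <- best$surface
  }
  data.table(review_id = rv$review_id[mdoc],
             token_index = midx - dstart + 1L,
             prev = ifelse(midx > dstart, flat[pmax(midx - 1L, 1L)], NA_character_),
             word = flat[midx],
             nxt = ifelse(midx < dend, flat[pmin(midx + 1L, length(flat))], NA_character_),
             resolved = res,
             matched_surface = msurf)
}

#' Resolve a single sweetness mention
#'
#' @param tokens character vector of tokens of one document.
#' @param token_index 1-based index of the sweet-family token to resolve.
#' @param lexicon a `sweet_lexicon`.
#' @return a one-row `data.table` as in [resolve_mentions()].
#' @export
resolve_mention <- function(tokens, token_index, lexicon = default_lexicon()) {
  stopifnot(token_index >= 1L, token_index <= length(tokens),
            tokens[token_index] %in% sweet_family())
  rv <- data.table(review_id = "doc", text = paste(tokens, collapse = " "))
  m <- resolve_mentions(rv, lexicon, text_fields = "text")
  m[m$token_index == token_index][1L]
}

#' Tally reviews by sweetness level
#'
#' A review contributes to a level's count iff it has at least one
#' mention resolved to that level (under `collapse = "multi"`, the
#' default, a review may contribute to several levels; under
#' `"dominant"` each review counts once, at its highest-precedence
#' level). Percentages are computed over the sum of the four category
#' counts (oversweet, under-sweet, neutral, sweet-only); `excluded`
#' mentions never count.
#'
#' @param reviews deduplicated review table.
#' @param lexicon a `sweet_lexicon`.
#' @param collapse `"multi"` or `"dominant"`.
#' @param text_fields text columns scanned.
#' @return an object of class `sweet_tally`: list with `by_level`
#'   (4-row table of counts and percentages), `two_row` (oversweet vs
#'   all other sweetness mentions) and `total_reviews_with_sweetness`.
#' @export
tally <- function(reviews, lexicon = default_lexicon(),
                  collapse = c("multi", "dominant"),
                  text_fields = c("title", "text")) {
  collapse <- match.arg(collapse)
  mentions <- resolve_mentions(reviews, lexicon, text_fields)
  lv <- mentions[resolved != "excluded", .(review_id, resolved)]
  lv <- unique(lv)
  if (collapse == "dominant" && nrow(lv)) {
    lv[, lrank := match(resolved, .osw_tally_levels)]
    lv <- lv[order(review_id, lrank)][!duplicated(review_id)][, lrank := NULL]
  }
  counts <- vapply(.osw_tally_levels,
                   function(l) sum(lv$resolved == l), integer(1L))
  tot4 <- sum(counts)
  by_level <- data.table(level = .osw_tally_levels,
                         n_reviews = counts,
                         pct = if (tot4 > 0L) 100 * counts / tot4 else rep(0, 4L))
  n_sweet_reviews <- data.table::uniqueN(lv$review_id)
  n_over <- data.table::uniqueN(lv[resolved == "oversweet"]$review_id)
  two_row <- data.table(
    level = c("oversweet", "other sweetness"),
    n_reviews = c(n_over, n_sweet_reviews - n_over),
    pct = if (n_sweet_reviews > 0L) {
      100 * c(n_over, n_sweet_reviews - n_over) / n_sweet_reviews
    } else c(0, 0))
  structure(list(by_level = by_level, two_row = two_row,
                 total_reviews_with_sweetness = n_sweet_reviews,
                 n_reviews_total = nrow(reviews), collapse = collapse),
            class = "sweet_tally")
}

#' @export
print.sweet_tally <- function(x, ...) {
  cat("Reviews with sweetness mentions:", x$total_reviews_with_sweetness,
      "of", x$n_reviews_total, "\n")
  print(x$by_level)
  cat("Two-row view (oversweet vs other sweetness):\n")
  print(x$two_row)
  invisible(x)
}
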