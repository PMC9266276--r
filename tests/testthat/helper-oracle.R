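# Brute-force oracle for the sweetness-phrase matcher: for every lexicon
# surface, scan all token n-grams of the document and collect the
# surfaces covering each sweet-family token; apply the same precedence
# (excluded > longest > oversweet > under-sweet > neutral > lexicographic).
# Surface-centric and loop-based, independent of the package's
# mention-centric vectorized matcher.

oracle_resolve_tokens <- function(tokens, lexicon) {
  fam <- sweet_family()
  pos <- which(tokens %in% fam)
  out <- data.frame(token_index = pos,
                    resolved = rep("sweet-only", length(pos)),
                    matched_surface = rep(NA_character_, length(pos)),
                    stringsAsFactors = FALSE)
  if (!length(pos) || !nrow(lexicon$entries)) return(out)
  surfs <- lexicon$entries$surface
  levs <- lexicon$entries$level
  stoks <- strsplit(surfs, " ", fixed = TRUE)
  nt <- length(tokens)
  cover <- vector("list", length(pos))   # candidate matches per mention
  for (si in seq_along(surfs)) {
    st <- stoks[[si]]
    L <- length(st)
    if (L > nt) next
    for (start in seq_len(nt - L + 1L)) {
      if (!all(tokens[start:(start + L - 1L)] == st)) next
      covered <- which(pos >= start & pos <= start + L - 1L)
      for (ci in covered) {
        cover[[ci]] <- rbind(cover[[ci]],
                             data.frame(surface = surfs[si], level = levs[si],
                                        len = L, stringsAsFactors = FALSE))
      }
    }
  }
  for (ci in seq_along(pos)) {
    df <- cover[[ci]]
    if (is.null(df)) next
    df$is_excl <- df$level == "excluded"
    df$lrank <- ifelse(df$is_excl, 0L,
                       match(df$level, c("oversweet", "under-sweet", "neutral")))
    df <- df[order(-df$is_excl, -df$len, df$lrank, df$surface), , drop = FALSE]
    out$resolved[ci] <- if (df$is_excl[1L]) "excluded" else df$level[1L]
    out$matched_surface[ci] <- df$surface[1L]
  }
  out
}

oracle_mentions <- function(reviews, lexicon) {
  res <- lapply(seq_len(nrow(reviews)), function(i) {
    txt <- paste(reviews$title[i], reviews$text[i])
    m <- oracle_resolve_tokens(tokenize(txt), lexicon)
    if (nrow(m)) m$review_id <- reviews$review_id[i]
    m
  })
  do.call(rbind, res[vapply(res, nrow, integer(1L)) > 0])
}

oracle_tally_counts <- function(reviews, lexicon) {
  m <- oracle_mentions(reviews, lexicon)
  levels4 <- c("oversweet", "under-sweet", "neutral", "sweet-only")
  if (is.null(m)) return(stats::setNames(integer(4L), levels4))
  sapply(levels4, function(l) {
    length(unique(m$review_id[m$resolved == l]))
  })
}

# Independent closed-form oracle for the continuity-corrected 2x2
# chi-square (Yates, capped so identical proportions give statistic 0).
yates_oracle <- function(k1, n1, k2, n2) {
  a <- k1; b <- n1 - k1; cc <- k2; d <- n2 - k2; N <- n1 + n2
  stat <- N * max(0, abs(a * d - b * cc) - N / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Exhaustive enumeration oracle for the one-sided rank-sum test: the
# share of all m-subsets of ranks whose sum is as small as observed.
wilcox_enum_oracle <- function(x, y) {
  m <- length(x); N <- m + length(y)
  W <- sum(rank(c(x, y))[seq_len(m)])
  sums <- combn(N, m, sum)
  mean(sums <= W)
}

# Random corpora with controlled sweetness phrases, for matcher fuzzing.
random_corpus <- function(n_reviews, seed) {
  words <- c("sweet", "sweetness", "sweeter", "sweetener", "too", "very",
             "not", "enough", "tooth", "way", "the", "a", "i", "love",
             "this", "tea", "is", "so", "much", "isn't", "flavor", "bit")
  set.seed(seed)
  texts <- vapply(seq_len(n_reviews), function(i) {
    paste(sample(words, sample(3:12, 1L), replace = TRUE), collapse = " ")
  }, character(1L))
  data.table::data.table(review_id = sprintf("r%04d", seq_len(n_reviews)),
                         title = "", text = texts)
}

random_lexicon <- function(seed) {
  pool <- c("too sweet" = "oversweet", "way too sweet" = "oversweet",
            "much too sweet" = "oversweet", "so sweet" = "oversweet",
            "very sweet" = "neutral", "sweet enough" = "neutral",
            "sweet tea" = "neutral", "a bit sweet" = "neutral",
            "not sweet" = "under-sweet", "sweetener" = "excluded",
            "sweet tooth" = "excluded")
  set.seed(seed)
  base <- pool[sort(sample(seq_along(pool), sample(4:8, 1L)))]
  build_lexicon(base,
                negation_prefixes = c("not", "isn't"),
                misspellings = list(too = "to"),
                exclusion_suffixes = "tooth")
}
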