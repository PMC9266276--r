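## corpus_io: read/write review and product tables, deduplicate reviews,
## normalize ingredient strings, detect sweeteners per product.

.osw_review_cols <- c("review_id", "product_id", "customer_id",
                      "title", "text", "rating", "date")
.osw_product_cols <- c("product_id", "name", "category", "raw_ingredients")

osw_sep_for <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Parse calendar dates permissively
#'
#' Accepts ISO (`2020-06-24`) and common US (`6/24/2020`) forms; anything
#' unparseable becomes `NA` rather than an error, since dates are
#' descriptive only in this pipeline.
#'
#' @param x character vector of date strings.
#' @return a `Date` vector with `NA` for unparseable entries.
#' @export
parse_date_permissive <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  for (fmt in c("%Y-%m-%d", "%Y/%m/%d", "%m/%d/%Y", "%d %B %Y", "%B %d, %Y")) {
    todo <- is.na(out) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.Date(x[todo], format = fmt)
  }
  out
}

#' Read a review table
#'
#' Reads a CSV/TSV review table (dialect chosen from the file extension)
#' with columns `review_id`, `product_id`, `customer_id`, `title`, `text`,
#' `rating`, `date`. Ratings must be integers 1-5 or empty; empty ratings
#' are preserved as `NA`, never coerced to 0.
#'
#' @param path path to a CSV or TSV file with a header row.
#' @return a `data.table`, one row per review; `rating` is integer,
#'   `date` is `Date` (possibly `NA`).
#' @export
read_reviews <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = osw_sep_for(path), header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  miss <- setdiff(.osw_review_cols, names(dt))
  if (length(miss)) {
    stop("schema error: missing required column(s): ", paste(miss, collapse = ", "))
  }
  raw <- trimws(dt$rating)
  num <- suppressWarnings(as.numeric(raw))
  has <- !is.na(raw) & nzchar(raw) & tolower(raw) != "na"
  bad <- has & (is.na(num) | num %% 1 != 0 | num < 1 | num > 5)
  if (any(bad)) {
    stop("unparseable rating (must be an integer 1-5) in row(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  out <- dt[, .osw_review_cols, with = FALSE]
  out[, rating := ifelse(has, as.integer(num), NA_integer_)]
  out[, date := parse_date_permissive(dt$date)]
  out[]
}

#' Read a product table
#'
#' @param path path to a CSV/TSV file with columns `product_id`, `name`,
#'   `category`, `raw_ingredients`.
#' @return a `data.table`, one row per product.
#' @export
read_products <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = osw_sep_for(path), header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  miss <- setdiff(.osw_product_cols, names(dt))
  if (length(miss)) {
    stop("schema error: missing required column(s): ", paste(miss, collapse = ", "))
  }
  dt[, .osw_product_cols, with = FALSE][]
}

#' Deduplicate reviews
#'
#' Removes duplicated reviews, keeping the first occurrence (deterministic
#' order). The duplicate key is configurable because "duplicated" is
#' ambiguous for cross-posted reviews of product variants: under the
#' `"strict"` preset two identical texts on different products are both
#' kept; under the `"text"` preset they collapse to one.
#'
#' @param reviews a review `data.table` as returned by [read_reviews()].
#' @param key `"strict"` (product_id, customer_id, title, text) or
#'   `"text"` (title, text); alternatively pass `cols` directly.
#' @param cols optional explicit character vector of key columns,
#'   overriding `key`.
#' @return the deduplicated `data.table`, first occurrences retained.
#' @export
deduplicate_reviews <- function(reviews, key = c("strict", "text"), cols = NULL) {
  if (is.null(cols)) {
    key <- match.arg(key)
    cols <- switch(key,
                   strict = c("product_id", "customer_id", "title", "text"),
                   text = c("title", "text"))
  }
  stopifnot(all(cols %in% names(reviews)))
  unique(data.table::as.data.table(reviews), by = cols)
}

#' Default filler-word lexicon for ingredient strings
#'
#' @return character vector of lowercase filler words.
#' @export
default_filler_words <- function() {
  lines <- readLines(osw_extdata("filler_words.txt"), encoding = "UTF-8")
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines[nzchar(lines)]
}

osw_normalize_ingredients_all <- function(raw, filler) {
  low <- tolower(ifelse(is.na(raw), "", raw))
  low <- gsub("[^a-z0-9]+", " ", low)
  toks <- strsplit(trimws(low), " +", fixed = FALSE)
  lapply(toks, function(tt) tt[nzchar(tt) & !(tt %in% filler)])
}

#' Normalize a raw ingredient string
#'
#' Lowercases, strips punctuation (commas, parentheses, asterisks, ...)
#' and drops filler words ("ingredients", "with", ...), returning the
#' ordered remaining tokens. An empty string yields an empty vector.
#'
#' @param raw_ingredients a single raw ingredient string.
#' @param filler_lexicon character vector of filler words to drop.
#' @return character vector of normalized tokens.
#' @export
normalize_ingredients <- function(raw_ingredients,
                                  filler_lexicon = default_filler_words()) {
  stopifnot(length(raw_ingredients) == 1L)
  osw_normalize_ingredients_all(raw_ingredients, filler_lexicon)[[1L]]
}

#' Packaged sweetener catalog
#'
#' Sweetener ontology with one row per canonical sweetener, its synonym
#' set and its caloric class (caloric, non-caloric, sugar alcohol, sugar
#' fiber). The canonical name is always a member of its own synonym set.
#'
#' @param path optional path to a catalog TSV in the packaged format;
#'   defaults to the packaged catalog.
#' @return a `data.table` with columns `canonical_name`, `caloric_class`
#'   and a list-column `synonyms`.
#' @export
sweetener_catalog <- function(path = NULL) {
  if (is.null(path) && !is.null(.osw_cache$catalog)) return(copy(.osw_cache$catalog))
  dt <- read_commented_tsv(path %||% osw_extdata("sweeteners.tsv"))
  stopifnot(all(c("canonical_name", "caloric_class", "synonyms") %in% names(dt)))
  bad <- !dt$caloric_class %in% .osw_caloric_classes
  if (any(bad)) {
    stop("invalid caloric_class: ", paste(unique(dt$caloric_class[bad]), collapse = ", "))
  }
  syn <- strsplit(dt$synonyms, "|", fixed = TRUE)
  syn <- Map(function(s, canon) unique(c(canon, trimws(s))), syn, dt$canonical_name)
  out <- data.table(canonical_name = dt$canonical_name,
                    caloric_class = dt$caloric_class,
                    synonyms = syn)
  if (is.null(path)) .osw_cache$catalog <- copy(out)
  out
}

## default phrases whose presence blocks a shorter synonym hit
## ("sugar free" must not register sucrose)
.osw_blocked_phrases <- c("sugar free", "sugar alcohol", "sugar alcohols")

#' Detect sweeteners in a normalized ingredient token list
#'
#' Multi-word synonyms are matched against consecutive tokens (not raw
#' substrings), and single-token hits that are part of a blocked phrase
#' such as "sugar free" are suppressed.
#'
#' @param ingredients character vector of normalized ingredient tokens.
#' @param catalog sweetener catalog, see [sweetener_catalog()].
#' @param blocked character vector of blocked phrases.
#' @return sorted character vector (a set) of canonical sweetener names.
#' @export
detect_sweeteners <- function(ingredients, catalog = sweetener_catalog(),
                              blocked = .osw_blocked_phrases) {
  stopifnot(nrow(catalog) > 0L)
  n <- length(ingredients)
  if (n == 0L) return(character())
  bigrams <- if (n > 1L) paste(ingredients[-n], ingredients[-1L]) else character()
  found <- character()
  for (r in seq_len(nrow(catalog))) {
    for (syn in catalog$synonyms[[r]]) {
      st <- strsplit(syn, " ", fixed = TRUE)[[1L]]
      L <- length(st)
      if (L > n) next
      starts <- which(ingredients == st[1L])
      starts <- starts[starts + L - 1L <= n]
      ok <- starts[vapply(starts, function(i) {
        all(ingredients[i:(i + L - 1L)] == st)
      }, logical(1L))]
      if (length(ok)) {
        ## suppress hits whose edge extends into a blocked phrase
        ## ("sugar free" must not register sucrose via "sugar" or
        ## "brown sugar")
        ok <- ok[vapply(ok, function(i) {
          last <- i + L - 1L
          after <- if (last < n) paste(ingredients[last], ingredients[last + 1L]) else ""
          before <- if (i > 1L) paste(ingredients[i - 1L], ingredients[i]) else ""
          !(after %in% blocked || before %in% blocked)
        }, logical(1L))]
      }
      if (length(ok)) {
        found <- c(found, catalog$canonical_name[r])
        break
      }
    }
  }
  sort(unique(found))
}

#' Annotate products with normalized ingredients and detected sweeteners
#'
#' @param products product `data.table` with a `raw_ingredients` column.
#' @param catalog sweetener catalog.
#' @param filler_lexicon filler words for [normalize_ingredients()].
#' @return copy of `products` with list-columns `ingredients` and
#'   `sweeteners` added.
#' @export
annotate_products <- function(products, catalog = sweetener_catalog(),
                              filler_lexicon = default_filler_words()) {
  out <- data.table::as.data.table(products)
  ing <- osw_normalize_ingredients_all(out$raw_ingredients, filler_lexicon)
  out[, ingredients := ing]
  out[, sweeteners := lapply(ing, detect_sweeteners, catalog = catalog)]
  out[]
}

#' Restrict products to the analysis set
#'
#' Products without any review or with an empty ingredient list are
#' excluded from analysis sets.
#'
#' @param products annotated product table (see [annotate_products()]).
#' @param reviews review table used to determine which products have reviews.
#' @return the filtered product `data.table`.
#' @export
analysis_products <- function(products, reviews) {
  products <- data.table::as.data.table(products)
  if (!"ingredients" %in% names(products)) {
    products <- annotate_products(products)
  }
  has_rev <- products$product_id %in% unique(reviews$product_id)
  has_ing <- lengths(products$ingredients) > 0L
  products[has_rev & has_ing]
}

#' Write the normalized product table with per-sweetener indicator columns
#'
#' Emits a TSV with one boolean column per catalog sweetener indicating
#' its presence in each product's ingredient list.
#'
#' @param products annotated product table.
#' @param path output TSV path.
#' @param catalog sweetener catalog defining the indicator columns.
#' @return the written `data.table`, invisibly.
#' @export
write_product_table <- function(products, path, catalog = sweetener_catalog()) {
  products <- data.table::as.data.table(products)
  if (!"sweeteners" %in% names(products)) products <- annotate_products(products, catalog)
  out <- products[, .(product_id, name, category)]
  for (canon in catalog$canonical_name) {
    col <- paste0("has_", gsub(" ", "_", canon))
    out[, (col) := vapply(products$sweeteners, function(s) canon %in% s, logical(1L))]
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(out)
}
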