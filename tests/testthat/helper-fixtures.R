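# Shared fixtures built in code at test time.

write_review_csv <- function(df, path = tempfile(fileext = ".csv")) {
  data.table::fwrite(df, path)
  path
}

make_reviews <- function(texts, titles = "", ratings = 5L,
                         product_ids = "P1", customer_ids = "C1") {
  n <- length(texts)
  data.table::data.table(
    review_id = sprintf("R%03d", seq_len(n)),
    product_id = rep_len(product_ids, n),
    customer_id = rep_len(customer_ids, n),
    title = rep_len(titles, n),
    text = texts,
    rating = rep_len(ratings, n),
    date = as.Date("2020-01-01"))
}

truth_labels <- function(corpus) {
  tr <- corpus$truth$reviews
  data.table::data.table(
    review_id = tr$review_id,
    label = ifelse(tr$oversweet, "oversweet-product", "not-oversweet-product"),
    source = "manual")
}
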