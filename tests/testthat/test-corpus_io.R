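test_that("read_reviews ingests well-formed tables and enforces the schema", {
  df <- make_reviews(c("nice", "too sweet", "ok"), ratings = c(5L, 1L, NA))
  path <- write_review_csv(df)
  rv <- read_reviews(path)
  expect_equal(nrow(rv), 3L)
  expect_identical(rv$rating, c(5L, 1L, NA_integer_))
  expect_s3_class(rv$date, "Date")

  no_rating <- df[, !"rating"]
  expect_error(read_reviews(write_review_csv(no_rating)),
               "missing required column.*rating")

  bad <- data.table::copy(df)[2L, rating := 6L]
  expect_error(read_reviews(write_review_csv(bad)), "row")
})

test_that("dates are parsed permissively, unparseable kept missing", {
  d <- parse_date_permissive(c("2020-06-24", "6/24/2020", "not a date", ""))
  expect_identical(d[1], d[2])
  expect_true(all(is.na(d[3:4])))
})

test_that("deduplicate_reviews: key policies, first occurrence wins", {
  # same customer, title and text cross-posted on two product variants
  rv <- make_reviews(c("too sweet", "too sweet"), titles = "dup",
                     product_ids = c("P1", "P2"))
  expect_equal(nrow(deduplicate_reviews(rv, key = "strict")), 2L)
  txt <- deduplicate_reviews(rv, key = "text")
  expect_equal(nrow(txt), 1L)
  expect_identical(txt$review_id, "R001")   # first occurrence retained

  # fully distinct reviews are untouched; exact duplicates collapse
  distinct <- make_reviews(c("a", "b", "c"))
  expect_identical(deduplicate_reviews(distinct), distinct)
  triple <- make_reviews(rep("same text", 3L), titles = "t")
  triple[, review_id := "R001"]
  expect_equal(nrow(deduplicate_reviews(triple)), 1L)
})

test_that("deduplicate_reviews is idempotent", {
  set.seed(11)
  rv <- make_reviews(sample(letters[1:4], 30, replace = TRUE),
                     product_ids = sample(c("P1", "P2"), 30, replace = TRUE))
  once <- deduplicate_reviews(rv)
  expect_identical(deduplicate_reviews(once), once)
})

test_that("normalize_ingredients strips punctuation and filler words", {
  expect_identical(
    normalize_ingredients("Ingredients: Sugar, Cocoa (processed with alkali)."),
    c("sugar", "cocoa", "processed", "alkali"))
  expect_identical(normalize_ingredients(""), character())
  expect_identical(normalize_ingredients("SUGAR"), "sugar")
})

test_that("normalize_ingredients never returns filler tokens", {
  filler <- default_filler_words()
  set.seed(3)
  pool <- c(filler, "sugar", "cocoa", "milk", "salt", "vanilla")
  for (i in 1:25) {
    raw <- paste(sample(pool, sample(1:12, 1), replace = TRUE), collapse = ", ")
    toks <- normalize_ingredients(raw)
    expect_false(any(toks %in% filler))
    expect_false(any(!nzchar(toks)))
  }
})

test_that("detect_sweeteners matches synonyms over consecutive tokens", {
  cat <- sweetener_catalog()
  expect_identical(detect_sweeteners(c("organic", "cane", "sugar"), cat), "sucrose")
  expect_identical(detect_sweeteners(c("water", "salt"), cat), character())
  expect_identical(detect_sweeteners(c("sucralose", "sucralose"), cat), "sucralose")
  # token-sequence matching, not substring: "sugar free" must not hit
  expect_identical(detect_sweeteners(c("sugar", "free"), cat), character())
  expect_identical(detect_sweeteners(c("brown", "sugar", "free"), cat), character())
  # multi-word synonym split across other tokens is no match
  expect_identical(detect_sweeteners(c("corn", "oil", "syrup"), cat), character())
})

test_that("detected sweeteners are always a subset of the catalog", {
  cat <- sweetener_catalog()
  set.seed(8)
  pool <- c(unlist(cat$synonyms), "water", "salt", "flour", "free")
  for (i in 1:25) {
    toks <- unlist(strsplit(sample(pool, sample(1:8, 1), replace = TRUE), " "))
    expect_true(all(detect_sweeteners(toks, cat) %in% cat$canonical_name))
  }
})

test_that("analysis set excludes products without reviews or ingredients", {
  products <- data.table::data.table(
    product_id = c("P1", "P2", "P3"),
    name = "x", category = "snacks",
    raw_ingredients = c("sugar", "", "honey"))
  reviews <- make_reviews(c("a", "b"), product_ids = c("P1", "P2"))
  kept <- analysis_products(annotate_products(products), reviews)
  expect_identical(kept$product_id, "P1")  # P2 empty ingredients, P3 no reviews
})

test_that("write_product_table emits one indicator column per sweetener", {
  cat <- sweetener_catalog()
  products <- annotate_products(data.table::data.table(
    product_id = "P1", name = "fizz", category = "beverages",
    raw_ingredients = "Ingredients: water, sucralose."))
  path <- tempfile(fileext = ".tsv")
  out <- write_product_table(products, path, cat)
  expect_true(file.exists(path))
  expect_equal(sum(unlist(out[, -(1:3)])), 1L)
  expect_true(out$has_sucralose)
})
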