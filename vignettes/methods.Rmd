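---
title: "Methods: mining food reviews for sweetness perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining food reviews for sweetness perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oversweet)
```

## The problem

Consumer reviews of food products are a large, spontaneous source of
sensory data. A recurring complaint in such reviews is that a product is
*too sweet*; linking that complaint to star ratings and to the
sweeteners on the ingredient list turns free text into actionable
sensory-nutrition evidence. `oversweet` implements that analysis as a
reusable pipeline:

1. **Phrase tagging** (`tally()`, `resolve_mentions()`): every
   occurrence of a sweet-family word (`sweet`, `sweetness`, `sweeter`,
   ...) is resolved against a phrase lexicon into *oversweet*,
   *under-sweet*, *neutral*, *sweet-only* (the bare word, matched by no
   phrase) or *excluded* ("sweet tooth", "sweetener", ...).
2. **Reference classification** (`train_classifier()`, `predict()`): a
   review containing an oversweet phrase does not necessarily call the
   purchased product oversweet ("I have had waffles from other mixes
   that are too sweet ... this mix is very good"). A bag-of-words
   gradient-boosted classifier separates genuine complaints from such
   non-referring mentions.
3. **Statistics** (`enrichment_by_sweetener()`,
   `compare_product_ratings()`, `customer_dispersion()`): per-sweetener
   enrichment of oversweet reviews (two-sided proportion tests,
   Bonferroni), per-product rating gaps between oversweet and other
   reviews (one-sided Wilcoxon rank-sum, Benjamini–Hochberg), and
   per-customer dispersion of oversweet complaints.
4. **Synthetic data** (`generate_corpus()`): a generator with planted
   ground truth, so that every stage is testable without any download.

## The lexicon model

The unit of matching is the *one-word environment*: for every
sweet-family token we consider all lexicon surfaces (1–6 words) that
cover it. Surfaces come from seed phrases expanded three ways:

* **Negation prefixes** (`not`, `isn't`, `isnt`, `wasn't`, `wasnt`,
  `never`) with a *flip table* deciding the level of the negated form.
  The table is data, not code: negated intensity complaints read as
  praise (`not too sweet` → neutral), negated plain-sweetness phrases
  assert a lack of sweetness (`not very sweet` → under-sweet), and
  negated under-sweet phrases are neutralized. The asymmetry is
  deliberate: "not too sweet" is colloquially an endorsement, not a
  sweetness complaint, whereas most negations of neutral sweetness
  phrases land in under-sweet.
* **Misspelling variants** keep the parent's level (`to sweet` for
  `too sweet`). Matching is literal; no fuzzy matching.
* **Exclusion suffixes** (`tooth`, `leaf`) void the sweetness reading;
  single-word exclusions (`sweetener`, `sweetheart`, ...) ship as
  seeds. "Enough" is handled in the seed data: `sweet enough` is a
  neutral seed, so the negation machinery derives `not sweet enough` →
  under-sweet.

Match precedence at a token is total, hence deterministic: an excluded
surface suppresses everything; otherwise the longest surface wins, ties
break by level (oversweet > under-sweet > neutral) and then
lexicographically. A review may count toward several levels
(multi-membership, the default) because the tallies count *mentions of
sweetness*; a dominant-level collapse is available as
`tally(..., collapse = "dominant")`. Matching always scans title and
text concatenated.

The packaged seeds (~60 oversweet, ~20 under-sweet, ~45 neutral, plus
exclusions) are curated for this artifact and are deliberately *not* a
reproduction of any published phrase inventory; the construction
procedure, not the verbatim list, is the point. Users can substitute
their own seed TSV in `build_lexicon()`.

## The classifier

Among reviews containing an oversweet phrase, genuine complaints are
separated from non-referring mentions with a bag-of-words boosted-tree
classifier. The reference implementation environment provides no
gradient-boosting library offline, so the package carries its own
deterministic engine (`fit_gbt()`): second-order logistic-loss
boosting on shallow trees whose splits are word-presence tests. For
sparse count features this makes split search over all words at a node
two sparse matrix–vector products, and it removes all training
randomness (no subsampling; gain ties break to the lowest feature
index). Hyperparameters (depth, learning rate, rounds) are grid-searched
by 10-fold cross-validated F1; the grid defaults
(`default_grid()`: depth {3, 6}, learning rate {0.1, 0.3}, trees
{100, 300}) are artifact choices, since no grid is published.

The vocabulary rule "the 99.5% most frequent words" is ambiguous; the
default reading is the smallest frequency-mass prefix
(`build_vocabulary(..., method = "mass")`), with a type-quantile
alternative behind a flag. The train/test split uses floor-then-
remainder sizing, so 5,590 labeled reviews at 75% split into exactly
4,192 + 1,398.

## Statistical choices

* `prop_test_two_sided()` is the closed-form 2×2 chi-square with Yates
  continuity correction, capped so equal proportions give statistic 0
  (matching `prop.test` defaults, which the source analysis used).
  Degenerate tables return p = 1 by convention, with a message.
* `wilcoxon_one_sided()` (alternative: oversweet ratings lower) uses
  exact enumeration via dynamic programming when the combined sample is
  ≤ 12 without ties, otherwise the normal approximation with tie and
  continuity corrections.
* Multiplicity: Bonferroni across sweeteners (m = sweeteners actually
  tested in the run, recorded in the manifest), Benjamini–Hochberg
  across retained products. Both adjustments dominate the raw p-values
  and cap at 1.
* Thresholds follow the printed wording strictly: products with *over*
  50 reviews (strict `>`) and *at least* 10% oversweet reviews (`>=`);
  customers with *over* 30 reviews (strict `>`).
* Missing ratings are excluded from rating comparisons (and counted in
  an attribute) but retained for proportion analyses, which need no
  rating.
* Reviews of multi-sweetener products count toward every sweetener they
  contain, and once per caloric class under class pooling.

## What the generator emulates — and what it does not

`default_paper_like_config()` states the world the package is tested
in; its values are fixed a priori from the headline magnitudes of the
source analysis and are not tuned to test outcomes:

* planted review-level oversweet prevalence 0.10 (between the reported
  7.1% and 16.1% oversweet shares of sweetness mentions);
* a 0.9-star rating penalty for oversweet-perceiving reviewers;
* a positive sucralose log-odds effect (+0.8) and smaller corn-syrup
  effects, with sucrose the dominant, baseline-setting sweetener (~40%
  of products);
* a decoy share making ~42% of oversweet-phrase reviews non-referring,
  echoing the reported 57%/43% manual-label balance;
* a two-component reviewer mixture so the over-30-reviews stratum is
  populated.

**Ratings are modeled latently.** Drawing integer stars and subtracting
a 0.9-star penalty would quantize the penalty to a full star after
rounding, contradicting the package's own recovery requirement (gap
within ±0.1 stars). Ratings are therefore drawn from a latent normal
(mean 3.5, product jitter sd 0.15, sd 0.8), penalized, clamped to
[1, 5] and rounded; closed-form integration shows the realized mean
star gap is then 0.89 for a planted 0.9 — the discretization bias the
real scale would also induce.

Review text is template-based: controllable lexicon hits, not fluent
prose. Decoy templates carry comparison markers ("other", "brands",
"unlike"), genuine complaints carry disposal/aversion markers, so the
classifier's task is deterministic and a ≥ 0.95 cross-validated
accuracy is a *sanity floor* — the 79–84% accuracies reported on real
text reflect noise this generator does not emulate, and are asserted
nowhere. Likewise a green recovery test establishes that the pipeline
machinery is correct, not that the packaged lexicon would reproduce any
published count on real corpora: vocabulary richness, review length
distributions and labeling ambiguity are all out of scope of the
generator.

The null-calibration and rating-gap acceptance tests feed the stats
stage with ground-truth labels: they isolate the statistical machinery,
while the classifier's contribution is tested separately (prevalence
recovery runs matcher → classifier → estimate end to end). The
customer-dispersion rarity property ("heavy reviewers above 10%
oversweet are rare") holds at the ~2% review-level oversweet rate the
source reports, not at the 10% prevalence planted for power elsewhere;
the dispersion test therefore uses a 0.02 base rate.

## Numerical and degenerate-input conventions

* Tally percentages are computed over the sum of the four category
  counts; an empty corpus reports 0 rather than NaN, while category
  frequencies on an empty review set are an error (no silent division
  by zero).
* Deduplication keys: "duplicated review" is ambiguous for cross-posted
  variants. The strict default key is (product_id, customer_id, title,
  text); a text-only key collapses cross-posts. First occurrence wins,
  so output order is deterministic.
* Synonym matching for sweeteners is over consecutive normalized
  tokens, never substrings, with blocked phrases ("sugar free")
  suppressing edge hits.
* The run manifest deliberately records no wall-clock timing: reruns
  under a fixed seed must be byte-identical, and determinism outranks
  the convenience of embedded timings (they go to the log instead).

## Known limitations

* The packaged lexicon's per-level phrase counts differ from any
  published inventory (only the four-category structure, including the
  single "sweet-only" fallback, is asserted).
* No syntactic parsing, embeddings, or sentiment models: the method is
  surface-phrase matching by design, and sarcasm or long-range
  reference ("the last one was too sweet; this one isn't") is resolved
  only insofar as the classifier's bag of words captures it.
* No modeling of sweetener concentration, synergy, or masking.
* Web scraping and the original corpora are out of scope; nothing here
  reproduces printed counts from those datasets.
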