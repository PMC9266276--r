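## lexicon: construct, validate, load and save the sweetness-phrase
## lexicon. Base phrases are expanded with negation prefixes (level
## flipped per a flip table), misspelling variants (level kept) and
## exclusion suffixes (level voided, e.g. "sweet tooth").

#' Sweet-family word forms
#'
#' The token forms treated as mentions of sweetness when scanning review
#' text.
#'
#' @return character vector of sweet-family tokens.
#' @export
sweet_family <- function() {
  c("sweet", "sweetness", "sweeter", "sweetest",
    "sweetened", "sweetener", "sweeteners", "sweets")
}

.osw_default_prefixes <- c("not", "isn't", "isnt", "wasn't", "wasnt", "never")
.osw_default_suffixes <- c("tooth", "leaf")
.osw_default_misspellings <- list(too = "to")
## Level of a negated phrase: negating an intensity complaint ("too
## sweet") yields praise, hence neutral; negating a plain-sweetness
## phrase ("very sweet") asserts lack of sweetness.
.osw_default_flip <- c("oversweet" = "neutral",
                       "under-sweet" = "neutral",
                       "neutral" = "under-sweet")

osw_as_base_phrases <- function(base_phrases) {
  if (is.data.frame(base_phrases)) {
    stopifnot(all(c("surface", "level") %in% names(base_phrases)))
    data.table(surface = as.character(base_phrases$surface),
               level = as.character(base_phrases$level))
  } else {
    data.table(surface = names(base_phrases), level = unname(base_phrases))
  }
}

#' Build a sweetness-phrase lexicon from base phrases
#'
#' Every base phrase must contain a sweet-family word. For each base
#' phrase the expansion adds: one entry per negation prefix with the
#' level flipped per `flip` (skipped when the phrase itself already
#' starts with a negation), one entry per misspelling variant with the
#' parent's level, and one `excluded` entry per exclusion suffix.
#' A surface generated twice with conflicting levels is a validation
#' error naming both parents.
#'
#' @param base_phrases named character vector (`phrase -> level`) or a
#'   data.frame with columns `surface`, `level`. Levels are `oversweet`,
#'   `under-sweet`, `neutral` or `excluded`.
#' @param negation_prefixes character vector of negation words prepended
#'   to each phrase.
#' @param misspellings named list, `word -> character vector` of
#'   misspelled variants substituted token-wise.
#' @param exclusion_suffixes words appended to yield `excluded` entries.
#' @param flip named character vector mapping a level to the level of its
#'   negated form.
#' @param version version string stored in the lexicon.
#' @return an object of class `sweet_lexicon`.
#' @export
build_lexicon <- function(base_phrases,
                          negation_prefixes = .osw_default_prefixes,
                          misspellings = .osw_default_misspellings,
                          exclusion_suffixes = .osw_default_suffixes,
                          flip = .osw_default_flip,
                          version = "1.0") {
  base <- osw_as_base_phrases(base_phrases)
  if (nrow(base) == 0L) {
    return(osw_new_lexicon(
      data.table(surface = character(), level = character(),
                 provenance = character(), parent = character()),
      negation_prefixes, exclusion_suffixes, version))
  }
  base[, surface := trimws(surface)]
  no_sweet <- !grepl("sweet", base$surface, fixed = TRUE)
  if (any(no_sweet)) {
    stop("base phrase(s) lacking 'sweet': ",
         paste(base$surface[no_sweet], collapse = "; "))
  }
  bad_level <- !base$level %in% .osw_levels
  if (any(bad_level)) {
    stop("invalid level(s): ", paste(unique(base$level[bad_level]), collapse = ", "))
  }
  stopifnot(all(names(flip) %in% .osw_levels), all(flip %in% .osw_levels))

  ent <- list(base[, .(surface, level, provenance = "base", parent = surface)])

  ## misspelling variants of base phrases
  if (length(misspellings)) {
    ms <- list()
    for (w in names(misspellings)) {
      has <- grepl(paste0("(^| )", w, "( |$)"), base$surface)
      for (v in misspellings[[w]]) {
        if (!any(has)) next
        ms[[length(ms) + 1L]] <- data.table(
          surface = gsub(paste0("(^| )", w, "( |$)"), paste0("\\1", v, "\\2"),
                         base$surface[has]),
          level = base$level[has], provenance = "misspelling",
          parent = base$surface[has])
      }
    }
    ent <- c(ent, ms)
  }

  expandable <- data.table::rbindlist(ent)[level != "excluded"]
  neg_guard <- union(negation_prefixes, c("no", "not", "never"))

  ## negated forms, level flipped
  if (length(negation_prefixes) && nrow(expandable)) {
    first_tok <- vapply(strsplit(expandable$surface, " ", fixed = TRUE),
                        `[`, character(1L), 1L)
    negatable <- expandable[!(first_tok %in% neg_guard)]
    if (nrow(negatable)) {
      for (pfx in negation_prefixes) {
        ent[[length(ent) + 1L]] <- data.table(
          surface = paste(pfx, negatable$surface),
          level = unname(flip[negatable$level]),
          provenance = "negated", parent = negatable$surface)
      }
    }
  }

  ## exclusion-suffix variants
  if (length(exclusion_suffixes) && nrow(expandable)) {
    for (sfx in exclusion_suffixes) {
      ent[[length(ent) + 1L]] <- data.table(
        surface = paste(expandable$surface, sfx),
        level = "excluded", provenance = "suffix-variant",
        parent = expandable$surface)
    }
  }

  entries <- data.table::rbindlist(ent)
  ## drop exact (surface, level) duplicates, first occurrence wins
  entries <- unique(entries, by = c("surface", "level"))
  dup <- entries[, .N, by = surface][N > 1L]
  if (nrow(dup)) {
    conf <- entries[surface %in% dup$surface]
    stop("surface collision with conflicting levels: ",
         paste(sprintf("'%s' (%s, from '%s')", conf$surface, conf$level, conf$parent),
               collapse = "; "))
  }
  osw_new_lexicon(entries, negation_prefixes, exclusion_suffixes, version)
}

osw_new_lexicon <- function(entries, negation_prefixes, exclusion_suffixes, version) {
  structure(list(entries = entries,
                 negation_prefixes = negation_prefixes,
                 exclusion_suffixes = exclusion_suffixes,
                 version = version),
            class = "sweet_lexicon")
}

#' Validate a sweetness lexicon
#'
#' @param lexicon a `sweet_lexicon`.
#' @return character vector of violation messages; empty iff all
#'   invariants hold.
#' @export
validate_lexicon <- function(lexicon) {
  e <- lexicon$entries
  v <- character()
  if (any(!nzchar(e$surface))) v <- c(v, "empty surface string")
  bad_case <- e$surface != tolower(e$surface) | grepl("  |^ | $", e$surface)
  if (any(bad_case)) {
    v <- c(v, paste0("surface not lowercase/single-spaced: ",
                     paste(e$surface[bad_case], collapse = "; ")))
  }
  dup <- e[, .N, by = surface][N > 1L]$surface
  if (length(dup)) {
    v <- c(v, paste0("surface under multiple entries: ", paste(dup, collapse = "; ")))
  }
  no_sweet <- !grepl("sweet", e$surface, fixed = TRUE)
  if (any(no_sweet)) {
    v <- c(v, paste0("surface lacking 'sweet': ",
                     paste(e$surface[no_sweet], collapse = "; ")))
  }
  bad_level <- !e$level %in% .osw_levels
  if (any(bad_level)) {
    v <- c(v, paste0("invalid level: ", paste(unique(e$level[bad_level]), collapse = ", ")))
  }
  nw <- lengths(strsplit(e$surface, " ", fixed = TRUE))
  if (any(nw > 6L)) {
    v <- c(v, paste0("surface longer than 6 words: ",
                     paste(e$surface[nw > 6L], collapse = "; ")))
  }
  v
}

#' The packaged default lexicon
#'
#' Built once per session from the packaged base-phrase seeds and the
#' default negation/misspelling/exclusion rules.
#'
#' @return a `sweet_lexicon`.
#' @export
default_lexicon <- function() {
  if (is.null(.osw_cache$lexicon)) {
    base <- read_commented_tsv(osw_extdata("base_phrases.tsv"))
    .osw_cache$lexicon <- build_lexicon(base, version = "1.0")
  }
  .osw_cache$lexicon
}

#' Save a lexicon as TSV
#'
#' Writes a TSV with columns surface/level/provenance, `#` comment lines
#' and `#!`-prefixed metadata (version, negation prefixes, exclusion
#' suffixes). [load_lexicon()] restores an identical object.
#'
#' @param lexicon a `sweet_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lexicon, path) {
  hdr <- c("# sweetness phrase lexicon",
           paste0("#! version\t", lexicon$version),
           paste0("#! negation_prefixes\t",
                  paste(lexicon$negation_prefixes, collapse = "|")),
           paste0("#! exclusion_suffixes\t",
                  paste(lexicon$exclusion_suffixes, collapse = "|")),
           "surface\tlevel\tprovenance")
  rows <- sprintf("%s\t%s\t%s", lexicon$entries$surface,
                  lexicon$entries$level, lexicon$entries$provenance)
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Load a lexicon saved by [save_lexicon()]
#'
#' @param path path to a lexicon TSV.
#' @return a `sweet_lexicon`.
#' @export
load_lexicon <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list(version = "1.0", negation_prefixes = character(),
               exclusion_suffixes = character())
  is_meta <- grepl("^#!", lines)
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^#!\\s*", "", ln), "\t", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed metadata line: ", ln)
    if (kv[1L] == "version") meta$version <- kv[2L]
    if (kv[1L] == "negation_prefixes") {
      meta$negation_prefixes <- strsplit(kv[2L], "|", fixed = TRUE)[[1L]]
    }
    if (kv[1L] == "exclusion_suffixes") {
      meta$exclusion_suffixes <- strsplit(kv[2L], "|", fixed = TRUE)[[1L]]
    }
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("parse error: no header row found")
  header <- strsplit(lines[body_idx[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("surface", "level", "provenance"))) {
    stop("parse error at line ", body_idx[1L],
         ": expected header 'surface\tlevel\tprovenance'")
  }
  rows <- body_idx[-1L]
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    stop("parse error at line ", rows[which(nfield != 3L)[1L]],
         ": expected 3 tab-separated fields")
  }
  entries <- data.table(surface = vapply(parts, `[`, character(1L), 1L),
                        level = vapply(parts, `[`, character(1L), 2L),
                        provenance = vapply(parts, `[`, character(1L), 3L))
  bad <- !entries$level %in% .osw_levels
  if (any(bad)) {
    stop("parse error at line ", rows[which(bad)[1L]],
         ": unknown level token '", entries$level[which(bad)[1L]], "'")
  }
  entries[, parent := NA_character_]
  osw_new_lexicon(entries, meta$negation_prefixes, meta$exclusion_suffixes,
                  meta$version)
}

#' Phrase counts by sweetness level
#'
#' Summary of lexicon size per level, with the bare sweet-family fallback
#' reported as its own single-entry "sweet only" category.
#'
#' @param lexicon a `sweet_lexicon`.
#' @return a `data.table` with columns `level` and `n_phrases`.
#' @export
lexicon_summary <- function(lexicon) {
  e <- lexicon$entries
  data.table(
    level = c("oversweet", "under-sweet", "neutral", "sweet only"),
    n_phrases = c(sum(e$level == "oversweet"), sum(e$level == "under-sweet"),
                  sum(e$level == "neutral"), 1L))
}

#' @export
print.sweet_lexicon <- function(x, ...) {
  cat("<sweet_lexicon> version", x$version, "-", nrow(x$entries), "entries\n")
  print(lexicon_summary(x))
  invisible(x)
}

#' Compare two lexicons for equality
#'
#' Entries (surface, level, provenance, in order), negation prefixes,
#' exclusion suffixes and version must all match; the `parent`
#' bookkeeping column is ignored so that [load_lexicon()] round-trips
#' to equality.
#'
#' @param a,b `sweet_lexicon` objects.
#' @return `TRUE` or `FALSE`.
#' @export
lexicons_equal <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a$entries[, .(surface, level, provenance)]),
                   as.data.frame(b$entries[, .(surface, level, provenance)]))) &&
    identical(a$negation_prefixes, b$negation_prefixes) &&
    identical(a$exclusion_suffixes, b$exclusion_suffixes) &&
    identical(a$version, b$version)
}
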