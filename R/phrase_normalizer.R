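#' Categorize the words of a data item
#'
#' Each token's category comes from, in priority order: the `category`
#' column of the word reference; built-in auto-categorizers (numeric
#' tokens, optionally 4-character PDB-style identifiers, whole-item
#' protected prefixes as `url`); else `"unknown"`. The serialized
#' categorization string uses the grammar `[category(index)]...` with
#' 0-based indices in token order.
#'
#' @param item A single string (char- and word-stage valid).
#' @param word_rules Word reference rules (supplies categories).
#' @param delimiters Word delimiters.
#' @param pdb_ids Enable the PDB-identifier auto-categorizer (4-character
#'   alphanumeric tokens starting with a digit become `pdb_id`).
#' @param protected_prefixes Items starting with one of these strings are
#'   one single token of category `url`.
#' @return A list with `tokens` (character vector), `categories`
#'   (parallel), and `cat_string`.
#' @export
categorize <- function(item, word_rules, delimiters = default_delimiters(),
                       pdb_ids = FALSE, protected_prefixes = character()) {
  if (is_protected(item, protected_prefixes)) {
    return(list(tokens = item, categories = "url",
                cat_string = "[url(0)]"))
  }
  toks <- split_words(item, delimiters)$text
  if (length(toks) == 0L) {
    return(list(tokens = character(), categories = character(),
                cat_string = ""))
  }
  act <- rule_action(word_rules)
  ref_cat <- act$category[match(tolower(toks), act$unit)]
  cats <- ifelse(!is.na(ref_cat) & nzchar(ref_cat), ref_cat, NA_character_)
  auto <- is.na(cats)
  num <- grepl("^[0-9]+([.,][0-9]+)*$", toks)
  cats[auto & num] <- "number"
  if (pdb_ids) {
    pdb <- grepl("^[0-9][a-z0-9]{3}$", tolower(toks)) & !num
    cats[is.na(cats) & pdb] <- "pdb_id"
  }
  cats[is.na(cats)] <- "unknown"
  list(tokens = toks, categories = cats, cat_string = make_cat_string(cats))
}

#' Serialize a category sequence
#'
#' @param categories Character vector of categories in token order.
#' @return The categorization string, e.g. `"[number(0)][unit(1)]"`.
#' @export
make_cat_string <- function(categories) {
  if (length(categories) == 0L) return("")
  paste0("[", categories, "(", seq_along(categories) - 1L, ")]",
         collapse = "")
}

match_categories <- function(categories, ruleset) {
  if (nrow(ruleset) == 0L) return(NA_integer_)
  key <- paste(categories, collapse = "\x1f")
  keys <- vapply(ruleset$categories, paste, character(1), collapse = "\x1f")
  hit <- which(keys == key)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Rewrite tokens into a standard form
#'
#' Replaces each bracketed index `[k]` in the template with the token at
#' position `k` (0-based); all other template characters are emitted
#' literally. Input delimiters are discarded; the template supplies all
#' separators of the normalized phrase.
#'
#' @param tokens Character vector of tokens.
#' @param standard_form Template string.
#' @return The normalized phrase.
#' @export
apply_standard_form <- function(tokens, standard_form) {
  idx <- template_indices(standard_form)
  if (any(idx >= length(tokens))) {
    stop("standard form references token index ", max(idx),
         " but only ", length(tokens), " token(s) are present")
  }
  out <- standard_form
  m <- gregexpr("\\[(\\d+)\\]", out, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  parts <- regmatches(out, list(m))[[1]]
  repl <- tokens[as.integer(gsub("\\[|\\]", "", parts)) + 1L]
  regmatches(out, list(m)) <- list(repl)
  out
}

#' Match and rewrite one phrase against a ruleset
#'
#' The first pattern (in file order) whose category sequence equals the
#' phrase's category sequence is selected. The phrase is valid iff the
#' matched pattern is flagged valid, in which case the standard form is
#' applied; with no match, or an invalid match, the item fails phrase
#' validation and is left unrewritten.
#'
#' @param item A single string.
#' @param word_rules Word reference rules.
#' @param ruleset A phrase-type ruleset tibble.
#' @param ... Passed to [categorize()].
#' @return A one-row tibble: `input`, `cat_string`, `matched_pattern`
#'   (`NA` if none), `valid`, `output` (`NA` unless valid).
#' @export
normalize_phrase <- function(item, word_rules, ruleset, ...) {
  cat <- categorize(item, word_rules, ...)
  hit <- match_categories(cat$categories, ruleset)
  if (is.na(hit)) {
    return(tibble::tibble(input = item, cat_string = cat$cat_string,
                          matched_pattern = NA_character_, valid = FALSE,
                          output = NA_character_))
  }
  valid <- ruleset$valid[hit]
  out <- if (valid) {
    apply_standard_form(cat$tokens, ruleset$standard_form[hit])
  } else {
    NA_character_
  }
  tibble::tibble(input = item, cat_string = cat$cat_string,
                 matched_pattern = ruleset$name[hit], valid = valid,
                 output = out)
}

#' Run the phrase stage over a vector of items
#'
#' @param items Character vector of (word-valid) items or segments.
#' @param word_rules Word reference rules.
#' @param ruleset Phrase-type ruleset.
#' @param ... Passed to [normalize_phrase()].
#' @return A tibble with one row per item, as in [normalize_phrase()].
#' @export
phrase_stage <- function(items, word_rules, ruleset, ...) {
  if (length(items) == 0L) {
    return(tibble::tibble(input = character(), cat_string = character(),
                          matched_pattern = character(), valid = logical(),
                          output = character()))
  }
  do.call(rbind, lapply(items, normalize_phrase, word_rules = word_rules,
                        ruleset = ruleset, ...))
}
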