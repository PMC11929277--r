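stage_result <- function(input, output, valid, invalidating, distance) {
  tibble::tibble(
    input = input, output = output, valid = valid,
    invalidating_units = paste(invalidating, collapse = ","),
    distance = as.integer(distance)
  )
}

#' Apply character rules to one data item
#'
#' The character stage lowercases the item (by default), then applies the
#' reference rules in a fixed order: all `replace_with` substitutions and
#' `remove` deletions in a single left-to-right pass (one map lookup per
#' character, so replacement output is never re-scanned), then the
#' `invalidate` check, then the `allow` check. The item is valid iff no
#' character carries an `invalidate` rule and every character of the
#' result is in the always-valid default set or carries an `allow` rule.
#' Invalid items pass through unmodified (`output == input`).
#'
#' @param item A single string.
#' @param rules Character-stage reference rules.
#' @param default_valid Always-valid characters.
#' @param lowercase Lowercase before applying rules.
#' @return A one-row tibble: `input`, `output`, `valid`,
#'   `invalidating_units` (comma-joined), `distance` (Levenshtein between
#'   input and output).
#' @export
apply_char_rules <- function(item, rules,
                             default_valid = default_valid_chars(),
                             lowercase = TRUE) {
  act <- rule_action(rules)
  x <- if (lowercase) tolower(item) else item
  chars <- if (nzchar(x)) strsplit(x, "", fixed = TRUE)[[1]] else character()

  inval_units <- act$unit[act$action == "invalidate"]
  hit_inval <- unique(chars[chars %in% inval_units])
  if (length(hit_inval) > 0L) {
    return(stage_result(item, item, FALSE, hit_inval, 0L))
  }

  idx <- match(chars, act$unit)
  out_chars <- chars
  has_rule <- !is.na(idx)
  if (any(has_rule)) {
    a <- act$action[idx[has_rule]]
    v <- act$value[idx[has_rule]]
    repl <- ifelse(a == "replace_with", v,
                   ifelse(a == "remove", "", chars[has_rule]))
    out_chars[has_rule] <- repl
  }
  output <- paste(out_chars, collapse = "")

  out_vec <- if (nzchar(output)) strsplit(output, "", fixed = TRUE)[[1]] else character()
  introduced <- unique(out_vec[out_vec %in% inval_units])
  if (length(introduced) > 0L) {
    stop("replacement introduces invalidated character(s): ",
         paste(introduced, collapse = ", "), " (rule-set inconsistency)")
  }

  allowed <- c(default_valid, act$unit[act$action == "allow"])
  leftover <- unique(out_vec[!out_vec %in% allowed])
  if (length(leftover) > 0L) {
    return(stage_result(item, item, FALSE, leftover, 0L))
  }
  stage_result(item, output, TRUE, character(), levenshtein(item, output))
}

# merge the delimiters around a removed token: start/end of string absorb
# the separator, otherwise the left-hand separator survives
merge_delims <- function(left, right) {
  if (!nzchar(left) || !nzchar(right)) "" else left
}

#' Apply word rules to one data item
#'
#' Tokens are matched exactly (whole-token) against rule units.
#' `replace_with` substitutes the token in place, preserving delimiters
#' (replacement text may contain delimiters; new words surface in the next
#' review cycle). `remove` deletes the token and collapses the doubled
#' delimiter. Any `invalidate`-ruled token marks the item invalid and
#' leaves it unchanged. The item is valid iff every token of the result
#' carries an `allow` rule. Items with a protected prefix (URLs) pass
#' through untouched and valid.
#'
#' @param item A single string (should already be character-stage valid).
#' @param rules Word-stage reference rules.
#' @param delimiters Word delimiters.
#' @param protected_prefixes Items starting with one of these strings are
#'   exempt from word normalization.
#' @param valid_chars Optional character vector; when supplied, a
#'   replacement introducing a character outside it is an error.
#' @return A one-row tibble as in [apply_char_rules()].
#' @export
apply_word_rules <- function(item, rules, delimiters = default_delimiters(),
                             protected_prefixes = character(),
                             valid_chars = NULL) {
  if (is_protected(item, protected_prefixes)) {
    return(stage_result(item, item, TRUE, character(), 0L))
  }
  act <- rule_action(rules)
  toks <- split_words(item, delimiters)
  if (nrow(toks) == 0L) {
    return(stage_result(item, item, TRUE, character(), 0L))
  }

  idx <- match(toks$text, act$unit)
  action <- ifelse(is.na(idx), "none", act$action[ifelse(is.na(idx), 1L, idx)])
  hit_inval <- unique(toks$text[action == "invalidate"])
  if (length(hit_inval) > 0L) {
    return(stage_result(item, item, FALSE, hit_inval, 0L))
  }

  if (!is.null(valid_chars)) {
    repl <- act$value[idx[action == "replace_with"]]
    repl_chars <- unique(unlist(strsplit(repl, "", fixed = TRUE)))
    bad <- setdiff(repl_chars, c(valid_chars, delimiters))
    if (length(bad) > 0L) {
      stop("replacement text contains character(s) invalid at the character ",
           "stage: ", paste(bad, collapse = ", "))
    }
  }

  # single left-to-right pass: build delimiter/text sequence
  out_delims <- toks$left_delim[1]
  out_texts <- character()
  for (i in seq_len(nrow(toks))) {
    d_right <- toks$right_delim[i]
    if (action[i] == "remove") {
      k <- length(out_delims)
      out_delims[k] <- merge_delims(out_delims[k], d_right)
    } else {
      txt <- if (action[i] == "replace_with") act$value[idx[i]] else toks$text[i]
      out_texts <- c(out_texts, txt)
      out_delims <- c(out_delims, d_right)
    }
  }
  output <- paste0(
    paste0(out_delims[seq_along(out_texts)], out_texts, collapse = ""),
    out_delims[length(out_delims)]
  )
  if (length(out_texts) == 0L) output <- out_delims[1]

  out_toks <- split_words(output, delimiters)$text
  allowed <- act$unit[act$action == "allow"]
  leftover <- unique(out_toks[!out_toks %in% allowed])
  if (length(leftover) > 0L) {
    return(stage_result(item, item, FALSE, leftover, 0L))
  }
  stage_result(item, output, TRUE, character(), levenshtein(item, output))
}

is_protected <- function(item, prefixes) {
  length(prefixes) > 0L && any(startsWith(item, prefixes))
}

#' Run the character stage over a corpus
#'
#' @param items Character vector of data items.
#' @param rules Character reference rules.
#' @param ... Passed to [apply_char_rules()].
#' @return A tibble with one row per item: `original`, `normalized`,
#'   `valid`, `invalidating_units`, `distance`.
#' @export
char_stage <- function(items, rules, ...) {
  res <- lapply(items, apply_char_rules, rules = rules, ...)
  res <- do.call(rbind, res)
  tibble::tibble(
    original = res$input, normalized = res$output, valid = res$valid,
    invalidating_units = res$invalidating_units, distance = res$distance
  )
}

#' Run the word stage over character-stage output
#'
#' Only items valid at the character stage are word-normalized (the gate
#' property); the rest are carried through with `entered = FALSE` and `NA`
#' word columns so no item is dropped.
#'
#' @param char_out Output tibble of [char_stage()].
#' @param rules Word reference rules.
#' @param ... Passed to [apply_word_rules()].
#' @return A tibble with `original`, `char_normalized`, `entered`,
#'   `normalized`, `valid`, `invalidating_units`, `distance`.
#' @export
word_stage <- function(char_out, rules, ...) {
  n <- nrow(char_out)
  out <- tibble::tibble(
    original = char_out$original,
    char_normalized = char_out$normalized,
    entered = char_out$valid,
    normalized = NA_character_,
    valid = NA,
    invalidating_units = NA_character_,
    distance = NA_integer_
  )
  for (i in which(char_out$valid)) {
    r <- apply_word_rules(char_out$normalized[i], rules, ...)
    out$normalized[i] <- r$output
    out$valid[i] <- r$valid
    out$invalidating_units[i] <- r$invalidating_units
    out$distance[i] <- r$distance
  }
  out
}
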