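#' Parse a phrase-pattern string
#'
#' Patterns are sequences of bracketed category tokens with 0-based
#' positions, e.g. `"[number(0)] [range_indicator(1)] [number(2)] [unit(3)]"`.
#' Whitespace between tokens is ignored; indices must be `0..n-1` in order.
#'
#' @param pattern The pattern string.
#' @return Character vector of categories, in position order.
#' @export
parse_phrase_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!nzchar(trimws(pattern))) return(character())
  rx <- "\\[([^][()]+)\\((\\d+)\\)\\]"
  m <- gregexpr(rx, pattern, perl = TRUE)[[1]]
  toks <- regmatches(pattern, list(m))[[1]]
  rest <- trimws(gsub(rx, " ", pattern, perl = TRUE))
  if (nzchar(rest) || length(toks) == 0L) {
    stop("malformed phrase pattern: ", pattern)
  }
  cats <- sub(rx, "\\1", toks, perl = TRUE)
  idx <- as.integer(sub(rx, "\\2", toks, perl = TRUE))
  if (!identical(idx, seq_along(idx) - 1L)) {
    stop("pattern indices must be 0..n-1 in order: ", pattern)
  }
  trimws(cats)
}

template_indices <- function(standard_form) {
  m <- gregexpr("\\[(\\d+)\\]", standard_form, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(gsub("\\[|\\]", "", regmatches(standard_form, list(m))[[1]]))
}

#' Construct a phrase-type ruleset
#'
#' A ruleset row names a pattern, gives its category sequence, flags
#' whether matching items are valid, and (for valid patterns) sets the
#' standard-form template that rewrites matched phrases. Template
#' placeholders `[k]` refer to pattern positions.
#'
#' @param name Pattern names.
#' @param pattern Pattern strings (see [parse_phrase_pattern()]).
#' @param valid Logical (or `"Y"`/`"N"`) validity flags.
#' @param standard_form Templates; may be empty only for invalid patterns.
#' @return A validated ruleset tibble with a parsed `categories`
#'   list-column.
#' @export
phrase_ruleset <- function(name, pattern, valid, standard_form = "") {
  n <- length(name)
  if (is.character(valid)) valid <- toupper(valid) == "Y"
  valid <- rep_len(valid, n)
  standard_form <- rep_len(standard_form, n)
  rs <- tibble::tibble(
    name = as.character(name),
    pattern = as.character(pattern),
    valid = valid,
    standard_form = as.character(standard_form)
  )
  rs$categories <- lapply(rs$pattern, parse_phrase_pattern)
  for (i in seq_len(nrow(rs))) {
    k <- length(rs$categories[[i]])
    ref <- template_indices(rs$standard_form[i])
    if (length(ref) > 0L && any(ref < 0L | ref >= k)) {
      stop("standard form of pattern '", rs$name[i],
           "' references an index outside 0..", k - 1L)
    }
    if (rs$valid[i] && !nzchar(trimws(rs$standard_form[i]))) {
      stop("valid pattern '", rs$name[i], "' needs a standard form")
    }
  }
  rs
}

phrase_ruleset_header <- c("name", "pattern", "valid", "standard_form")

#' Load a phrase-type ruleset TSV
#'
#' If the file does not exist, a blank ruleset with headers is written
#' there and an empty ruleset is returned, so a first pipeline run
#' bootstraps the file for the user to fill in.
#'
#' @param path File path.
#' @return A ruleset tibble (see [phrase_ruleset()]).
#' @export
load_phrase_ruleset <- function(path) {
  if (!file.exists(path)) {
    generate_blank_phrase_ruleset(path)
    return(phrase_ruleset(character(), character(), logical(), character()))
  }
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          check.names = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  missing <- setdiff(phrase_ruleset_header, names(df))
  if (length(missing) > 0L) {
    stop("phrase ruleset ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  phrase_ruleset(df$name, df$pattern, df$valid, df$standard_form)
}

#' @rdname load_phrase_ruleset
#' @export
generate_blank_phrase_ruleset <- function(path) {
  utils::write.table(
    as.data.frame(matrix(character(), ncol = 4,
                         dimnames = list(NULL, phrase_ruleset_header))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname load_phrase_ruleset
#' @param ruleset A ruleset tibble.
#' @export
write_phrase_ruleset <- function(ruleset, path) {
  out <- ruleset[phrase_ruleset_header]
  out$valid <- ifelse(out$valid, "Y", "N")
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Lint a phrase-type ruleset
#'
#' Reports (as warnings) duplicate category sequences, templates that drop
#' pattern positions, and valid patterns whose standard-form output would
#' not itself match any pattern in the ruleset (breaking idempotence of the
#' phrase stage). Categorization of template output uses the supplied word
#' reference, as in [categorize()].
#'
#' @param ruleset A ruleset tibble.
#' @param word_rules Word reference rules used to categorize template text.
#' @param ... Passed to [categorize()].
#' @return Invisibly, a character vector of messages (also warned).
#' @export
lint_phrase_ruleset <- function(ruleset, word_rules = NULL, ...) {
  msgs <- character()
  keys <- vapply(ruleset$categories, paste, character(1), collapse = "\x1f")
  dup <- duplicated(keys)
  if (any(dup)) {
    msgs <- c(msgs, paste0("duplicate pattern sequence: ",
                           ruleset$name[dup], collapse = "; "))
  }
  for (i in seq_len(nrow(ruleset))) {
    if (!ruleset$valid[i]) next
    k <- length(ruleset$categories[[i]])
    ref <- template_indices(ruleset$standard_form[i])
    dropped <- setdiff(seq_len(k) - 1L, ref)
    if (length(dropped) > 0L) {
      msgs <- c(msgs, paste0("pattern '", ruleset$name[i],
                             "' drops position(s) ",
                             paste(dropped, collapse = ",")))
    }
    if (!is.null(word_rules)) {
      # probe the template with placeholder tokens of the pattern's own
      # categories: category labels come from the reference, so a stable
      # probe is the category sequence the template induces
      probe <- apply_standard_form(
        paste0("tok", seq_len(k) - 1L), ruleset$standard_form[i]
      )
      # cannot categorize synthetic tokens; instead check structural reach:
      # the induced sequence is the pattern categories in template order
      induced <- ruleset$categories[[i]][ref + 1L]
      hit <- match_categories(induced, ruleset)
      if (is.na(hit) || !ruleset$valid[hit]) {
        msgs <- c(msgs, paste0("standard form of '", ruleset$name[i],
                               "' does not re-match a valid pattern (", probe,
                               ")"))
      }
    }
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}
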