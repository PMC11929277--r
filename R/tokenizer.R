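#' Default word delimiter set
#'
#' Characters that bound words in a data item. A word is a maximal run of
#' non-delimiter characters; runs of delimiter characters form a single
#' delimiter. Start and end of string also bound words.
#'
#' @return Character vector of single characters.
#' @export
default_delimiters <- function() {
  c(" ", "\t", "-", ",", ".", ":", ";", "(", ")", "[", "]", "/", "=")
}

#' Count the characters of a data item
#'
#' Tallies every character of `item`, preserving the order of first
#' occurrence. Used to seed the character review file.
#'
#' @param item A single string (may be empty).
#' @return A tibble with columns `char` and `count`.
#' @export
extract_chars <- function(item) {
  stopifnot(is.character(item), length(item) == 1L, !is.na(item))
  if (!nzchar(item)) {
    return(tibble::tibble(char = character(), count = integer()))
  }
  chars <- strsplit(item, "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = unique(chars)))
  tibble::tibble(char = names(tab), count = as.integer(tab))
}

#' Split a data item into words with their delimiters
#'
#' Decomposes `item` into delimiter-bounded word tokens. Each token records
#' its 0-based start offset and the delimiter runs on either side, so the
#' source string can be reconstructed exactly (see [rejoin_tokens()]).
#'
#' A single `.` or `,` flanked by digits is treated as part of the word, so
#' decimal numbers (`6.3`) and digit-grouped numbers (`11,782`) stay whole
#' even though period and comma are delimiters. Disable with
#' `merge_numeric = FALSE`.
#'
#' @param item A single string.
#' @param delimiters Character vector of single delimiter characters.
#' @param merge_numeric Keep `digit[.,]digit` sequences as one token.
#' @return A tibble with columns `text`, `start`, `left_delim`,
#'   `right_delim`. Zero rows for an empty or all-delimiter string; in that
#'   case the attribute `"orphan"` carries the full source string so
#'   reconstruction stays exact.
#' @export
split_words <- function(item, delimiters = default_delimiters(),
                        merge_numeric = TRUE) {
  stopifnot(is.character(item), length(item) == 1L, !is.na(item))
  stopifnot(length(delimiters) >= 1L)
  empty <- tibble::tibble(
    text = character(), start = integer(),
    left_delim = character(), right_delim = character()
  )
  if (!nzchar(item)) {
    attr(empty, "orphan") <- ""
    return(empty)
  }
  chars <- strsplit(item, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_delim <- chars %in% delimiters
  if (merge_numeric && n >= 3L) {
    digit <- chars %in% as.character(0:9)
    mid <- which(is_delim & chars %in% c(".", ","))
    mid <- mid[mid > 1L & mid < n]
    keep <- mid[digit[mid - 1L] & digit[mid + 1L]]
    is_delim[keep] <- FALSE
  }
  r <- rle(is_delim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, delim = r$values)
  texts <- substring(item, runs$start, runs$end)
  word_idx <- which(!runs$delim)
  if (length(word_idx) == 0L) {
    attr(empty, "orphan") <- item
    return(empty)
  }
  left <- vapply(word_idx, function(i) {
    if (i > 1L && runs$delim[i - 1L]) texts[i - 1L] else ""
  }, character(1))
  right <- vapply(word_idx, function(i) {
    if (i < nrow(runs) && runs$delim[i + 1L]) texts[i + 1L] else ""
  }, character(1))
  tibble::tibble(
    text = texts[word_idx],
    start = runs$start[word_idx] - 1L,
    left_delim = left,
    right_delim = right
  )
}

#' Reassemble a tokenized string
#'
#' Inverse of [split_words()]: concatenates each token's `left_delim` and
#' `text`, then the final token's `right_delim`.
#'
#' @param tokens A token tibble from [split_words()].
#' @return The reconstructed string.
#' @export
rejoin_tokens <- function(tokens) {
  if (nrow(tokens) == 0L) {
    orphan <- attr(tokens, "orphan")
    return(if (is.null(orphan)) "" else orphan)
  }
  paste0(
    paste0(tokens$left_delim, tokens$text, collapse = ""),
    tokens$right_delim[nrow(tokens)]
  )
}
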