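#' Default head words for data-location splitting
#'
#' Location words that can form the head of an enumerated reference
#' ("Fig.", "Supplementary Figs.", "Table", ...). Matched case-insensitively
#' against word tokens (trailing periods are delimiters and never part of
#' the token).
#'
#' @return Character vector of lowercase head words.
#' @export
default_head_words <- function() {
  c("fig", "figs", "figure", "figures", "tab", "table", "tables",
    "page", "pg", "p", "pp", "data", "set", "file", "additional",
    "suppl", "supplemental", "supplementary", "supporting", "information")
}

trim_segment <- function(x) gsub("^[ \t.,;]+|[ \t.,;]+$", "", x)

num_suffix_rx <- "^([0-9]+(\\.[0-9]+)?)([A-Za-z]+)?$"

#' Split a list-like data item into segments
#'
#' Splits on commas, semicolons, and the separator words "and"/"&", then
#' expands two kinds of shorthand: a head phrase (one or more location
#' words) distributes over subsequent bare numbers ("Figs. 1, 2, 3" gives
#' one segment per number), and letter suffixes attached to a number
#' expand into one lowercased segment per letter ("Fig. 2A,B,C" gives
#' "Fig. 2a", "Fig. 2b", "Fig. 2c"). Elements that do not parse as head +
#' number are kept whole as their own segment (ranges like "Figs. 1-4" are
#' deliberately not expanded). Items with a protected prefix (URLs) are
#' never split. An unsplittable item returns itself as one segment.
#'
#' @param item A single string (typically word-stage output).
#' @param head_words Lowercase head words (see [default_head_words()]).
#' @param delimiters Word delimiters.
#' @param protected_prefixes Prefixes of items that must never be split.
#' @return Character vector of non-empty segments.
#' @export
split_locations <- function(item, head_words = default_head_words(),
                            delimiters = default_delimiters(),
                            protected_prefixes = character()) {
  if (is_protected(item, protected_prefixes)) return(item)
  toks <- split_words(item, delimiters)
  if (nrow(toks) == 0L) {
    seg <- trim_segment(item)
    return(if (nzchar(seg)) seg else character())
  }

  lower <- tolower(toks$text)
  is_sep_word <- lower %in% c("and", "&")
  # element boundary after token i when the delimiter run to its right
  # contains a list separator
  sep_right <- grepl("[,;]", toks$right_delim)
  n <- nrow(toks)
  elem_id <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    if (is_sep_word[i]) {
      elem_id[i] <- 0L           # separator token, not part of any element
      cur <- cur + 1L
    } else {
      elem_id[i] <- cur
      if (i < n && sep_right[i]) cur <- cur + 1L
    }
  }

  surface <- function(i1, i2) {  # item substring spanning tokens i1..i2
    substr(item, toks$start[i1] + 1L, toks$start[i2] + nchar(toks$text[i2]))
  }

  segments <- character()
  cur_head <- NULL   # head surface incl. trailing delimiter, e.g. "Fig. "
  cur_num <- NULL    # most recent number under that head
  for (e in setdiff(unique(elem_id), 0L)) {
    ix <- which(elem_id == e)
    el_text <- trim_segment(surface(ix[1], ix[length(ix)]))
    if (!nzchar(el_text)) next
    heads <- which(cumsum(!(lower[ix] %in% head_words)) == 0L)
    rest <- ix[setdiff(seq_along(ix), heads)]
    if (length(heads) > 0L) {
      m <- if (length(rest) == 1L) regmatches(toks$text[rest],
             regexec(num_suffix_rx, toks$text[rest]))[[1]] else character()
      if (length(m) > 0L) {
        num <- m[2]; suffix <- m[4]
        cur_head <- substr(item, toks$start[ix[1]] + 1L, toks$start[rest])
        cur_num <- num
        segments <- c(segments, if (nzchar(suffix)) {
          paste0(cur_head, num, tolower(suffix))
        } else {
          el_text
        })
      } else {
        segments <- c(segments, el_text)
        cur_head <- NULL; cur_num <- NULL
      }
    } else if (length(ix) == 1L &&
               length(m <- regmatches(toks$text[ix],
                        regexec(num_suffix_rx, toks$text[ix]))[[1]]) > 0L) {
      num <- m[2]; suffix <- m[4]
      if (!is.null(cur_head)) {
        cur_num <- num
        segments <- c(segments,
                      paste0(cur_head, num,
                             if (nzchar(suffix)) tolower(suffix) else ""))
      } else {
        segments <- c(segments, el_text)
      }
    } else if (length(ix) == 1L && grepl("^[A-Za-z]{1,2}$", toks$text[ix]) &&
               !is.null(cur_head) && !is.null(cur_num)) {
      segments <- c(segments, paste0(cur_head, cur_num,
                                     tolower(toks$text[ix])))
    } else {
      segments <- c(segments, el_text)
      cur_head <- NULL; cur_num <- NULL
    }
  }
  if (length(segments) == 0L) {
    seg <- trim_segment(item)
    segments <- if (nzchar(seg)) seg else character()
  }
  segments
}

#' Explode a corpus of items into one row per segment
#'
#' Applies [split_locations()] to each item and returns a long table with
#' index bookkeeping: `original_index` traces a segment back to its source
#' item, `split_index` (0-based, gapless) orders the segments of one item.
#'
#' @param items Character vector of data items.
#' @param ... Passed to [split_locations()].
#' @return A tibble with `original_index`, `split_index`, `segment`.
#' @export
explode_rows <- function(items, ...) {
  if (length(items) == 0L) {
    return(tibble::tibble(original_index = integer(), split_index = integer(),
                          segment = character()))
  }
  segs <- lapply(items, split_locations, ...)
  k <- vapply(segs, length, integer(1))
  tibble::tibble(
    original_index = rep(seq_along(items), k),
    split_index = unlist(lapply(k, function(x) seq_len(x) - 1L),
                         use.names = FALSE),
    segment = unlist(segs, use.names = FALSE)
  )
}
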