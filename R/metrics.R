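#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertion, deletion, substitution),
#' computed with base R's generalized distance machinery. Vectorized
#' elementwise over `a` and `b`.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- utils::adist(a[i], b[i])[1, 1]
  out
}

#' Validity rate of a stage
#'
#' Fraction of items valid among those entering the stage. Denominators
#' follow the gating rule: each stage's rate is over the items that
#' entered it, so pass `NA`-free flags for entered items only (or let the
#' function drop the `NA` flags of gated-out items).
#'
#' @param valid Logical vector of per-item validity flags; `NA` marks an
#'   item that did not enter the stage and is dropped.
#' @return A fraction in `[0, 1]`.
#' @export
stage_validity <- function(valid) {
  valid <- valid[!is.na(valid)]
  if (length(valid) == 0L) stop("no items entered the stage")
  mean(valid)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize per-item normalization metrics
#'
#' Computes, for each numeric metric column present (`char_distance`,
#' `word_distance`, `split_phrase_count`, `phrase_validity_rate`), the
#' mean, population and sample standard deviations, and a frequency
#' distribution for the distance columns. Protected (URL-like) items can
#' be excluded, mirroring with/without-URL corpus summaries.
#'
#' @param items A tibble of per-item metrics; an optional logical
#'   `protected` column marks URL-like items.
#' @param exclude_protected Drop rows with `protected == TRUE`.
#' @return A list with `n`, a `summary` tibble (metric, mean, sd_pop,
#'   sd_sample), and `distributions` (named list of frequency tables).
#' @export
summarize_metrics <- function(items, exclude_protected = FALSE) {
  if (nrow(items) == 0L) stop("no items to summarize")
  if (exclude_protected) {
    if (!"protected" %in% names(items)) {
      stop("exclude_protected requires a 'protected' column")
    }
    items <- items[!items$protected, , drop = FALSE]
    if (nrow(items) == 0L) stop("no items remain after excluding protected items")
  }
  metrics <- intersect(
    c("char_distance", "word_distance", "split_phrase_count",
      "phrase_validity_rate"),
    names(items)
  )
  rows <- lapply(metrics, function(m) {
    x <- items[[m]]
    x <- x[!is.na(x)]
    tibble::tibble(
      metric = m,
      n = length(x),
      mean = mean(x),
      sd_pop = sd_pop(x),
      sd_sample = if (length(x) > 1L) stats::sd(x) else 0
    )
  })
  dists <- lapply(
    intersect(c("char_distance", "word_distance", "split_phrase_count"),
              metrics),
    function(m) table(items[[m]], useNA = "no")
  )
  names(dists) <- intersect(
    c("char_distance", "word_distance", "split_phrase_count"), metrics
  )
  list(n = nrow(items), summary = do.call(rbind, rows),
       distributions = dists)
}

#' Render a metrics summary as a log block
#'
#' @param s Output of [summarize_metrics()].
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
format_metrics <- function(s) {
  lines <- c(sprintf("items: %d", s$n))
  for (i in seq_len(nrow(s$summary))) {
    r <- s$summary[i, ]
    lines <- c(lines, sprintf(
      "%s: mean %.3f, sd(pop) %.3f, sd(sample) %.3f (n=%d)",
      r$metric, r$mean, r$sd_pop, r$sd_sample, r$n
    ))
  }
  lines
}
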