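#' Pipeline configuration
#'
#' All knobs of a dataset's normalization run. `dataset_name` keys every
#' rule and output filename inside `workdir`.
#'
#' @param dataset_name Short dataset key, e.g. `"age"`.
#' @param input_path TSV of data items (first column, header row).
#' @param workdir Directory for rule files, outputs, and logs (created if
#'   absent).
#' @param delimiters Word delimiter characters.
#' @param default_valid_chars Always-valid characters for the char stage.
#' @param protected_prefixes Item prefixes exempt from word normalization
#'   and splitting (URLs).
#' @param enable_splitter Run the list-splitter between the word and
#'   phrase stages.
#' @param enable_pdb_autocategory Auto-categorize 4-character identifiers
#'   starting with a digit as `pdb_id`.
#' @param seed Integer seed recorded in logs (core normalization is
#'   deterministic; fixtures use it).
#' @return A `normalizer_config` list.
#' @export
normalizer_config <- function(dataset_name, input_path, workdir,
                              delimiters = default_delimiters(),
                              default_valid_chars = textnorm::default_valid_chars(),
                              protected_prefixes = character(),
                              enable_splitter = FALSE,
                              enable_pdb_autocategory = FALSE,
                              seed = 1L) {
  structure(list(
    dataset_name = dataset_name, input_path = input_path, workdir = workdir,
    delimiters = delimiters, default_valid_chars = default_valid_chars,
    protected_prefixes = protected_prefixes,
    enable_splitter = isTRUE(enable_splitter),
    enable_pdb_autocategory = isTRUE(enable_pdb_autocategory),
    seed = as.integer(seed)
  ), class = "normalizer_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config A `normalizer_config`.
#' @return `read_config()`: a `normalizer_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("dataset_name", "input_path", "workdir")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("config ", path, " lacks field(s): ", paste(missing, collapse = ", "))
  }
  args <- raw[intersect(names(raw), names(formals(normalizer_config)))]
  if (!is.null(args$delimiters)) {
    args$delimiters <- strsplit(args$delimiters, "", fixed = TRUE)[[1]]
  }
  if (!is.null(args$default_valid_chars)) {
    args$default_valid_chars <-
      strsplit(args$default_valid_chars, "", fixed = TRUE)[[1]]
  }
  do.call(normalizer_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$delimiters <- paste(out$delimiters, collapse = "")
  out$default_valid_chars <- paste(out$default_valid_chars, collapse = "")
  out$protected_prefixes <- as.list(out$protected_prefixes)
  yaml::write_yaml(out, path)
  invisible(path)
}

stage_paths <- function(config) {
  ds <- config$dataset_name
  wd <- config$workdir
  p <- function(x) file.path(wd, paste0(ds, "_", x))
  list(
    char_review = p("char_review.tsv"), char_reference = p("char_reference.tsv"),
    char_output = p("char_output.tsv"),
    word_review = p("word_review.tsv"), word_reference = p("word_reference.tsv"),
    word_output = p("word_output.tsv"),
    split_output = p("split_output.tsv"),
    phrase_types = p("phrase_types.tsv"), phrase_output = p("phrase_output.tsv"),
    metrics = p("metrics.tsv"), log = p("log.txt")
  )
}

append_log <- function(config, stage, ...) {
  fields <- c(list(...), seed = config$seed)
  line <- paste0(
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage=", stage, " ",
    paste(names(fields), unlist(fields), sep = "=", collapse = " ")
  )
  cat(line, "\n", sep = "", file = stage_paths(config)$log, append = TRUE)
  message(line)
  invisible(line)
}

write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  lg <- vapply(out, is.logical, logical(1))
  out[lg] <- lapply(out[lg], function(x) as.integer(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

read_tsv <- function(path) {
  tibble::as_tibble(
    utils::read.delim(path, colClasses = "character", quote = "",
                      check.names = FALSE, na.strings = "",
                      fileEncoding = "UTF-8")
  )
}

#' Run one normalization stage against the working directory
#'
#' Performs the review-cycle loop for the requested stage: migrate decided
#' review rows to the reference, apply the reference rules to the stage's
#' input, refresh the review file with newly observed units, write the
#' stage output, and append a structured log line. Stages gate on their
#' predecessor's output file.
#'
#' @param stage One of `"char"`, `"word"`, `"split"`, `"phrase"`,
#'   `"metrics"`.
#' @param config A [normalizer_config()].
#' @return Invisibly, the stage's primary output tibble.
#' @export
run_stage <- function(stage = c("char", "word", "split", "phrase", "metrics"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "normalizer_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(config)
  switch(stage,
    char = run_char_file_stage(config, paths),
    word = run_word_file_stage(config, paths),
    split = run_split_file_stage(config, paths),
    phrase = run_phrase_file_stage(config, paths),
    metrics = run_metrics_file_stage(config, paths)
  )
}

read_input_items <- function(config) {
  if (!file.exists(config$input_path)) {
    stop("input file not found: ", config$input_path)
  }
  df <- read_tsv(config$input_path)
  items <- df[[1]]
  items[is.na(items)] <- ""
  items
}

run_unit_cycle <- function(items, review_path, reference_path, stage,
                           config) {
  review <- read_rules(review_path, stage)
  reference <- read_rules(reference_path, stage)
  mig <- migrate_decided(review, reference)
  units <- count_units(items, stage, delimiters = config$delimiters)
  before <- nrow(mig$review)
  review <- build_review(units, mig$review, mig$reference, stage,
                         default_valid = config$default_valid_chars)
  write_rules(review, review_path)
  write_rules(mig$reference, reference_path)
  list(review = review, reference = mig$reference,
       new_review = nrow(review) - before)
}

run_char_file_stage <- function(config, paths) {
  items <- read_input_items(config)
  cyc <- run_unit_cycle(items, paths$char_review, paths$char_reference,
                        "char", config)
  out <- char_stage(items, cyc$reference,
                    default_valid = config$default_valid_chars)
  write_tsv(out, paths$char_output)
  append_log(config, "char", items = length(items), valid = sum(out$valid),
             invalid = sum(!out$valid), new_review = cyc$new_review)
  invisible(out)
}

run_word_file_stage <- function(config, paths) {
  if (!file.exists(paths$char_output)) {
    stop("character-stage output not found (run the char stage first): ",
         paths$char_output)
  }
  ch <- read_tsv(paths$char_output)
  char_out <- tibble::tibble(
    original = ch$original, normalized = ch$normalized,
    valid = ch$valid == "1"
  )
  entering <- char_out$normalized[char_out$valid &
    !vapply(char_out$normalized, is_protected, logical(1),
            prefixes = config$protected_prefixes)]
  cyc <- run_unit_cycle(entering, paths$word_review, paths$word_reference,
                        "word", config)
  out <- word_stage(char_out, cyc$reference,
                    delimiters = config$delimiters,
                    protected_prefixes = config$protected_prefixes)
  write_tsv(out, paths$word_output)
  append_log(config, "word", items = nrow(out), entered = sum(out$entered),
             valid = sum(out$valid, na.rm = TRUE),
             invalid = sum(!out$valid, na.rm = TRUE),
             new_review = cyc$new_review)
  invisible(out)
}

run_split_file_stage <- function(config, paths) {
  if (!file.exists(paths$word_output)) {
    stop("word-stage output not found (run the word stage first): ",
         paths$word_output)
  }
  wo <- read_tsv(paths$word_output)
  eligible <- which(wo$entered == "1" & wo$valid == "1")
  seg <- explode_rows(wo$normalized[eligible],
                      delimiters = config$delimiters,
                      protected_prefixes = config$protected_prefixes)
  seg$original_index <- eligible[seg$original_index]
  write_tsv(seg, paths$split_output)
  append_log(config, "split", items = length(eligible),
             segments = nrow(seg))
  invisible(seg)
}

run_phrase_file_stage <- function(config, paths) {
  if (!file.exists(paths$word_output)) {
    stop("word-stage output not found (run the word stage first): ",
         paths$word_output)
  }
  wo <- read_tsv(paths$word_output)
  ruleset <- load_phrase_ruleset(paths$phrase_types)
  word_rules <- read_rules(paths$word_reference, "word")
  if (config$enable_splitter) {
    if (!file.exists(paths$split_output)) {
      stop("split output not found (run the split stage first): ",
           paths$split_output)
    }
    seg <- read_tsv(paths$split_output)
    seg$original_index <- as.integer(seg$original_index)
    seg$split_index <- as.integer(seg$split_index)
  } else {
    eligible <- which(wo$entered == "1" & wo$valid == "1")
    seg <- tibble::tibble(original_index = eligible,
                          split_index = 0L,
                          segment = wo$normalized[eligible])
  }
  ph <- phrase_stage(seg$segment, word_rules, ruleset,
                     delimiters = config$delimiters,
                     pdb_ids = config$enable_pdb_autocategory,
                     protected_prefixes = config$protected_prefixes)
  out <- tibble::tibble(
    original_index = seg$original_index,
    split_index = seg$split_index,
    original = wo$original[seg$original_index],
    word_normalized = seg$segment,
    cat_string = ph$cat_string,
    matched_pattern = ph$matched_pattern,
    valid = ph$valid,
    phrase_normalized = ph$output
  )
  # per-original metrics, recorded exactly once (on split_index 0)
  counts <- table(factor(out$original_index, levels = unique(out$original_index)))
  vrate <- vapply(split(out$valid, factor(out$original_index,
                                          levels = unique(out$original_index))),
                  mean, numeric(1))
  first <- out$split_index == 0L
  out$split_phrase_count <- NA_integer_
  out$phrase_validity_rate <- NA_real_
  key <- as.character(out$original_index[first])
  out$split_phrase_count[first] <- as.integer(counts[key])
  out$phrase_validity_rate[first] <- vrate[key]
  write_tsv(out, paths$phrase_output)
  append_log(config, "phrase", segments = nrow(out),
             valid = sum(out$valid), invalid = sum(!out$valid),
             originals = length(unique(out$original_index)))
  invisible(out)
}

run_metrics_file_stage <- function(config, paths) {
  for (p in c(paths$char_output, paths$word_output, paths$phrase_output)) {
    if (!file.exists(p)) stop("stage output not found: ", p)
  }
  ch <- read_tsv(paths$char_output)
  wo <- read_tsv(paths$word_output)
  ph <- read_tsv(paths$phrase_output)
  first <- ph[ph$split_index == "0", , drop = FALSE]
  idx <- as.integer(first$original_index)
  items <- tibble::tibble(
    original = ch$original,
    protected = vapply(ch$original, is_protected, logical(1),
                       prefixes = config$protected_prefixes),
    char_distance = as.integer(ch$distance),
    word_distance = suppressWarnings(as.integer(wo$distance)),
    split_phrase_count = NA_integer_,
    phrase_validity_rate = NA_real_
  )
  items$split_phrase_count[idx] <- as.integer(first$split_phrase_count)
  items$phrase_validity_rate[idx] <- as.numeric(first$phrase_validity_rate)
  s <- summarize_metrics(items)
  write_tsv(s$summary, paths$metrics)
  for (line in format_metrics(s)) message(line)
  append_log(config, "metrics", items = s$n)
  invisible(items)
}

#' Run all stages in order
#'
#' Convenience wrapper executing char, word, (split when enabled), phrase,
#' and metrics.
#'
#' @param config A [normalizer_config()].
#' @return Invisibly, the phrase-stage output tibble.
#' @export
run_pipeline <- function(config) {
  run_stage("char", config)
  run_stage("word", config)
  if (config$enable_splitter) run_stage("split", config)
  out <- run_stage("phrase", config)
  run_stage("metrics", config)
  invisible(out)
}

#' Normalize a corpus fully in memory
#'
#' The three stages (plus optional splitting) applied end to end with
#' explicit rule tables, without touching the filesystem. Used by tests,
#' the synthetic round-trip check, and downstream analyses.
#'
#' @param items Character vector of data items.
#' @param char_rules,word_rules Reference rule tibbles.
#' @param phrase_rules A phrase ruleset tibble.
#' @param delimiters,default_valid,protected_prefixes,pdb_ids See the
#'   stage functions.
#' @param splitter Run the list-splitter before the phrase stage.
#' @return A list with `items` (one row per input: stage strings, flags,
#'   distances, split counts, validity rate, and a `verdict` column
#'   holding the pipe-joined canonical segments or `"INVALID"`) and
#'   `segments` (one row per phrase-stage segment).
#' @export
normalize_corpus <- function(items, char_rules, word_rules, phrase_rules,
                             delimiters = default_delimiters(),
                             default_valid = default_valid_chars(),
                             protected_prefixes = character(),
                             pdb_ids = FALSE, splitter = FALSE) {
  cs <- char_stage(items, char_rules, default_valid = default_valid)
  ws <- word_stage(cs, word_rules, delimiters = delimiters,
                   protected_prefixes = protected_prefixes)
  eligible <- which(ws$entered & ws$valid)
  if (splitter) {
    seg <- explode_rows(ws$normalized[eligible], delimiters = delimiters,
                        protected_prefixes = protected_prefixes)
    seg$original_index <- eligible[seg$original_index]
  } else {
    seg <- tibble::tibble(original_index = eligible, split_index = 0L,
                          segment = ws$normalized[eligible])
  }
  ph <- phrase_stage(seg$segment, word_rules, phrase_rules,
                     delimiters = delimiters, pdb_ids = pdb_ids,
                     protected_prefixes = protected_prefixes)
  segments <- tibble::tibble(
    original_index = seg$original_index, split_index = seg$split_index,
    segment = seg$segment, cat_string = ph$cat_string,
    matched_pattern = ph$matched_pattern, valid = ph$valid,
    phrase_normalized = ph$output
  )
  n <- length(items)
  res <- tibble::tibble(
    original = items,
    char_normalized = cs$normalized, char_valid = cs$valid,
    char_distance = cs$distance,
    word_normalized = ws$normalized, word_valid = ws$valid,
    word_distance = ws$distance,
    split_phrase_count = NA_integer_, phrase_validity_rate = NA_real_,
    verdict = "INVALID"
  )
  if (nrow(segments) > 0L) {
    by_orig <- split(seq_len(nrow(segments)), segments$original_index)
    for (key in names(by_orig)) {
      i <- as.integer(key)
      rows <- by_orig[[key]]
      res$split_phrase_count[i] <- length(rows)
      res$phrase_validity_rate[i] <- mean(segments$valid[rows])
      res$verdict[i] <- paste(
        ifelse(segments$valid[rows], segments$phrase_normalized[rows],
               "INVALID"),
        collapse = "|"
      )
    }
  }
  list(items = res, segments = segments)
}

#' Score pipeline recovery against fixture ground truth
#'
#' Fraction of corpus items whose pipeline verdict (canonical segments or
#' `INVALID`) matches the generator's ground truth. Optionally restricted
#' to items whose noise classes are all within a covered set.
#'
#' @param corpus A generator corpus tibble (`messy`, `ground_truth`,
#'   `classes`).
#' @param result The `items` tibble of [normalize_corpus()] on
#'   `corpus$messy`.
#' @param covered_classes If non-NULL, only items whose classes are all in
#'   this set are scored.
#' @return A list with `rate`, `n_scored`, and the logical `match` vector.
#' @export
score_roundtrip <- function(corpus, result, covered_classes = NULL) {
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(covered_classes) && "classes" %in% names(corpus)) {
    keep <- vapply(strsplit(corpus$classes, ",", fixed = TRUE), function(cl) {
      all(cl %in% c(covered_classes, ""))
    }, logical(1))
  }
  match <- result$verdict[keep] == corpus$ground_truth[keep]
  list(rate = mean(match), n_scored = sum(keep), match = match)
}
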