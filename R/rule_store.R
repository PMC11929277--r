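#' Characters that are always valid at the character stage
#'
#' Lowercase letters, digits, and a small set of basic punctuation are
#' treated as allowed without a rule, so they never appear in the character
#' review file. Configurable per dataset.
#'
#' @return Character vector of single characters.
#' @export
default_valid_chars <- function() {
  c(letters, as.character(0:9), " ", ".", ",", "-", ":", ";", "(", ")", "/")
}

rule_columns <- function(stage = c("char", "word")) {
  stage <- match.arg(stage)
  cols <- c("unit", "context", "count",
            "replace_with", "remove", "invalidate", "allow")
  if (stage == "word") cols <- c(cols, "category")
  cols
}

#' Create an empty rule table
#'
#' Review and reference files share one schema: the text unit, a context
#' sample, an occurrence count, the four action-decision columns, and (word
#' stage only) a category column. Action cells hold text; a row is
#' "decided" when exactly one action cell is non-empty.
#'
#' @param stage `"char"` or `"word"`.
#' @return A zero-row tibble with the rule schema.
#' @export
empty_rules <- function(stage = c("char", "word")) {
  stage <- match.arg(stage)
  cols <- rule_columns(stage)
  out <- lapply(cols, function(x) character())
  names(out) <- cols
  out$count <- integer()
  tibble::as_tibble(out)
}

#' Build rule rows programmatically
#'
#' Convenience constructor used for demonstration rulesets and tests.
#' `action` is one of `replace_with`, `remove`, `invalidate`, `allow`,
#' `undecided`; `value` is required (non-empty) for `replace_with` and
#' ignored otherwise.
#'
#' @param unit Character vector of units (characters or words).
#' @param action Action name, recycled along `unit`.
#' @param value Replacement text for `replace_with` rows.
#' @param category Optional word category (word stage).
#' @param context,count Bookkeeping columns; defaults are placeholders.
#' @param stage `"char"` or `"word"`.
#' @return A rule tibble.
#' @export
make_rules <- function(unit, action = "undecided", value = "",
                       category = NULL, context = "", count = 1L,
                       stage = c("char", "word")) {
  stage <- match.arg(stage)
  n <- length(unit)
  action <- rep_len(action, n)
  value <- rep_len(value, n)
  bad <- !action %in% c("replace_with", "remove", "invalidate", "allow",
                        "undecided")
  if (any(bad)) stop("unknown action: ", paste(unique(action[bad]), collapse = ", "))
  if (any(action == "replace_with" & !nzchar(trimws(value)))) {
    stop("replace_with rules need a non-empty replacement (use remove to delete)")
  }
  out <- tibble::tibble(
    unit = as.character(unit),
    context = rep_len(as.character(context), n),
    count = rep_len(as.integer(count), n),
    replace_with = ifelse(action == "replace_with", value, ""),
    remove = ifelse(action == "remove", "x", ""),
    invalidate = ifelse(action == "invalidate", "x", ""),
    allow = ifelse(action == "allow", "x", "")
  )
  if (stage == "word") {
    out$category <- rep_len(if (is.null(category)) "" else as.character(category), n)
  }
  out
}

populated_actions <- function(rules) {
  act <- cbind(
    replace_with = nzchar(rules$replace_with),
    remove = nzchar(rules$remove),
    invalidate = nzchar(rules$invalidate),
    allow = nzchar(rules$allow)
  )
  act
}

#' Derive each rule row's action decision
#'
#' @param rules A rule tibble.
#' @return A tibble with `unit`, `action` (`undecided` when no action cell
#'   is populated), `value` (replacement text), and `category` if present.
#' @export
rule_action <- function(rules) {
  if (nrow(rules) == 0L) {
    return(tibble::tibble(unit = character(), action = character(),
                          value = character(), category = character()))
  }
  act <- populated_actions(rules)
  n_set <- rowSums(act)
  if (any(n_set > 1L)) {
    stop("multiple action decisions for unit(s): ",
         paste(rules$unit[n_set > 1L], collapse = ", "))
  }
  action <- rep("undecided", nrow(rules))
  for (a in colnames(act)) action[act[, a]] <- a
  bad <- action == "replace_with" & !nzchar(trimws(rules$replace_with))
  if (any(bad)) {
    stop("empty replace_with for unit(s) (use remove instead): ",
         paste(rules$unit[bad], collapse = ", "))
  }
  tibble::tibble(
    unit = rules$unit,
    action = action,
    value = rules$replace_with,
    category = if ("category" %in% names(rules)) rules$category else ""
  )
}

sanitize_field <- function(x) gsub("[\t\r\n]+", " ", x)

#' Read or write a rule table as TSV
#'
#' UTF-8, header row, no quoting; literal tabs are forbidden inside fields
#' (context samples have them replaced by spaces on write).
#'
#' @param path File path.
#' @param stage `"char"` or `"word"`.
#' @param rules A rule tibble.
#' @return `read_rules()`: a rule tibble (empty if the file is absent).
#' @export
read_rules <- function(path, stage = c("char", "word")) {
  stage <- match.arg(stage)
  if (!file.exists(path)) return(empty_rules(stage))
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          check.names = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  missing <- setdiff(rule_columns(stage), names(df))
  if (length(missing) > 0L) {
    stop("rule file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[rule_columns(stage)]
  df$count <- as.integer(df$count)
  tibble::as_tibble(df)
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  out <- as.data.frame(rules)
  chr <- vapply(out, is.character, logical(1))
  out[chr] <- lapply(out[chr], sanitize_field)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Tally the distinct units of a corpus
#'
#' Counts every distinct character or word across the data items, with
#' total occurrences and a context sample: distinct containing items in
#' dataset order joined by `" | "`, truncated at `max_context` characters.
#'
#' @param items Character vector of data items.
#' @param stage `"char"` or `"word"`.
#' @param delimiters Word delimiters (word stage).
#' @param max_context Context sample cap, in characters.
#' @return A tibble with `unit`, `context`, `count`.
#' @export
count_units <- function(items, stage = c("char", "word"),
                        delimiters = default_delimiters(),
                        max_context = 300L) {
  stage <- match.arg(stage)
  per_item <- lapply(items, function(it) {
    if (stage == "char") {
      tab <- extract_chars(it)
      tibble::tibble(unit = tab$char, n = tab$count)
    } else {
      toks <- split_words(it, delimiters)$text
      if (length(toks) == 0L) {
        tibble::tibble(unit = character(), n = integer())
      } else {
        tab <- table(factor(toks, levels = unique(toks)))
        tibble::tibble(unit = names(tab), n = as.integer(tab))
      }
    }
  })
  unit <- unlist(lapply(per_item, `[[`, "unit"))
  n <- unlist(lapply(per_item, `[[`, "n"))
  item_of <- rep(seq_along(items), vapply(per_item, nrow, integer(1)))
  if (length(unit) == 0L) {
    return(tibble::tibble(unit = character(), context = character(),
                          count = integer()))
  }
  lv <- unique(unit)
  count <- vapply(split(n, factor(unit, levels = lv)), sum, integer(1))
  context <- vapply(split(item_of, factor(unit, levels = lv)), function(ix) {
    ctx <- paste(items[unique(ix)], collapse = " | ")
    substr(ctx, 1L, max_context)
  }, character(1))
  tibble::tibble(unit = lv, context = unname(context), count = unname(count))
}

#' Add newly observed units to the review table
#'
#' Appends one undecided row per distinct unit that is not already present
#' in the review or reference tables and (character stage only) is not in
#' the always-valid default set. Uppercase letters are also exempt at the
#' character stage when the engine lowercases, since lowercasing already
#' decides them. Existing reference rows are never modified.
#'
#' @param units Output of [count_units()].
#' @param review,reference Current rule tables.
#' @param stage `"char"` or `"word"`.
#' @param default_valid Always-valid characters (character stage).
#' @param lowercase Whether the character stage lowercases (exempts A-Z).
#' @return The review tibble with new rows appended.
#' @export
build_review <- function(units, review, reference, stage = c("char", "word"),
                         default_valid = default_valid_chars(),
                         lowercase = TRUE) {
  stage <- match.arg(stage)
  known <- c(review$unit, reference$unit)
  new <- units[!units$unit %in% known, , drop = FALSE]
  if (stage == "char") {
    exempt <- default_valid
    if (lowercase) exempt <- c(exempt, LETTERS)
    new <- new[!new$unit %in% exempt, , drop = FALSE]
  }
  dup <- intersect(review$unit, reference$unit)
  if (length(dup) > 0L) {
    warning("unit(s) present in both review and reference (reference wins): ",
            paste(dup, collapse = ", "))
  }
  if (nrow(new) == 0L) return(review)
  rows <- make_rules(new$unit, "undecided", context = sanitize_field(new$context),
                     count = new$count, stage = stage)
  rbind(review, rows[names(review)])
}

#' Move decided review rows into the reference table
#'
#' Rows with exactly one populated action column move from review to
#' reference; undecided rows stay in review. No row is lost or duplicated,
#' and the operation is idempotent.
#'
#' @param review,reference Rule tibbles with the same schema.
#' @return A list with elements `review` and `reference`.
#' @export
migrate_decided <- function(review, reference) {
  act <- rule_action(review)  # validates single-action + non-empty replace_with
  decided <- act$action != "undecided"
  list(
    review = review[!decided, , drop = FALSE],
    reference = rbind(reference, review[decided, , drop = FALSE])
  )
}

#' Mass-allow review rows matching a regular expression
#'
#' Mirrors bulk curation of open-ended vocabularies (e.g. numeric tokens or
#' structured identifiers matched by a regex): matching undecided review
#' rows are marked `allow` (optionally with a category) and migrated to the
#' reference in one step.
#'
#' @param review,reference Rule tibbles.
#' @param pattern Regular expression matched against the whole unit.
#' @param category Category to assign (word stage; `""` for none).
#' @return A list with elements `review` and `reference`.
#' @export
mass_allow <- function(review, reference, pattern, category = "") {
  hit <- grepl(pattern, review$unit, perl = TRUE)
  if (any(hit)) {
    review$allow[hit] <- "x"
    if ("category" %in% names(review) && nzchar(category)) {
      review$category[hit] <- category
    }
  }
  migrate_decided(review, reference)
}
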