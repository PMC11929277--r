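#' Specify a synthetic messy corpus
#'
#' Bundles the size, seed, and per-variance-class noise probabilities of a
#' generated corpus. Classes mirror the character/word/phrase variance the
#' normalizer addresses: stray characters, abbreviated or plural units,
#' spelled-out numbers, en-dash ranges, word-order inversion of
#' statistical qualifiers, filler age words, uppercase, list length of
#' enumerations, and the URL / PDB-identifier / unitless-number item
#' fractions. All probabilities default to 0; the `noise` presets of
#' [generate_age_corpus()] and [generate_dataloc_corpus()] document
#' realistic values. Identical spec + seed yields an identical corpus.
#'
#' @param n_items Number of data items (>= 1).
#' @param seed Integer RNG seed.
#' @param ... Named noise rates overriding the zero defaults:
#'   `char_substitution`, `unit_abbreviation`, `plural_unit`,
#'   `spelled_number`, `dash_variant`, `range_word`, `hyphen_unit`,
#'   `stat_equals`, `stat_trailing`, `age_words`, `case_upper`,
#'   `unitless_number`, `url_fraction`, `pdb_fraction`, and `list_length`
#'   (Poisson mean of extra list elements, may exceed 1).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_items, seed = 1L, ...) {
  stopifnot(n_items >= 1L)
  rates <- list(
    char_substitution = 0, unit_abbreviation = 0, plural_unit = 0,
    spelled_number = 0, dash_variant = 0, range_word = 0, hyphen_unit = 0,
    stat_equals = 0, stat_trailing = 0, age_words = 0, case_upper = 0,
    unitless_number = 0, url_fraction = 0, pdb_fraction = 0,
    list_length = 1.5
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(rates))
  if (length(unknown) > 0L) {
    stop("unknown noise rate(s): ", paste(unknown, collapse = ", "))
  }
  rates[names(extra)] <- extra
  probs <- unlist(rates[setdiff(names(rates), "list_length")])
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(list(n_items = as.integer(n_items), seed = as.integer(seed),
                 noise = rates),
            class = "fixture_spec")
}

#' Moderate-noise preset used in examples and round-trip checks
#' @return A named list of noise rates.
#' @export
moderate_noise <- function() {
  list(char_substitution = 0.02, unit_abbreviation = 0.3, plural_unit = 0.4,
       spelled_number = 0.15, dash_variant = 0.4, range_word = 0.2,
       hyphen_unit = 0.15, stat_equals = 0.2, stat_trailing = 0.2,
       age_words = 0.3, case_upper = 0.3, unitless_number = 0.08)
}

with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

coin <- function(p) stats::runif(1) < p

spell_number <- function(n) {
  words <- c("one", "two", "three", "four", "five", "six", "seven", "eight",
             "nine", "ten", "eleven", "twelve")
  words[as.integer(n)]
}

abbreviate_unit <- function(u) {
  switch(u, week = "wk", year = "yr", month = "mo", hour = "hr", u)
}

#' Generate an age-style messy corpus with ground truth
#'
#' Emits pairs of a messy string and the canonical form the demonstration
#' rulesets should recover: `"N unit"`, `"A-B unit"`, or
#' `"stat: N unit"`, all lowercase and singular. Items generated as
#' unitless numbers or ranges, or struck by the stray-character class,
#' carry the verdict `INVALID`. With all noise rates zero, messy equals
#' canonical for every item.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble with columns `messy`, `ground_truth`, and `classes`
#'   (comma-joined noise classes applied to each item).
#' @export
generate_age_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nz <- spec$noise
  units <- c("week", "month", "year", "day", "hour")
  stats_q <- c("mean", "median", "average")
  with_fixture_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_items), function(i) {
      classes <- character()
      mark <- function(cls) classes <<- c(classes, cls)

      render_num <- function(n) {
        if (coin(nz$spelled_number) && grepl("^[0-9]+$", n) &&
            as.integer(n) <= 12 && as.integer(n) >= 1) {
          mark("spelled_number")
          spell_number(n)
        } else n
      }
      render_unit <- function(u) {
        out <- u
        if (coin(nz$unit_abbreviation) && u != "day") {
          mark("unit_abbreviation")
          out <- abbreviate_unit(u)
        }
        if (coin(nz$plural_unit)) {
          mark("plural_unit")
          out <- paste0(out, "s")
        }
        out
      }
      pick_num <- function() {
        if (coin(0.2)) sample(demo_decimal_pool(), 1) else
          as.character(sample(1:60, 1))
      }

      unit <- sample(units, 1)
      if (coin(nz$unitless_number)) {
        mark("unitless_number")
        if (coin(0.5)) {
          a <- sample(1:60, 1); b <- a + sample(1:20, 1)
          sep <- if (coin(nz$dash_variant)) {mark("dash_variant"); "–"} else "-"
          messy <- paste0(a, sep, b)
        } else {
          messy <- as.character(sample(1:99, 1))
        }
        canonical <- "INVALID"
      } else {
        form <- sample(c("single", "range", "stat"), 1,
                       prob = c(0.4, 0.35, 0.25))
        if (form == "single") {
          n <- pick_num()
          canonical <- paste(n, unit)
          messy <- paste(render_num(n), render_unit(unit))
          if (coin(nz$age_words)) {
            mark("age_words")
            messy <- paste(messy, sample(c("old", "of age"), 1))
          }
        } else if (form == "range") {
          a <- sample(1:60, 1); b <- a + sample(1:20, 1)
          canonical <- paste0(a, "-", b, " ", unit)
          sep <- "-"
          if (coin(nz$range_word)) {
            mark("range_word"); sep <- " to "
          } else if (coin(nz$dash_variant)) {
            mark("dash_variant"); sep <- "–"
          }
          usep <- if (coin(nz$hyphen_unit)) {mark("hyphen_unit"); "-"} else " "
          messy <- paste0(render_num(as.character(a)), sep,
                          render_num(as.character(b)), usep,
                          render_unit(unit))
          if (coin(nz$age_words)) {
            mark("age_words")
            messy <- paste(messy, "old")
          }
        } else {
          s <- sample(stats_q, 1)
          n <- pick_num()
          canonical <- paste0(s, ": ", n, " ", unit)
          if (coin(nz$stat_trailing)) {
            mark("stat_trailing")
            messy <- paste(render_num(n), render_unit(unit), s)
          } else {
            ssep <- if (coin(nz$stat_equals)) {mark("stat_equals"); " = "} else ": "
            filler <- if (coin(nz$age_words)) {mark("age_words"); " age"} else ""
            messy <- paste0(s, filler, ssep, render_num(n), " ",
                            render_unit(unit))
          }
        }
      }
      if (coin(nz$case_upper)) {
        mark("case_upper")
        messy <- paste0(toupper(substr(messy, 1, 1)),
                        substring(messy, 2))
      }
      if (coin(nz$char_substitution)) {
        mark("char_substitution")
        messy <- paste0(messy, " €")
        canonical <- "INVALID"
      }
      tibble::tibble(messy = messy, ground_truth = canonical,
                     classes = paste(unique(classes), collapse = ","))
    })
    do.call(rbind, rows)
  })
}

#' Generate a data-location-style messy corpus with ground truth
#'
#' Emits list-like figure/table enumerations (with head distribution and
#' letter-suffix shorthand), page references, PDB identifiers, fixed-prefix
#' URLs with 9-letter paths, and bare numbers. Ground truth is the list of
#' canonical segments the full pipeline (including splitting) should
#' produce, serialized with `"|"`; bare-number items carry `INVALID`.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble with columns `messy`, `ground_truth` (pipe-joined
#'   canonical segments), and `classes`.
#' @export
generate_dataloc_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nz <- spec$noise
  with_fixture_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_items), function(i) {
      classes <- character()
      mark <- function(cls) classes <<- c(classes, cls)
      u <- stats::runif(1)
      if (u < nz$url_fraction) {
        path <- paste(sample(letters, 9, replace = TRUE), collapse = "")
        messy_path <- if (coin(nz$case_upper)) {
          mark("case_upper"); toupper(path)
        } else path
        messy <- paste0(demo_url_prefix(), messy_path)
        canonical <- paste0(demo_url_prefix(), path)
      } else if (u < nz$url_fraction + nz$pdb_fraction) {
        id <- sample(demo_pdb_pool(), 1)
        canonical <- paste("pdb", id)
        messy <- if (coin(nz$case_upper)) {
          mark("case_upper"); toupper(canonical)
        } else canonical
      } else if (coin(nz$unitless_number)) {
        mark("unitless_number")
        messy <- as.character(sample(1:120, 1))
        canonical <- "INVALID"
      } else if (coin(0.2)) {
        n <- sample(c(1:60, 664L, 1410L), 1)
        canonical <- paste("page", n)
        messy <- if (coin(nz$unit_abbreviation)) {
          mark("unit_abbreviation")
          paste0(sample(c("pg.", "p."), 1), " ", n)
        } else canonical
        if (coin(nz$case_upper)) {
          mark("case_upper")
          messy <- paste0(toupper(substr(messy, 1, 1)), substring(messy, 2))
        }
      } else {
        head <- sample(c("figure", "table", "supplemental figure"), 1,
                       prob = c(0.5, 0.3, 0.2))
        abbrev <- coin(nz$unit_abbreviation)
        if (abbrev) mark("unit_abbreviation")
        k <- 1L + stats::rpois(1, nz$list_length)
        if (coin(0.25) && head != "table") {
          # letter-suffix shorthand: figure 2a,b,c
          n <- sample(1:20, 1)
          letts <- letters[seq_len(min(1L + stats::rpois(1, 1), 4L))]
          canonical_segs <- paste0(head, " ", n, letts)
          msg_head <- if (abbrev) {
            switch(head, figure = "Fig.",
                   `supplemental figure` = "Suppl Fig.", head)
          } else head
          # first letter rides on the number: "figure 2A,B,C"
          messy <- paste0(msg_head, " ", n,
                          paste(toupper(letts), collapse = ","))
        } else {
          ns <- sort(sample(1:40, k))
          canonical_segs <- paste(head, ns)
          msg_head <- if (abbrev) {
            switch(head, figure = if (k > 1) "Figs." else "Fig.",
                   table = if (k > 1) "Tables" else "Table",
                   `supplemental figure` =
                     if (k > 1) "Supplementary Figs." else "Suppl Fig.")
          } else head
          if (k > 1 && coin(0.5)) {
            messy <- paste0(msg_head, " ",
                            paste(ns[-k], collapse = ", "), " and ", ns[k])
          } else {
            messy <- paste0(msg_head, " ", paste(ns, collapse = ", "))
          }
        }
        canonical <- canonical_segs
      }
      if (coin(nz$char_substitution)) {
        mark("char_substitution")
        messy <- paste0(messy, " €")
        canonical <- "INVALID"
      }
      tibble::tibble(messy = messy,
                     ground_truth = paste(canonical, collapse = "|"),
                     classes = paste(unique(classes), collapse = ","))
    })
    do.call(rbind, rows)
  })
}

#' Write or read a fixture corpus as two-column TSV
#'
#' @param corpus A corpus tibble from a generator.
#' @param path File path.
#' @return `read_corpus()`: the corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  out <- as.data.frame(corpus[intersect(c("messy", "ground_truth"),
                                        names(corpus))])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  tibble::as_tibble(
    utils::read.delim(path, colClasses = "character", quote = "",
                      check.names = FALSE, na.strings = NULL,
                      fileEncoding = "UTF-8")
  )
}
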