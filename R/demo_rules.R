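#' Vocabulary pools used by the demonstration rulesets and the generator
#'
#' The bundled rulesets and the synthetic-corpus generator share finite
#' vocabularies so that every token a generated corpus can contain is
#' covered by a rule: integers, a fixed decimal pool, panel letters,
#' number+letter panel labels, and a fixed pool of PDB-style identifiers.
#'
#' @name demo_pools
#' @return Character vectors (pools) or a single string (URL prefix).
NULL

#' @rdname demo_pools
#' @export
demo_decimal_pool <- function() {
  c("0.5", "1.5", "2.5", "6.3", "7.5", "18.5", "29.8", "30.5", "32.2",
    "36.5", "44.9", "68.2", "74.1")
}

#' @rdname demo_pools
#' @export
demo_pdb_pool <- function() {
  c("1mfd", "1rzj", "1rzk", "5ec1", "5ec2", "5ebw", "5ebl", "5ebm", "6hd8",
    "1abc", "1xyz", "2qrs", "2tuv", "3def", "3ghi", "4jkl", "4mno", "5pqr",
    "6stu", "7vwx", "8yza", "9bcd", "1efg", "2hij", "3klm", "4nop", "5qrt",
    "6uvw", "7xyz", "8abc")
}

#' @rdname demo_pools
#' @export
demo_url_prefix <- function() "https://hla-ligand-atlas.org/peptide/"

#' Demonstration character rules
#'
#' Reference tables replicating the worked character-rule examples (en and
#' em dashes normalized to hyphen, `=` allowed in the age dataset, `&`
#' spelled out, the euro sign invalidating its items), ready to apply with
#' [apply_char_rules()].
#'
#' @param dataset `"age"` or `"data_loc"`.
#' @return A character-stage rule tibble.
#' @export
demo_char_rules <- function(dataset = c("age", "data_loc")) {
  dataset <- match.arg(dataset)
  common <- rbind(
    make_rules("–", "replace_with", "-", context = "20–67 years",
               count = 31L),
    make_rules("—", "replace_with", "-"),
    make_rules("&", "replace_with", "and", context = "Abstract & p. 664",
               count = 53L),
    make_rules("€", "invalidate", context = "Fig. 1 and PDB 6HD8",
               count = 10L)
  )
  if (dataset == "age") {
    rbind(common,
          make_rules("=", "allow", context = "mean age = 30 years",
                     count = 65L))
  } else {
    common
  }
}

#' Demonstration word rules
#'
#' Reference tables replicating the worked word-rule examples
#' (abbreviation expansion, plural-to-singular units, removal of age
#' filler words, figure/table head canonicalization) together with the
#' allow-and-categorize rows those examples need: units, statistical
#' qualifiers, range indicators, location words, and generated allow rows
#' covering the finite number/panel/identifier pools shared with the
#' synthetic generator.
#'
#' @param dataset `"age"` or `"data_loc"`.
#' @return A word-stage rule tibble.
#' @export
demo_word_rules <- function(dataset = c("age", "data_loc")) {
  dataset <- match.arg(dataset)
  numbers <- make_rules(as.character(0:120), "allow", category = "number",
                        stage = "word")
  decimals <- make_rules(demo_decimal_pool(), "allow", category = "number",
                         stage = "word")
  if (dataset == "age") {
    spelled <- c(one = "1", two = "2", three = "3", four = "4", five = "5",
                 six = "6", seven = "7", eight = "8", nine = "9", ten = "10",
                 eleven = "11", twelve = "12")
    repl <- c(wk = "week", wks = "week", weeks = "week",
              yr = "year", yrs = "year", years = "year",
              mo = "month", mos = "month", months = "month",
              hr = "hour", hrs = "hour", hours = "hour",
              days = "day", avg = "average", spelled)
    rbind(
      make_rules(names(repl), "replace_with", unname(repl), stage = "word",
                 context = "8-10 wk", count = 57L),
      make_rules(c("old", "age", "aged", "of"), "remove", stage = "word",
                 context = "6-10 week old", count = 710L),
      make_rules(c("week", "month", "year", "day", "hour"), "allow",
                 category = "unit", stage = "word"),
      make_rules(c("mean", "median", "average"), "allow",
                 category = "statistical", stage = "word"),
      make_rules(c("to", "through"), "allow", category = "range_indicator",
                 stage = "word"),
      numbers, decimals
    )
  } else {
    repl <- c(fig = "figure", figs = "figure", figures = "figure",
              tab = "table", tabs = "table", tables = "table",
              suppl = "supplemental", supp = "supplemental",
              supplementary = "supplemental",
              pg = "page", pgs = "page", p = "page", pp = "page")
    panels <- as.vector(outer(1:20, c("a", "b", "c", "d"), paste0))
    rbind(
      make_rules(names(repl), "replace_with", unname(repl), stage = "word",
                 context = "Figs. 1 and 2", count = 285L),
      make_rules(c("figure", "table", "page", "data", "set", "file",
                   "additional", "supplemental", "supporting",
                   "information"),
                 "allow", category = "location", stage = "word",
                 context = "additional file 1", count = 148L),
      make_rules("pdb", "allow", category = "pdb", stage = "word"),
      make_rules(demo_pdb_pool(), "allow", category = "pdb_id",
                 stage = "word"),
      make_rules("and", "allow", stage = "word"),
      make_rules(letters[1:6], "allow", category = "letter", stage = "word"),
      make_rules(panels, "allow", category = "number", stage = "word"),
      make_rules(paste0("s", 1:12), "allow", stage = "word"),
      make_rules(c("664", "1410", "11,782"), "allow", category = "number",
                 stage = "word"),
      numbers, decimals
    )
  }
}

#' Demonstration phrase-type rulesets
#'
#' Replicates the worked phrase patterns (ranges, statistical qualifiers,
#' PDB identifiers, location+number references, invalid unitless numbers
#' and ranges) plus the patterns their own standard-form outputs match, so
#' the phrase stage is idempotent on this ruleset. Note that by the phrase
#' stage a hyphenated range like `8-10` tokenizes to two number tokens
#' (the hyphen is a delimiter), so unitless hyphen ranges are caught by a
#' two-number pattern while spelled ranges ("8 to 10") are caught by a
#' number/range-indicator/number pattern.
#'
#' @param dataset `"age"` or `"data_loc"`.
#' @return A phrase ruleset tibble (see [phrase_ruleset()]).
#' @export
demo_phrase_rules <- function(dataset = c("age", "data_loc")) {
  dataset <- match.arg(dataset)
  if (dataset == "age") {
    phrase_ruleset(
      name = c("number unit", "range", "normalized range", "statistical",
               "trailing statistical", "unitless range",
               "unitless worded range", "number"),
      pattern = c(
        "[number(0)] [unit(1)]",
        "[number(0)] [range_indicator(1)] [number(2)] [unit(3)]",
        "[number(0)] [number(1)] [unit(2)]",
        "[statistical(0)] [number(1)] [unit(2)]",
        "[number(0)] [unit(1)] [statistical(2)]",
        "[number(0)] [number(1)]",
        "[number(0)] [range_indicator(1)] [number(2)]",
        "[number(0)]"
      ),
      valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      standard_form = c("[0] [1]", "[0]-[2] [3]", "[0]-[1] [2]",
                        "[0]: [1] [2]", "[2]: [0] [1]", "", "", "")
    )
  } else {
    phrase_ruleset(
      name = c("url", "pdb id", "loc number", "loc loc number", "number"),
      pattern = c(
        "[url(0)]",
        "[pdb(0)][pdb_id(1)]",
        "[location(0)] [number(1)]",
        "[location(0)] [location(1)] [number(2)]",
        "[number(0)]"
      ),
      valid = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      standard_form = c("[0]", "[0] [1]", "[0] [1]", "[0] [1] [2]", "")
    )
  }
}
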