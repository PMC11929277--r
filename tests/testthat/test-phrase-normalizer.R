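test_that("categorize uses reference categories, auto-categorizers, then unknown", {
  cat <- categorize("6 week mean", age_rules$word)
  expect_equal(cat$cat_string, "[number(0)][unit(1)][statistical(2)]")

  expect_equal(categorize("glarbl", age_rules$word)$cat_string,
               "[unknown(0)]")
  expect_equal(categorize("", age_rules$word)$cat_string, "")

  # numeric auto-categorization covers decimals and grouped digits
  expect_equal(categorize("11,782 6.3", empty_rules("word"))$categories,
               c("number", "number"))

  # PDB-style identifiers only when the dataset flag is on
  expect_equal(categorize("9zzz", empty_rules("word"))$categories, "unknown")
  expect_equal(categorize("9zzz", empty_rules("word"),
                          pdb_ids = TRUE)$categories, "pdb_id")

  url <- paste0(demo_url_prefix(), "aaaaaqsvy")
  expect_equal(categorize(url, dataloc_rules$word,
                          protected_prefixes = demo_url_prefix())$cat_string,
               "[url(0)]")
})

test_that("matching is exact on the category sequence, first pattern wins", {
  r <- normalize_phrase("6 to 8-week", age_rules$word, age_rules$phrase)
  expect_equal(r$matched_pattern, "range")
  expect_true(r$valid)
  expect_equal(r$output, "6-8 week")

  r <- normalize_phrase("8 to 10", age_rules$word, age_rules$phrase)
  expect_equal(r$matched_pattern, "unitless worded range")
  expect_false(r$valid)
  expect_true(is.na(r$output))

  r <- normalize_phrase("glarbl glarbl", age_rules$word, age_rules$phrase)
  expect_true(is.na(r$matched_pattern))
  expect_false(r$valid)
})

test_that("standard forms rearrange tokens with literal separators", {
  expect_equal(apply_standard_form(c("6", "week", "mean"), "[2]: [0] [1]"),
               "mean: 6 week")
  expect_equal(apply_standard_form(c("6", "to", "8", "week"), "[0]-[2] [3]"),
               "6-8 week")
  expect_equal(apply_standard_form(c("pdb", "1mfd"), "[0] [1]"), "pdb 1mfd")
  expect_error(apply_standard_form(c("a", "b"), "[5] [0]"), "index")
})

test_that("phrase normalization is idempotent over the demo rulesets", {
  set.seed(15)
  spec <- do.call(fixture_spec, c(list(n_items = 150, seed = 77),
                                  moderate_noise()))
  co <- generate_age_corpus(spec)
  r <- normalize_age(co$messy)
  valid <- r$segments[r$segments$valid, ]
  again <- phrase_stage(valid$phrase_normalized, age_rules$word,
                        age_rules$phrase)
  expect_true(all(again$valid))
  expect_identical(again$output, valid$phrase_normalized)
})

test_that("phrase accounting: no-match + invalid-match + valid = items entering", {
  spec <- do.call(fixture_spec, c(list(n_items = 200, seed = 5),
                                  moderate_noise()))
  co <- generate_age_corpus(spec)
  r <- normalize_age(co$messy)
  seg <- r$segments
  no_match <- sum(is.na(seg$matched_pattern))
  invalid_match <- sum(!is.na(seg$matched_pattern) & !seg$valid)
  valid <- sum(seg$valid)
  expect_equal(no_match + invalid_match + valid, nrow(seg))
})

test_that("ruleset lint flags duplicates and non-idempotent standard forms", {
  dup <- phrase_ruleset(c("a", "b"), c("[number(0)]", "[number(0)]"),
                        c(FALSE, FALSE))
  expect_warning(lint_phrase_ruleset(dup), "duplicate")

  orphan <- phrase_ruleset("solo", "[unit(0)] [number(1)]", "Y", "[1] [0]")
  expect_warning(lint_phrase_ruleset(orphan, empty_rules("word")),
                 "re-match")
})
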