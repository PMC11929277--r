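test_that("character rules replace, allow, and invalidate as decided", {
  r <- apply_char_rules("20–67 years", age_rules$char)
  expect_equal(r$output, "20-67 years")
  expect_true(r$valid)
  expect_equal(r$distance, 1L)

  r <- apply_char_rules("Abstract & p. 664", dataloc_rules$char)
  expect_equal(r$output, "abstract and p. 664")
  expect_true(r$valid)

  r <- apply_char_rules("price € 30", dataloc_rules$char)
  expect_false(r$valid)
  expect_identical(r$output, r$input)
  expect_equal(r$invalidating_units, "€")
  expect_equal(r$distance, 0L)

  r <- apply_char_rules("6 week", age_rules$char)
  expect_equal(r$output, "6 week")
  expect_equal(r$distance, 0L)
})

test_that("undecided characters fail validation and pass through unchanged", {
  r <- apply_char_rules("30 ~ 40", age_rules$char)
  expect_false(r$valid)
  expect_identical(r$output, "30 ~ 40")
  expect_equal(r$invalidating_units, "~")
})

test_that("a replacement introducing an invalidated character errors", {
  rules <- rbind(make_rules("@", "replace_with", "€"),
                 make_rules("€", "invalidate"))
  expect_error(apply_char_rules("a@b", rules), "inconsistency")
})

test_that("word rules remove, replace, and allow whole tokens", {
  r <- apply_word_rules("6-10 week old", age_rules$word)
  expect_equal(r$output, "6-10 week")
  expect_true(r$valid)

  r <- apply_word_rules("8-10 wk", age_rules$word)
  expect_equal(r$output, "8-10 week")
  expect_true(r$valid)

  r <- apply_word_rules("additional file 1", dataloc_rules$word)
  expect_identical(r$output, "additional file 1")
  expect_true(r$valid)
  expect_equal(r$distance, 0L)

  # undecided token: invalid, untouched
  r <- apply_word_rules("6 glarbl week", age_rules$word)
  expect_false(r$valid)
  expect_identical(r$output, "6 glarbl week")
  expect_equal(r$invalidating_units, "glarbl")
})

test_that("word invalidate rules freeze the item", {
  rules <- rbind(age_rules$word, make_rules("unknown", "invalidate",
                                            stage = "word"))
  r <- apply_word_rules("6 week unknown", rules)
  expect_false(r$valid)
  expect_identical(r$output, "6 week unknown")
  expect_equal(r$invalidating_units, "unknown")
})

test_that("protected-prefix items skip word normalization", {
  url <- paste0(demo_url_prefix(), "aaaaaqsvy")
  r <- apply_word_rules(url, dataloc_rules$word,
                        protected_prefixes = demo_url_prefix())
  expect_identical(r$output, url)
  expect_true(r$valid)
  expect_equal(r$distance, 0L)
})

test_that("removal collapses the doubled delimiter at edges and inside", {
  rules <- make_rules(c("old", "stop"), "remove", stage = "word")
  rules <- rbind(rules, make_rules(c("a", "b", "6", "week"), "allow",
                                   stage = "word"))
  expect_equal(apply_word_rules("a old b", rules)$output, "a b")
  expect_equal(apply_word_rules("old a", rules)$output, "a")
  expect_equal(apply_word_rules("a old", rules)$output, "a")
  expect_equal(apply_word_rules("6-old week", rules)$output, "6-week")
})

test_that("char and word stages are idempotent on their own output", {
  set.seed(7)
  spec <- do.call(fixture_spec, c(list(n_items = 120, seed = 31),
                                  moderate_noise()))
  co <- generate_age_corpus(spec)
  cs <- char_stage(co$messy, age_rules$char)
  cs2 <- char_stage(cs$normalized, age_rules$char)
  expect_identical(cs2$normalized, cs$normalized)
  expect_identical(cs2$valid | !cs$valid, rep(TRUE, nrow(cs)))

  ws <- word_stage(cs, age_rules$word)
  ok <- which(ws$entered)
  ws2 <- vapply(ws$normalized[ok], function(x) {
    apply_word_rules(x, age_rules$word)$output
  }, character(1))
  expect_identical(unname(ws2), ws$normalized[ok])
})

test_that("word stage gates on character validity and drops no item", {
  cs <- char_stage(c("6 week", "bad ~ char"), age_rules$char)
  ws <- word_stage(cs, age_rules$word)
  expect_equal(nrow(ws), 2L)
  expect_true(ws$entered[1])
  expect_false(ws$entered[2])
  expect_true(is.na(ws$valid[2]))
  expect_identical(ws$char_normalized[2], "bad ~ char")
})

test_that("stage distances match the independent DP oracle on random rule applications", {
  set.seed(1234)
  alph <- mixed_alphabet()
  for (i in 1:200) {
    s <- rand_string(alph, max_len = 25L, min_len = 1L)
    r <- apply_char_rules(s, age_rules$char)
    expect_equal(r$distance, lev_dp(r$input, r$output))
  }
})
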