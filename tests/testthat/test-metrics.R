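test_that("levenshtein reproduces reference distances", {
  expect_equal(levenshtein("18 years average", "average 18 years"), 14L)
  url <- paste0(demo_url_prefix(), "AAAAAQSVY")
  expect_equal(levenshtein(url, tolower(url)), 9L)
  expect_equal(levenshtein("abc", "abc"), 0L)
  expect_equal(levenshtein(c("a", "ab"), c("", "ba")), c(1L, 2L))
})

test_that("levenshtein agrees with the DP oracle; metric axioms hold", {
  set.seed(2024)
  alph <- mixed_alphabet()
  a <- replicate(500, rand_string(alph))
  b <- replicate(500, rand_string(alph))
  expect_equal(levenshtein(a, b), mapply(lev_dp, a, b), ignore_attr = TRUE)
  # symmetry and triangle inequality on sampled triples
  c_ <- replicate(100, rand_string(alph, max_len = 15L))
  for (i in 1:100) {
    x <- a[i]; y <- b[i]; z <- c_[i]
    expect_equal(levenshtein(x, y), levenshtein(y, x))
    expect_lte(levenshtein(x, z), levenshtein(x, y) + levenshtein(y, z))
  }
})

test_that("stage validity is the fraction of entering items that pass", {
  expect_equal(stage_validity(c(TRUE, TRUE, TRUE, FALSE)), 0.75)
  expect_equal(stage_validity(c(TRUE, TRUE)), 1.0)
  expect_equal(stage_validity(c(FALSE, FALSE)), 0.0)
  # NA flags mark items that never entered the stage
  expect_equal(stage_validity(c(TRUE, NA, FALSE)), 0.5)
  expect_error(stage_validity(logical()), "no items")
})

test_that("summarize_metrics reports means, both SDs, and distributions", {
  items <- tibble::tibble(
    protected = c(FALSE, FALSE, TRUE),
    char_distance = c(1L, 3L, 9L),
    split_phrase_count = c(2L, 4L, 1L)
  )
  s <- summarize_metrics(items)
  sp <- s$summary[s$summary$metric == "split_phrase_count", ]
  expect_equal(sp$mean, 7 / 3)
  cd <- s$summary[s$summary$metric == "char_distance", ]
  expect_equal(cd$sd_pop, sqrt(mean((c(1, 3, 9) - 13 / 3)^2)))
  expect_equal(cd$sd_sample, stats::sd(c(1, 3, 9)))
  expect_named(s$distributions,
               c("char_distance", "split_phrase_count"))

  noproto <- summarize_metrics(items, exclude_protected = TRUE)
  expect_equal(noproto$summary$mean[
    noproto$summary$metric == "split_phrase_count"], 3.0)

  one <- summarize_metrics(tibble::tibble(char_distance = 5L))
  expect_equal(one$summary$sd_pop, 0)
  expect_equal(one$summary$sd_sample, 0)

  expect_error(summarize_metrics(items[0, ]), "summarize")
  expect_error(
    summarize_metrics(tibble::tibble(protected = TRUE, char_distance = 1L),
                      exclude_protected = TRUE),
    "excluding"
  )
})

test_that("aggregate stage counts reconcile through the gates", {
  spec <- do.call(fixture_spec, c(list(n_items = 150, seed = 41),
                                  moderate_noise()))
  co <- generate_age_corpus(spec)
  r <- normalize_age(co$messy)
  it <- r$items
  expect_equal(sum(it$char_valid) + sum(!it$char_valid), nrow(it))
  entered_word <- sum(!is.na(it$word_valid))
  expect_equal(entered_word, sum(it$char_valid))
  expect_equal(sum(it$word_valid, na.rm = TRUE) +
                 sum(!it$word_valid, na.rm = TRUE), entered_word)
  entered_phrase <- sum(!is.na(it$split_phrase_count))
  expect_equal(entered_phrase, sum(it$word_valid, na.rm = TRUE))
})
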