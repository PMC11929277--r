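test_that("fixture generation is deterministic given spec + seed", {
  spec <- do.call(fixture_spec, c(list(n_items = 50, seed = 9),
                                  moderate_noise()))
  expect_identical(generate_age_corpus(spec), generate_age_corpus(spec))
  dspec <- do.call(fixture_spec, c(list(n_items = 50, seed = 9),
                                   modifyList(moderate_noise(),
                                              list(url_fraction = 0.3,
                                                   pdb_fraction = 0.1))))
  expect_identical(generate_dataloc_corpus(dspec),
                   generate_dataloc_corpus(dspec))
  # and the ambient RNG stream is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_age_corpus(spec)); after <- stats::runif(1)
  expect_equal(before, after)
})

test_that("zero noise yields messy == canonical", {
  co <- generate_age_corpus(fixture_spec(80, seed = 3))
  expect_identical(co$messy, co$ground_truth)
  urls <- generate_dataloc_corpus(fixture_spec(25, seed = 4,
                                               url_fraction = 1))
  expect_identical(urls$messy, urls$ground_truth)
})

test_that("composed variance operators keep a recoverable canonical form", {
  spec <- fixture_spec(200, seed = 21, spelled_number = 1, plural_unit = 1,
                       age_words = 1)
  co <- generate_age_corpus(spec)
  singles <- grepl("^[0-9]+ [a-z]+$", co$ground_truth)
  expect_true(any(grepl(" olds?$| of age$", co$messy[singles])))
  r <- normalize_age(co$messy)
  expect_identical(r$items$verdict, co$ground_truth)
})

test_that("generated items stay inside the documented alphabet", {
  spec <- do.call(fixture_spec, c(list(n_items = 200, seed = 55),
                                  moderate_noise()))
  co <- generate_age_corpus(spec)
  expect_false(any(grepl("[^a-zA-Z0-9 .,:=–€-]",
                         co$messy)))
  dspec <- do.call(fixture_spec, c(list(n_items = 200, seed = 56),
                                   modifyList(moderate_noise(),
                                              list(url_fraction = 0.2,
                                                   pdb_fraction = 0.1))))
  dco <- generate_dataloc_corpus(dspec)
  expect_false(any(grepl("[^a-zA-Z0-9 .,:/€-]", dco$messy)))
})

test_that("corpus TSVs round-trip", {
  co <- generate_age_corpus(fixture_spec(20, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(co, path)
  back <- read_corpus(path)
  expect_equal(back$messy, co$messy)
  expect_equal(back$ground_truth, co$ground_truth)
})
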