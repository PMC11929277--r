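test_that("build_review exempts default-valid characters but not words", {
  units <- count_units("mean age = 30 years", "char")
  review <- build_review(units, empty_rules("char"), empty_rules("char"),
                         "char")
  expect_equal(review$unit, "=")

  wunits <- count_units("8-10 wk", "word")
  wreview <- build_review(wunits, empty_rules("word"), empty_rules("word"),
                          "word")
  expect_setequal(wreview$unit, c("8", "10", "wk"))
})

test_that("already-decided units get no new review row", {
  ref <- make_rules("=", "allow")
  units <- count_units("mean = 30", "char")
  review <- build_review(units, empty_rules("char"), ref, "char")
  expect_equal(nrow(review), 0L)
})

test_that("context samples cap at 300 characters and carry counts", {
  items <- c(strrep("x=", 100), strrep("=y", 150))
  units <- count_units(items, "char")
  eq <- units[units$unit == "=", ]
  expect_equal(eq$count, 250L)
  expect_lte(nchar(eq$context), 300L)
})

test_that("migrate_decided moves decided rows and rejects bad rows", {
  review <- rbind(
    make_rules("wk", "replace_with", "week", stage = "word"),
    make_rules("glarbl", "undecided", stage = "word")
  )
  out <- migrate_decided(review, empty_rules("word"))
  expect_equal(out$reference$unit, "wk")
  expect_equal(out$review$unit, "glarbl")

  # idempotent
  again <- migrate_decided(out$review, out$reference)
  expect_identical(again$review, out$review)
  expect_identical(again$reference, out$reference)

  two <- make_rules("z", "remove")
  two$allow <- "x"
  expect_error(migrate_decided(two, empty_rules("char")), "z")

  blank <- make_rules("q", "allow")
  blank$allow <- ""
  blank$replace_with <- " "
  expect_error(migrate_decided(blank, empty_rules("char")), "remove")
})

test_that("review/reference conserve every observed unit across cycles", {
  set.seed(99)
  items <- replicate(40, rand_string(mixed_alphabet(), max_len = 20L,
                                     min_len = 1L))
  review <- empty_rules("char")
  reference <- empty_rules("char")
  for (cycle in 1:5) {
    # simulate the user deciding a random subset of review rows
    if (nrow(review) > 0L) {
      pick <- which(stats::runif(nrow(review)) < 0.5)
      review$allow[pick] <- "x"
    }
    mig <- migrate_decided(review, reference)
    units <- count_units(items, "char")
    review <- build_review(units, mig$review, mig$reference, "char")
    reference <- mig$reference
    observed <- setdiff(units$unit, c(default_valid_chars(), LETTERS))
    where <- observed %in% review$unit
    where_ref <- observed %in% reference$unit
    expect_true(all(xor(where, where_ref)))
    expect_false(any(duplicated(c(review$unit, reference$unit))))
  }
})

test_that("mass_allow migrates matching rows with a category", {
  review <- build_review(count_units(c("8 week", "pdb 1abc"), "word"),
                         empty_rules("word"), empty_rules("word"), "word")
  out <- mass_allow(review, empty_rules("word"), "^[0-9]+$", "number")
  expect_true("8" %in% out$reference$unit)
  expect_equal(out$reference$category[out$reference$unit == "8"], "number")
  expect_false("8" %in% out$review$unit)
  expect_true("pdb" %in% out$review$unit)
})

test_that("rule tables survive a TSV round trip", {
  rules <- demo_word_rules("age")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, path)
  back <- read_rules(path, "word")
  expect_equal(as.data.frame(back), as.data.frame(rules))
})

test_that("phrase ruleset parsing enforces its invariants", {
  rs <- phrase_ruleset("statistical",
                       "[statistical(0)] [number(1)] [unit(2)]",
                       "Y", "[0]: [1] [2]")
  expect_equal(rs$categories[[1]], c("statistical", "number", "unit"))

  inv <- phrase_ruleset("number", "[number(0)]", "N")
  expect_false(inv$valid)

  expect_error(phrase_ruleset("bad", "[a(0)] [b(1)]", "Y", "[5] [0]"),
               "outside")
  expect_error(phrase_ruleset("bad", "[a(1)] [b(0)]", "N"), "0..n-1")
  expect_error(phrase_ruleset("bad", "[a(0)] junk", "N"), "malformed")
  expect_error(phrase_ruleset("bad", "[a(0)]", "Y", ""), "standard form")
})

test_that("load_phrase_ruleset bootstraps a blank file and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rs <- load_phrase_ruleset(path)
  expect_true(file.exists(path))
  expect_equal(nrow(rs), 0L)

  write_phrase_ruleset(demo_phrase_rules("age"), path)
  back <- load_phrase_ruleset(path)
  expect_equal(back$name, demo_phrase_rules("age")$name)
  expect_equal(back$valid, demo_phrase_rules("age")$valid)
})
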