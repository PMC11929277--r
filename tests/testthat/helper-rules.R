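# Shared demo rulesets; built once per test run.
age_rules <- list(
  char = demo_char_rules("age"),
  word = demo_word_rules("age"),
  phrase = demo_phrase_rules("age")
)
dataloc_rules <- list(
  char = demo_char_rules("data_loc"),
  word = demo_word_rules("data_loc"),
  phrase = demo_phrase_rules("data_loc")
)

normalize_dataloc <- function(items, splitter = TRUE) {
  normalize_corpus(items, dataloc_rules$char, dataloc_rules$word,
                   dataloc_rules$phrase,
                   protected_prefixes = demo_url_prefix(),
                   pdb_ids = TRUE, splitter = splitter)
}

normalize_age <- function(items) {
  normalize_corpus(items, age_rules$char, age_rules$word, age_rules$phrase)
}
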