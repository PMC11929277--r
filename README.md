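# textnorm

Rule-based normalization of free-text data fields, for database curators.

Curated biomedical databases accumulate free-text columns — subject ages
("6 to 8 weeks", "Mean age of 32.2 years"), data locations ("Figs. 1, 2 and
4", "PDB: 5EC1", URLs) — whose values mean the same thing in dozens of
surface forms. textnorm standardizes such a column with user-authored
rules applied at three levels of variance:

1. **Characters.** Every distinct character outside an always-valid set
   (lowercase letters, digits, basic punctuation) surfaces in a *review*
   TSV with its contexts and occurrence count. The curator records an
   *action decision* per character — `replace_with`, `remove`,
   `invalidate`, or `allow` — and on the next run decided rows migrate to
   a *reference* TSV (the rule bank) and are applied. An item passes the
   character stage iff only allowed characters remain.
2. **Words.** The same review/reference cycle over delimiter-bounded word
   tokens (with a `category` column: `unit`, `number`, `statistical`,
   `location`, ...). Abbreviations expand (`wk` → `week`), plurals
   singularize, filler words drop (`old`), and an item passes iff every
   remaining token is allowed.
3. **Phrases.** Each word-valid item is serialized into a categorization
   string such as `[number(0)][unit(1)][statistical(2)]` and matched
   against a phrase-type ruleset. A matched *valid* pattern rewrites the
   item into its standard form (template `[2]: [0] [1]` turns
   `6 week mean` into `mean: 6 week`); matching an *invalid* pattern (a
   unitless number, say) deliberately invalidates the item; no match
   leaves it invalid pending a new pattern.

An accessory splitter expands list-like data locations
(`Fig. 2A,B,C, Fig. 6.` → `Fig. 2a`, `Fig. 2b`, `Fig. 2c`, `Fig. 6`)
between the word and phrase stages, with per-item bookkeeping (split
phrase count, phrase validity rate) recorded once per original item.
Levenshtein distances quantify how much the character and word stages
changed each item; they are intentionally not tracked at the phrase
stage, where benign reorderings produce large distances (e.g.
`18 years average` vs `average 18 years` is distance 14).

## Worked example

Bundled demonstration rulesets (`demo_char_rules()`, `demo_word_rules()`,
`demo_phrase_rules()`) cover the classic age and data-location rewrites:

```r
library(textnorm)
r <- normalize_corpus(
  c("Mean age = 30 years", "6 to 8-week old", "8-10 wk",
    "20–67 years", "6 week mean", "8–10"),
  demo_char_rules("age"), demo_word_rules("age"), demo_phrase_rules("age"))
r$items[, c("original", "char_normalized", "word_normalized", "verdict")]
#>              original     char_normalized word_normalized       verdict
#> 1 Mean age = 30 years mean age = 30 years    mean 30 year mean: 30 year
#> 2     6 to 8-week old     6 to 8-week old     6 to 8-week      6-8 week
#> 3             8-10 wk             8-10 wk       8-10 week     8-10 week
#> 4         20–67 years         20-67 years      20-67 year    20-67 year
#> 5         6 week mean         6 week mean     6 week mean  mean: 6 week
#> 6                8–10                8-10            8-10       INVALID
```

Each stage's column shows the string after that stage; `verdict` is the
final standard form, or `INVALID` for items that failed a stage (here the
unitless range `8–10`, deliberately invalidated because its unit — hours?
weeks? years? — is unknowable). With the splitter on, a list-like data
location fans out into segments:

```r
d <- normalize_corpus("Fig. 2A,B,C, Fig. 6.",
  demo_char_rules("data_loc"), demo_word_rules("data_loc"),
  demo_phrase_rules("data_loc"),
  protected_prefixes = demo_url_prefix(), pdb_ids = TRUE, splitter = TRUE)
d$segments$phrase_normalized
#> [1] "figure 2a" "figure 2b" "figure 2c" "figure 6"
d$items$split_phrase_count        # 4
d$items$phrase_validity_rate      # 1
```

For file-based curation, `run_pipeline()` (or the CLI,
`Rscript inst/cli/normalize.R run-all --config config.yml`) maintains the
review/reference TSVs in a working directory, writes per-stage outputs,
and appends structured log lines with per-stage validity counts.
`generate_age_corpus()` and `generate_dataloc_corpus()` produce seeded
messy corpora with ground-truth canonical forms for testing rulesets.

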