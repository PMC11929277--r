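---
title: "Methods: rule-driven normalization of free-text fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-driven normalization of free-text fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textnorm)
```

## The model

textnorm treats a free-text column as a set of *data items* whose
variance decomposes into three levels, each handled by its own stage:

* **Character variance** — stray symbols, dash variants, case. A
  character-level rule maps one character to an action: substitute it
  (`replace_with`), delete it (`remove`), condemn any item containing it
  (`invalidate`), or accept it (`allow`). Lowercase letters, digits, and
  a small configurable punctuation set (`default_valid_chars()`) are
  always valid and never reviewed.
* **Word variance** — abbreviations, plurals, misspellings, filler
  words. A *word* is a maximal run of non-delimiter characters; the
  delimiter set (`default_delimiters()`) contains space, tab, hyphen,
  comma, period, colon, semicolon, parentheses, brackets, slash, and the
  equals sign, plus the start and end of string. Word rules use the same
  four actions and add a `category` column that feeds the phrase stage.
* **Phrase variance** — the same content in different arrangements. Each
  word-valid item is mapped to a categorization string (categories with
  0-based positions, e.g. `[number(0)][unit(1)][statistical(2)]`) and
  compared against a phrase-type ruleset. A pattern carries a validity
  flag and, when valid, a standard-form template (`[2]: [0] [1]`) that
  rearranges the tokens into the canonical surface.

The method is deliberately user-dependent: no rule is ever guessed. A
unit without a rule leaves its items invalid and surfaces in the review
file for the curator to decide; the review → reference migration happens
at the start of every run, so curation proceeds in short cycles. Two
invariants underpin this workflow and are enforced by tests: every
observed non-default unit lives in exactly one of review/reference
(conservation), and re-running any stage with unchanged rules reproduces
its output byte for byte (idempotence). Invalid items are always carried
through unmodified, so later rule additions can still rescue them.

### Validation gates

An item enters the word stage only if it passed the character stage, and
the phrase stage only if it also passed the word stage. Validity rates
are therefore reported per stage over the items *entering* that stage.
At the phrase stage an item is valid only if it matches a pattern
flagged valid — matching an invalid pattern (a bare number, a unitless
range) is an intentional elimination of unusable data, not a failure of
the machinery.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `delimiters` | space, tab, `- , . : ; ( ) [ ] / =` | the common separators of curated free text; configurable per dataset |
| `default_valid_chars` | a–z, 0–9, space, `. , - : ; ( ) /` | characters that never need review; `=` is deliberately excluded so it must be allowed explicitly |
| `lowercase` | `TRUE` | case variance is handled wholesale rather than with 26 rules |
| `protected_prefixes` | none (demo: the HLA Ligand Atlas URL prefix) | URLs are lowercased at the character stage but exempt from word normalization and splitting |
| `merge_numeric` | `TRUE` | a single `.` or `,` between digits stays inside the token so `6.3` and `11,782` survive tokenization |
| `enable_pdb_autocategory` | `FALSE` | 4-character alphanumeric tokens starting with a digit auto-categorize as `pdb_id` only where such identifiers are expected |

## Surface-form decisions

Canonical output is all-lowercase. Uppercase letters sit outside the
default-valid set, and lowercasing first means one engine default
replaces a page of per-letter rules; the cost is that display forms like
"Fig." are not reintroduced, so the canonical figure word is `figure`.
Replacing a token cannot touch its neighbouring delimiters, so
`figs. 1` → `figure. 1` briefly carries a stray period; the phrase stage
heals this because templates discard input delimiters entirely and
supply all output separators (`figure. 1` → `figure 1`).

By the phrase stage a hyphenated range such as `8-10` tokenizes to two
number tokens — the hyphen is a delimiter — so the demo age ruleset
invalidates unitless ranges with a two-number pattern (`unitless range`)
and keeps a separate `[number][range_indicator][number]` pattern
(`unitless worded range`) for spelled ranges like `8 to 10`. Valid
ranges normalize to `A-B unit` via templates, and a `normalized range`
pattern (`[number][number][unit]`) re-matches that output, which is what
makes the phrase stage idempotent; `lint_phrase_ruleset()` checks this
closure property for any ruleset, and also warns when a template drops a
pattern position (the `range` template intentionally drops the
range-indicator word).

Rule application order within a stage is fixed for determinism: all
`replace_with` substitutions and `remove` deletions in one left-to-right
pass, then the `invalidate` check, then the `allow` check. Replacement
output is not re-scanned in the same run — new units surface at the next
review cycle instead, which keeps rule semantics predictable and
prevents rewrite loops. Removing a word merges the delimiters around it:
start/end of string absorb the separator, otherwise the left separator
survives (`6-10 week old` → `6-10 week`, `mean age = 30` → `mean 30`).
Ties among phrase patterns go to the first match in file order; duplicate
category sequences are linted. Degenerate inputs are defined everywhere:
empty strings tokenize to nothing and reconstruct exactly, an
all-delimiter string is preserved via an orphan-delimiter attribute, and
an unsplittable item returns itself as its single segment.

Occurrence counts in review files are total occurrences across all data
items (not distinct-item counts); review contexts are distinct
containing items in dataset order joined by `" | "`, truncated at 300
characters. Action cells accept any non-empty text as a mark, except
that a whitespace-only `replace_with` is rejected with a pointer to
`remove`. When a unit somehow appears in both review and reference, the
reference wins and a warning is issued — the reference is the rule bank.

## The list splitter

The splitter is an accessory stage between word and phrase for
data-location-like fields. Its grammar is a design choice: elements are
separated by commas, semicolons, and the words "and"/"&"; a *head* (one
or more location words such as `supplemental figure`) followed by
exactly one number sets the current head and distributes over subsequent
bare numbers; letters attached to or following a number expand into one
lowercased segment each (`Fig. 2A,B,C` → `Fig. 2a`, `Fig. 2b`,
`Fig. 2c`). Anything that does not parse as head + number is kept whole
as its own segment and resets the head — so hyphen ranges (`Figs. 1-4`)
are flagged for review rather than guessed at, and mixed tails like
`Supporting Information S2 Figure` survive verbatim (and fail phrase
validation, which is the honest outcome). Segments are atomic:
re-splitting a segment is a no-op. Split phrase count and phrase
validity rate are recorded exactly once per original item, on its first
segment row, so corpus means are not skewed by the row fan-out.

## Metrics

`levenshtein()` wraps base R's generalized edit distance (`utils::adist`)
at unit costs; the test suite cross-checks it against an independently
coded dynamic-programming oracle on 10,000 random pairs and verifies
symmetry and the triangle inequality on sampled triples. Distances are
computed on the exact stored stage strings (post-lowercasing): character
distance compares the original with the character-normalized string,
word distance the character-normalized with the word-normalized string.
No distance is recorded at the phrase stage. Because it is unstated
whether published summary deviations are population or sample
statistics, `summarize_metrics()` emits both.

## What the synthetic generator emulates — and what it does not

`generate_age_corpus()` and `generate_dataloc_corpus()` produce messy
strings *with known canonical verdicts* by composing variance operators
on canonical forms: unit abbreviation and pluralization, spelled-out
numbers, en-dash and worded ranges, hyphen-attached units, statistical
qualifiers with `=`/trailing order, age filler words, uppercase,
stray-character injection (`€`), list-like enumerations with distributed
heads and letter suffixes, fixed-prefix URLs with 9-letter paths,
PDB-style identifiers, and unitless numbers (ground truth `INVALID`).
All rates default to zero — a zero-noise corpus is its own canonical
form — and `moderate_noise()` documents a realistic mixture (30–40%
abbreviation/plural rates, a few percent stray characters) chosen once
as typical of hand-entered curation fields.

The generator draws from finite vocabularies (integers 0–120, a fixed
decimal pool, panel labels, a fixed identifier pool) that the bundled
demonstration rulesets fully cover, which is what makes exact round-trip
scoring possible: the pipeline's verdict (canonical segments or
`INVALID`) is compared string-for-string with ground truth. What passing
that check shows is that the engine applies a *covering* ruleset
correctly; it does not show that any fixed ruleset covers real data,
where vocabulary is open-ended, misspellings are unbounded, and list
syntax is messier than the generator's grammar. On real corpora the
uncovered remainder surfaces as review rows — never as silently wrong
outputs — and the curation cycle continues until the return on new rules
diminishes.

## Problem sizes

The bundled checks run at sizes chosen to exercise every property while
keeping a full suite run in the low minutes on one core: 10,000
random pairs for the distance oracle, 1,000 fixture items for stage
idempotence, 300-item tokenizer round-trip sampling, 5 simulated
curation cycles for conservation, and 200–1,000-item corpora for
round-trip recovery (the observed rate on covered corpora is 100%,
against a ≥ 99% requirement). Larger corpora change nothing structurally;
the engine is linear in total text size.

## Known limitations

* The splitter grammar is intentionally conservative; nested or mixed
  lists beyond head + enumeration are kept whole rather than guessed.
* Word matching is exact: misspellings need explicit rules
  (`mass_allow()` helps only for regex-shaped vocabularies such as
  numbers or structured identifiers).
* No semantic or context-dependent disambiguation: a word means one
  thing per dataset.
* Canonical surfaces are all-lowercase; consumers wanting display case
  must post-process.
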