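---
title: "Methods: two-pass rule-based FEV1 extraction and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-pass rule-based FEV1 extraction and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirotext)
```

## The problem

Forced expiratory volume in one second (FEV1) is the standard physiologic
measure of airflow limitation and the anchor for grading severity of
chronic obstructive pulmonary disease. In many health systems spirometry is
run on vendor equipment that is poorly linked to the structured electronic
health record, so the numbers end up transcribed into free-text progress
notes instead of structured measurement tables. spirotext recovers those
values with a deliberately lightweight, fully rule-based pipeline: no
trained components, every decision auditable, every extraction traceable to
a character offset.

## The two-pass pipeline

**Pass one — candidate retrieval.** `build_keyword_index()` tokenizes each
note into maximal runs of alphanumeric characters, case-folded, emulating
the word-breaker of a relational full-text index. `find_candidates()` then
returns every note containing a token with the prefix `"fev"`. This pass is
deliberately permissive: `fever` passes, because the division of labor puts
all rejection logic in pass two; its only job is to shrink the scan set
cheaply. Prefix matching over alphanumeric-run tokens has one structural
consequence we rely on: a mention the pattern pass can match always yields
an fev-prefixed token, so the candidate pass is *complete* — two-pass and
single-pass extraction provably return identical results (a property the
test suite checks corpus-wide).

**Pass two — pattern extraction.** For each candidate note,
`find_fev1_mentions()` matches the surface variants `FEV1`, `FEV-1`,
`FEV_1` and `FEV 1` case-insensitively, requiring a non-alphanumeric
character on *both* sides of the match. The trailing boundary is the
negation rule: `fever`, `feverish`, `fevers` can never match because
letters continue after `fev`. The leading boundary is our addition; beyond
blocking junk like `XFEV1`, it is required for candidate-pass completeness,
since the keyword tokenizer would fold `XFEV1` into a single token that is
not fev-prefixed. The space variant `FEV 1` goes beyond the classic trio
because it is a common transcription form; it is config-removable
(`pattern_variants`).

`scan_window_for_value()` then looks *forward* from the mention end for the
first numeric token whose first character lies within `window_chars`
(default 20) characters. The window is forward-only because clinical
reporting convention places the value after its label (`FEV1: 1.85`); a
bidirectional window would let one number serve two labels and capture
dates preceding a mention. The numeric grammar is digits, optionally one
decimal point with trailing digits, optionally an attached `%` kept as a
unit hint. Comma-grouped numbers are not numeric: FEV1 is never reported
with thousands separators.

Two guards refine the scan:

* **Date-like skip** (`skip_datelike`): a token immediately followed by
  `/digit` *or* immediately preceded by `/` is passed over, so every
  component of `12/04/2019` is skipped and scanning continues. The
  preceded-by-`/` half is needed to avoid capturing the tail of a date
  (`04` out of `12/04`), which the followed-by rule alone would return.
* **Ratio guard** (`exclude_ratio_context`): if the text between the
  mention and the token contains `FVC`, the mention yields nothing — the
  first number after `FEV1/FVC` is the ratio, typically 0.4–0.7, which
  would otherwise validate as a plausible liters value. The guard abandons
  the mention rather than skipping the token, because any number inside a
  ratio phrase is suspect; later mentions in the note are still scanned.

`validate_value()` applies plausibility ranges: liters `[0.2, 8.0]`,
percent-predicted `[10, 160]`. The ranges are deliberately generous (0.2 L
and 160% are extreme but physiologically possible); their job is to reject
ages, temperatures, years and dates, not to clip the clinical tails. A
`%`-suffixed token must sit in the percent range; a bare number is read as
liters first, percent-predicted second, and the chosen interpretation is
recorded in `unit_guess` since free text rarely states the unit.

With the default `emit_all_mentions = FALSE`, `extract_note()` emits the
first mention in document order that yields a valid value — there is no
principled way to rank multiple FEV1 strings in one note, so the tool takes
the first and raises the `multi_mention` flag so downstream users can
audit those notes (the flagged value may refer to a previous study).

All offsets in the output are 0-based and half-open; one stated convention
everywhere prevents off-by-one drift between the mention finder, the
scanner and the serialized records.

## Evaluation module

The scoring unit is the note (a record), not the mention: a note with any
emitted extraction is tool-positive. From the confusion counts against a
reference-annotation table we report precision — identical to positive
predictive value for a tool with no ranking — recall, and their harmonic
mean F. Undefined quantities (zero denominators) are reported as `NA`,
never coerced to 0. The PPV interval is a Wilson score interval, chosen
because it behaves sensibly at proportions near 0 and 1, exactly where a
high-precision extractor lives; Wald collapses to zero width at p = 1.
Value-level accuracy over true positives uses a 0.5% relative tolerance by
default — enough to absorb decimal re-formatting, tight enough to catch any
wrong-number capture — and Spearman's coefficient (average ranks for ties)
summarizes rank agreement between extracted and reference values.

## The synthetic corpus generator

No public corpus of clinical notes with FEV1 annotations exists, so the
package ships a seeded generator (`generate_corpus()`) that builds one with
exact gold annotations. Each note draws independently:

| parameter | default | role |
|---|---|---|
| `p_positive` | 0.40 | note carries a true FEV1 value |
| `p_fever_distractor` | 0.20 | a fever sentence (the classic keyword false positive) |
| `p_valueless_fev` | 0.05 | an FEV1 mention with no number in reach |
| `p_ratio_context` | 0.10 | an FEV1/FVC phrase |
| `p_multi_mention` | 0.15 | positives with a second value mention |
| `p_percent_format` | 0.50 | planted value styled as percent-predicted |

Planted values come from truncated normals — liters mean 2.0, sd 0.8 on
[0.5, 5]; percent-predicted mean 65, sd 20 on [15, 140] — a plausible
COPD-clinic mixture of moderate-to-severe obstruction. The truncation
bounds sit strictly *inside* the extraction plausibility ranges on purpose:
on distractor-free positives, any disagreement between generator and
extractor is a code defect, never a configuration mismatch
("extractability by construction"; the suite asserts exact value recovery).
The template bank is fixed in the source so gold answers are stable;
valueless-mention templates keep at least 20 digit-free characters after
the mention so the forward window can never leak into the next sentence.
The RNG is pinned (Mersenne-Twister, inversion, rejection sampling) so a
seed produces byte-identical corpora across platforms, and the generator
restores the caller's RNG stream.

What the generator does *not* emulate — and hence what green tests do not
show about real notes: misspellings and OCR noise, tabular/semi-structured
PFT report layouts, pre- versus post-bronchodilator labeling, values
preceding their label, and narrative numbers adjacent to FEV1 mentions
that belong to other measurements. Performance on the synthetic corpus is
an upper bound that certifies the rules do what they claim on the failure
modes they were designed around, not an estimate for any real corpus.

## Problem sizes and numerical choices

The end-to-end suite and the acceptance script use a 500-note corpus at the
defaults above (about 200 positives), where the full pipeline — index,
candidate pass, extraction, scoring — runs in a few seconds; the
scanner-versus-oracle property suite uses 10,000 randomized strings.
Dual-route checks back every nontrivial numeric: the window scanner against
a character-walk oracle, Wilson bounds against an independent closed-form
evaluation, Spearman against brute-force average ranks, yield counts
against direct set arithmetic.

Tie-breaks are all deterministic: first valid mention per note, earliest
`note_datetime` then smallest `note_id` in `first_per_patient()`,
left-closed right-open bins with a closed last bin and an explicit overflow
tally in `distribution_summary()`. In `merge_yield()` the percent increase
is reported against the combined total (added / total), not the structured
baseline — the convention under which "24%" style figures are quoted for
this kind of yield analysis; both counts are returned so either reading can
be reconstructed.

## Known limitations

* `FEV 1.85` is ambiguous under the space variant: the mention consumes
  `FEV 1` and the scan then reads `85`. Drop `"FEV 1"` from
  `pattern_variants` if such transcriptions dominate a corpus.
* The first-value rule has no notion of measurement recency; in
  multi-mention notes the chosen value may be a prior study's
  (`multi_mention` flags them).
* Unit attribution for bare numbers is a guess recorded as such; a corpus
  reporting liters above 8.0 (none known) or percent below 10 would be
  misread.
* The ratio guard only inspects text between mention and token; a ratio
  written before the mention (`ratio FEV1/FVC was low, FEV1 1.2`) is
  handled by mention order, not by the guard itself.
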