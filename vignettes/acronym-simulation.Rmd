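---
title: "Simulating and annotating global acronym usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and annotating global acronym usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrosim)
```

## The problem

Clinical narratives use acronyms *globally*: "MRS" appears with no
definition in sight, and may mean magnetic resonance spectroscopy,
Melkersson-Rosenthal syndrome, or something else entirely. Supervised
word sense disambiguation (WSD) can resolve such ambiguity, but needs
large labelled training sets, and clinical text cannot be crowd-annotated
because of patient privacy.

Scientific abstracts offer a way out. Scientific writing convention
requires an acronym to be defined at first mention as
`long form (SHORTFORM)`. When we can recognize that definition, the
document itself tells us what its acronym means. acrosim exploits this in
three steps:

1. **Extraction** — recognize `long form (SF)` definitions by
   parenthetical pattern matching plus heuristic character alignment.
2. **Simulation** — per document and acronym, flip a fair coin and rewrite
   the text to use *either* the acronym *or* the full form consistently.
   Wherever a full form is removed, it is retained as the sense
   annotation. This emulates the global usage style of clinical text
   while keeping gold labels for free.
3. **Dataset construction** — turn annotated occurrences of *ambiguous*
   acronyms into sentence-level binary verification samples and evaluate
   a most-frequent-sense (MFS) baseline.

A synthetic-corpus generator with exact ground truth makes all of this
testable offline, without network access to any bibliographic or
terminology service.

## Definition extraction

A candidate short form is the content of an innermost balanced pair of
parentheses, accepted when it has 2–10 characters, at most two
whitespace-delimited words, at least one letter and an alphanumeric first
character. When the content fails these rules (e.g. it is itself a long
phrase) but the token immediately before the parenthesis passes them, the
reversed pattern `SF (long form)` is assumed instead. An unbalanced
opening parenthesis stops the candidate search from that point.

The long form is found by scanning the short form right to left against a
window of up to `min(|SF| + 5, 2|SF|)` words before the parenthesis
(`|SF|` counts characters). Each alphanumeric character of the short form
must match a window character in order; matching is case-insensitive,
digits match literally, and hyphens or periods in the short form are
skipped. The result is the **shortest** suffix of the window that
supports such a matching and whose first word begins with the short
form's first character:

```{r extraction}
best_long_form("DM2", "patients with diabetes mellitus type 2")
best_long_form("IL-6", "serum levels of interleukin 6")
best_long_form("XYZ", "alpha beta gamma")

d <- acro_document("ex1", "Melkersson-Rosenthal syndrome (MRS) was suspected.")
extract_definitions(d)[, 1:5]
```

Word boundaries are whitespace-only throughout: a hyphenated token such
as `Melkersson-Rosenthal` is one word, so a short form may align into its
interior but a suffix can only start at its head. All spans in the
package are 0-based, half-open, and count Unicode code points.

The implementation uses a greedy right-to-left scan (each short-form
character takes the rightmost available match, with a word-start
constraint on the first character). For this matching relation, the
greedy anchor coincides with the brute-force minimum over all word
suffixes; the test suite verifies that equivalence against an independent
enumeration oracle on 10,000 fuzz-generated pairs.

## Sense inventory

Long forms are normalized (lowercase, collapsed whitespace, trailing
sentence punctuation stripped, hyphens kept) and grouped into senses.
Two surfaces fall into one sense when their normalized forms are equal or
when a supplied concept map sends both to the same concept identifier —
the offline stand-in for a terminology-service lookup such as a UMLS CUI
query. Numeral variants ("type 2" vs "type II") are deliberately *not*
merged by normalization; only the concept map can unify them:

```{r inventory}
mentions <- data.frame(
  doc_id = c("a", "b", "c"), short_form = "DM2",
  long_form = c("diabetes mellitus type 2", "diabetes mellitus type II",
                "type two diabetes mellitus"))
cm <- concept_map(mentions$long_form, rep("C0011860", 3))
inv <- build_inventory(mentions, cm)
length(inv[["DM2"]])          # one unified sense
ambiguous_acronyms(inv)       # DM2 is therefore not ambiguous
```

A long form with no concept-map hit is kept as its own sense rather than
discarded, so corpora without any concept map still produce a usable
inventory. Sense ids are the concept identifier when available, else a
stable hash of the acronym and normalized canonical form, making
inventory construction independent of iteration order. The canonical
surface of a sense is its most frequent variant, ties broken
lexicographically.

## Simulation

The style decision is drawn independently per (document, acronym) pair
with probability 0.5. The wording "choose between an acronym and its full
form" is ambiguous when a document defines several acronyms; the
per-acronym reading maximizes variety in the produced dataset, and a
per-document reading is recoverable by filtering.

Rewriting collapses each defining expression to the chosen surface (the
parenthetical is not deleted outright, preserving sentence grammar) and
replaces every other occurrence of the non-chosen surface document-wide.
Replacement matching is case-insensitive, token-boundary and
exact-surface over the known variants of the document's sense; inflected
forms are not touched, which avoids corrupting text at the cost of
missing morphological variants. Replacements are applied in one
left-to-right splice over non-overlapping intervals, and annotation spans
are recomputed against the transformed body:

```{r simulate}
corpus <- acro_corpus(list(acro_document("m1", paste0(
  "Magnetic resonance spectroscopy (MRS) was performed. ",
  "Magnetic resonance spectroscopy showed changes."))))
sim <- simulate_corpus(corpus, seed = 7)
sim$documents[[1]]$body
sim$documents[[1]]$annotations
```

Under acronym style every resulting acronym occurrence is annotated with
the document's single sense — the in-document form of the one-sense-per-
discourse assumption, which holds by construction here. Titles are never
transformed; the abstract body is the only coordinate system.

## Dataset construction and the MFS baseline

Sentences are segmented by a deliberately simple rule — split at `.`,
`!`, `?` followed by whitespace and an uppercase letter or digit, with a
guard for single-letter initials and a small abbreviation list ("e.g",
"i.e", "vs", "Fig", "et al"). Each annotated occurrence of an ambiguous
acronym yields one positive sample (sentence, acronym, canonical long
form of the true sense) and `min(k_neg, n_senses - 1)` negatives with
distinct incorrect senses drawn uniformly; `k_neg` defaults to 1, giving
exactly balanced labels. Non-ambiguous acronyms are discarded entirely.

Per acronym with `n` samples, `1000` (when `n >= 10000`, else
`floor(0.10 n)`) samples are reserved for validation *and* the same
number again for test, drawn without replacement before pooling; the
remainder trains. The MFS baseline predicts positive exactly when the
candidate sense is the acronym's most frequent training sense (ties
lexicographic, unseen acronyms negative), and is scored with accuracy,
precision, recall and F1 on the positive class; zero-denominator ratios
are reported as 0 with a warning.

## The synthetic corpus

The generator emulates only what the pipeline consumes: definition-first
mention structure, repeated mentions alternating randomly between long
and short form, filler sentences, and controlled document-level sense
frequencies. It makes no attempt at realistic biomedical language — the
pipeline under test is surface-pattern based, so passing tests show that
the mechanics (recognition, rewriting, span bookkeeping, splitting,
scoring) are exact, *not* that extraction would reach precision 1.0 on
real abstracts, where elliptic definitions, inflections and stray
parentheticals occur.

Defaults, chosen once as the package's study conditions: 2000 documents,
26 acronym specs (19 ambiguous with dominant-sense probabilities between
0.5 and 0.8, digit- and hyphen-bearing short forms included), 1–3
acronyms per document, 2–5 subsequent mentions per acronym, and a filler
vocabulary screened against collisions with any short form or planted
long form. Configuration is validated up front: a pair whose long form
is not *exactly* recoverable by the alignment (e.g. `("XY",
"alpha beta")`) is rejected naming the pair, which keeps the closed-loop
ground truth exact by construction.

```{r synth}
cfg <- synth_config(n_docs = 50, seed = 42)
res <- generate_corpus(cfg)
closed_loop_check(res$corpus, res$ground_truth)
```

One sense is drawn per (document, acronym), so within a document all
occurrences share a sense. This has a statistical consequence worth
stating: in the generated WSD dataset, the positive and negative sample
of one occurrence — and all occurrences of one document — succeed or fail
together under the MFS baseline. The independent unit of randomness is
the per-document sense draw, and the test suite's baseline-recovery check
therefore computes its binomial standard error over documents, not over
samples, against an expectation obtained by exact enumeration of the
outcome space.

## Numerical and design choices

- **Spans**: 0-based half-open code-point offsets everywhere; JSON bundle
  keys are lowercase snake-case. Identical inputs and seeds produce
  byte-identical bundles (no timestamps are written).
- **Seeds**: every random stage (`generate_corpus()`,
  `simulate_corpus()`, `build_wsd_dataset()`) takes an explicit integer
  seed and restores the caller's RNG state afterwards.
- **Whitespace-only documents** are retained (and flagged) rather than
  dropped, so corpus problems stay visible; they contribute nothing
  downstream.
- **Same short form defined twice** in one document: both mentions are
  collapsed, but annotations carry the first definition's sense, keeping
  the one-sense-per-document invariant assertable.
- **Overlapping definition mentions**: the earlier mention wins; the
  later is dropped with a warning.
- **Unparseable reservations** cannot occur: `floor(0.10 n)` twice never
  exceeds `n`, and the 1000-each branch requires `n >= 10000`.

Problem sizes used by the tests and the acceptance script — 2000
documents for the closed loop and residual scans, 10,000 fuzz pairs for
the alignment oracle, 3600 single-acronym documents (≥ 10,000 samples)
for the baseline recovery — are the package's chosen study conditions.

## Known limitations

- Extraction is the parenthetical convention only: acronyms never defined
  in-document are out of scope, as are statistical definition detectors.
- Replacement is exact-surface; morphological variants of a long form
  survive rewriting and would surface as residuals on real text.
- The sentence splitter is rule-based and English-oriented.
- The concept map is a static file; concept-identifier versioning and
  live terminology lookups are out of scope.
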