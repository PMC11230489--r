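---
title: "LLM weak supervision for clinical NER: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LLM weak supervision for clinical NER: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weakner)
```

## The problem and the approach

Supervised clinical named-entity recognition (NER) needs large gold-annotated
corpora, which are expensive to produce and hard to share. `weakner`
implements a knowledge-free weak-supervision pipeline around a generative
labeler (a large language model): the LLM is prompted, sentence by sentence,
to emit entity mentions as JSON; a strict four-step post-processor turns the
generated JSON into character-span *weak* labels; a compact sequence tagger
(in production, an encoder model such as a clinical BERT) is first fine-tuned
on the weak labels of the many unannotated notes and then fine-tuned on a
small, representatively chosen set of gold notes. The product is a small
deployable tagger, not the LLM.

The package is the desk-scale implementation of that pipeline: every stage is
a tested, pluggable function, and the generation step is served by replay,
oracle, or corruptor backends so the whole system runs and is validated
without model weights or protected clinical data. An adapter to a real local
LLM only has to honor the one-method contract `backend_generate(backend,
prompt, sentence_id) -> text`.

## Data model

Offsets everywhere are 0-based, half-open, in Unicode code points — the BRAT
standoff convention — and every entity must satisfy
`substr(text, start + 1, end) == surface` exactly, case-sensitively. That
invariant is enforced after every operation; it is what makes weak labels
directly usable as training spans.

Sentences are the unit of processing (generative labelers have bounded
context windows). The default segmenter is rule-based (sentence-final
punctuation followed by whitespace, and newlines); any segmenter returning
boundary offsets can be injected. A gold entity crossing a proposed sentence
boundary forces a merge of the adjacent sentences rather than a truncation:
we prefer conservative segmentation to losing gold spans. This repair rule is
a package design choice; boundary handling in sentence segmenters is
generally unspecified in evaluation protocols.

BIO encoding is single-layer, so overlapping gold entities cannot be
represented: the longer span wins and the shorter is dropped and logged
(deterministic and recall-oriented for the dominant span). An entity boundary
strictly inside a token is snapped outward to token boundaries and flagged.
An orphan `I-X` tag decodes as a fresh entity, so any tag sequence decodes.

## Prompts and SFT records

The prompt has exactly four sections in fixed order: system prompt,
instruction, few-shot examples, input placeholder. The default special-token
dialect is `[INST]`/`[/INST]`; the rendered prompt ends at the final
`[/INST]` so generation continues after it. Few-shot examples (default
`k = 8`) are sampled uniformly without replacement from all training
sentences, entity-free ones included — no stratification, because none is
assumed by the protocol.

Label JSON is canonical: an array of `{"text": ..., "type": ...}` objects in
that key order, entities sorted by start offset, no whitespace variance.
Supervised fine-tuning (SFT) records are `prompt + " " + label_json`, the
completion appended directly after the final `[/INST]`; splitting a record at
that token recovers the completion exactly. The exported SFT manifest carries
the training defaults: cosine schedule, initial learning rate `2e-5`, weight
decay `0.1`, sequence length `4096`, `2` epochs, batch size `1`. Over-length
records shed whole few-shot examples from the left of the few-shot block;
the completion is never truncated (that would teach the model to emit
malformed JSON).

Generation settings default to `top_k = 1` (greedy decoding, for
reproducibility) and `max_new_tokens = 128` (labels are short; the cap bounds
cost).

## Post-processing: four steps, strict on purpose

1. **Generated-text extraction.** Take everything after the *last*
   `[/INST]` (few-shot blocks contain earlier ones); truncate at any newly
   generated `[INST]`.
2. **JSON formatting.** Apply the non-greedy brace pattern `\{.*?\}` and
   parse each match independently; one malformed object cannot poison the
   rest. Keys are strictly `"text"` and `"type"` — no aliases. A generation
   with zero parseable objects and no `[]` token marks the sentence *failed*;
   a bare `[]` is a success with zero entities (format failures, not empty
   answers, are what the failure statistic measures).
3. **Entity recovery.** Exact, case-sensitive string matching of each
   record's text in the input sentence. Records are consumed in generation
   order, each taking the leftmost occurrence not covered by a previously
   recovered entity, so repeated mentions are consumed left to right; one
   record yields at most one entity. A record with no free occurrence drops
   as `duplicate` (if an identical text/type was already recovered) or
   `text_not_found`.
4. **Type filtering.** Keep only labels exactly matching a schema type;
   everything else drops as `off_schema_type`. Idempotent.

No trimming, lowercasing, or fuzzy matching anywhere: strictness keeps the
pipeline automatic and bias-free, and the SFT stage teaches the canon. Every
parsed record is accounted for — recovered or dropped with a reason — and the
per-corpus report mirrors the summary a practitioner checks before training:
totals, per-sentence and per-note median [Q1, Q3], percent failed sentences.

A sentence whose backend call errored is counted as failed with no drop
records: a failed generation yields no JSON, so it lands in the same bucket
as free-text output.

## Gold-note selection and two-stage training

With an annotation budget of `n_s` notes (typically 3, 5, 10, or 50), the
selected notes should be representative. Notes are ranked by
`|entity_count - median(entity_counts)|`; the `n_s` closest are selected.
The median of an even count is the mean of the middle two; ties break by
ascending note id. Because the objective is separable, the greedy rank
selection equals the exhaustive subset minimizer — the test suite checks this
against brute-force enumeration.

Training is two-stage: stage 1 fits the tagger on BIO-encoded weak labels of
the `N - n_s` weak notes; stage 2 continues *from the stage-1 state* (no
re-initialization — "followed by fine-tuning" means warm-started) on the gold
labels of the `n_s` notes. Each stage splits by sentence 80/20 into
train/validation with a fixed seed (sentence-level splitting maximizes
validation coverage when `n_s` is tiny); after each epoch the strict micro F1
on the validation split is recorded, the best checkpoint is kept, and
training halts after 8 continuous non-improving epochs. A flat validation
curve therefore stops after exactly 9 epochs.

Two reference taggers ship with the package: a dictionary memorizer (exact
sentence-to-tags lookup, the test oracle) and a lightweight token-frequency
tagger (per-token tag counts, argmax prediction with BIO-grammar repair, ties
by tag name). The frequency tagger is deliberately simple — majority voting
per surface form — which is exactly the property the weak-supervision
experiments need: robustness to moderate label noise through redundancy.
Real encoder models slot in behind the same four-method contract
(`tagger_fit_epoch`, `tagger_predict`, `tagger_state`, `tagger_restore`).

## Evaluation

Entity-level micro precision/recall/F1, with two matching modes: **strict**
(identical start, end, and label) and **lenient**/relaxed (same label, at
least one character of overlap). Matching is one-to-one greedy: candidate
pairs sorted by (overlap descending, gold start, pred start), each entity
used at most once — the behavior of the standard clinical-benchmark scorers,
with the tie order made explicit. TP/FP/FN are pooled over notes and types
before computing P, R, and F1 (micro), and 0/0 is 0. Strict matches are a
subset of lenient matches, so strict F1 never exceeds lenient F1; the suite
property-tests this and the exact P/R swap under exchanging gold and
predictions.

## Compute budgeting

The closed-form cost of labeling one sentence with a decoder-only transformer
is

$$\mathrm{FLOPs} = n_{tokens\,out}\,(2N + 2\,n_{layer}\,n_{ctx}\,d_{attn}),$$

with `N` total parameters and `n_ctx` estimated from the rendered prompt
template's token count (`estimate_n_ctx()`). For a 13B-parameter, 40-layer
model with a 400-token prompt, 4096-dimensional attention output and a
128-token cap, this is exactly 3,348,838,481,920 FLOPs per sentence — the
package reports both the exact integer and a 4-significant-digit scientific
rendering that truncates rather than rounds (`"3.348e+12"`), matching how
such cost tables are printed. Total GPU time for a large collection is
projected by ordinary least squares of measured `gpu_seconds` on `n_notes`,
since inference cost is linear in the number of processed notes.

## The synthetic corpus and noise model

`generate_corpus()` emits clinical-note-shaped text: notes of 4–12 sentences,
each sentence a mix of filler words and whole-token entity phrases from
per-type vocabularies (drug-like names, dosages, frequencies). Entities per
sentence follow a zero-inflated Poisson, default `p_zero = 0.7`,
`lambda = 1.1`: per-sentence median [Q1, Q3] of 0 [0, 0] with mean about 0.5
— the sparse regime of sentence-level entity distributions in real
medication-extraction corpora, where most sentences carry nothing and a few
are dense. Everything is seeded and byte-reproducible.

The vocabularies are built so that no word or phrase in play (entity, filler,
hallucination) is a substring of any other. That property makes exact-string
span recovery collision-free, which in turn makes the oracle path *exactly*
invertible (weak labels identical to gold, strict F1 of 1.0) and the noise
audit an exact accounting identity instead of an approximate one.

`simulate_generations()` produces the raw text a real backend would (prompt
echo, payload, then a spurious new `[INST]` block, so extraction and
truncation are always exercised) with five noise channels:

* `p_format_corrupt` — replace the whole output with free text (no JSON);
  the sentence must fail. Failed-sentence fractions calibrate to this
  probability (binomial check in the suite).
* `p_drop` — omit a gold record (a recall hole in the weak labels).
* `p_type_swap` — replace the type with an off-schema name; the type filter
  removes it.
* `p_boundary_jitter` — truncate multi-token texts by one token, or extend
  single-token texts with the sentence's following characters: a surviving
  wrong-boundary label (occasionally unfindable when a neighboring extension
  covers its occurrence first).
* `p_hallucinate` — once per sentence, add a record whose text comes from a
  vocabulary disjoint from the corpus; it must drop as `text_not_found`.
  This channel is per sentence rather than per record because zero-entity
  sentences dominate the default corpus shape and a per-record channel would
  almost never fire there.

Per-record channels are mutually exclusive (drop, then swap, then jitter), so
every ledger entry maps to exactly one post-processing outcome; the suite
audits this 1:1.

For the weak-supervision benefit experiment the noise is different on
purpose: `perturb_entity_types()` applies *in-schema* type swaps directly to
the weak label tables. Off-schema swaps are filtered away — they only lose
labels — whereas in-schema swaps survive as genuinely wrong training labels,
the harder and more realistic condition for "30% label noise".

## What the synthetic experiments do and do not show

`run_ws_experiment()` (300 training notes, 60 held-out notes, `n_s = 3`, 30%
in-schema type noise) shows the expected ordering robustly: the two-stage
tagger recovers most of the corpus (held-out strict F1 near 1 with the
frequency tagger, since majority voting defeats 30% noise given enough
occurrences per surface form), while gold-only training on 3 notes is limited
by vocabulary coverage (F1 roughly 0.2–0.3). This demonstrates the pipeline's
*mechanics* — selection, assembly, two-stage continuation, early stopping,
evaluation — and the direction and rough magnitude of the weak-supervision
gain at desk scale.

It does not show performance on real clinical text: the synthetic language
has no ambiguity (a surface form has one true type), no subword effects, no
spelling variation, and LLM errors are injected independently rather than
correlated with content. Absolute F1 values here say nothing about benchmark
F1 on protected clinical corpora; only the orderings and the contracts carry
over.

## Numerical and engineering choices

* Problem sizes in the test suite (200-note oracle round-trip, roughly 2,000
  sentences for failure-rate calibration, 1,000-sentence BIO round-trip, 200
  corpora for the selection oracle, 5 seeds for the two-stage comparison) are
  chosen so the whole suite runs in a few minutes on one CPU while keeping
  the binomial and property checks well-powered.
* Quartiles use R's default `quantile()` type 7; medians are `median()`.
* The replay store keys prompts by a 32-bit FNV-1a content hash (implemented
  in the package, exact in double arithmetic), making replay robust to
  re-ordering without external digest dependencies.
* FLOPs arithmetic is done in doubles; all quantities stay far below 2^53,
  so results are exact integers.
* Seeded sampling uses R's default RNG throughout; a fixed seed fixes
  corpora, few-shot samples, noise, and splits byte-exactly.

## Known limitations

* Single-layer BIO cannot express overlapping or discontinuous entities;
  BRAT discontinuous (`;`-separated) spans are not parsed.
* The rule-based segmenter is deliberately simple; abbreviation-heavy text
  wants an injected segmenter.
* `extract_json_objects`'s non-greedy brace pattern cannot recover objects
  whose string values contain `}` — by design, mirroring the strict
  formatting contract rather than attempting repair.
* Benchmark-specific XML annotation dialects are out of scope here; BRAT
  standoff and JSONL are the supported interchange formats, and any reader
  that normalizes to `note()` objects plugs in upstream.
* Label harmonization, fuzzy matching, and prompt/template search are
  intentionally absent.
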