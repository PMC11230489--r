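# weakner

Knowledge-free weak supervision for clinical named-entity recognition (NER),
driven by a generative labeler.

## The problem

Clinical NER systems need gold-annotated notes, which are expensive to
produce, require clinical expertise, and usually cannot be shared. A large
language model can label notes automatically — but LLM inference is orders of
magnitude more expensive than running a compact encoder tagger, and its raw
text output is not training data. `weakner` implements the pipeline that
bridges the two: prompt an LLM sentence by sentence for JSON entity mentions,
post-process the generations into character-span *weak* labels with strict
accounting, train a small sequence tagger on the weak labels of the many
unannotated notes, then fine-tune it on a handful of representatively chosen
gold notes. The deployable product is the small tagger, not the LLM.

The package is aimed at clinical NLP practitioners and methods researchers:
every stage is a plain R function with a tested contract, the generation step
is pluggable (replay stores, an oracle, a calibrated noise simulator, or your
own local-model adapter), and a synthetic corpus generator makes the whole
system runnable and testable without protected clinical data.

## The method

For a training corpus of `N` notes and an annotation budget of `n_s` notes:

1. **Prompting.** A 4-section template (system prompt, instruction, `k = 8`
   few-shot sentence/JSON pairs, input placeholder) rendered per sentence in
   the `[INST]`/`[/INST]` dialect; greedy decoding (`top_k = 1`), 128-token
   output cap. SFT records for fine-tuning the labeler append the canonical
   gold label JSON after the final `[/INST]`.
2. **Post-processing** (four strict steps): extract the text after the last
   `[/INST]` (truncating any newly generated `[INST]`); parse `\{.*?\}`
   matches independently with strict `"text"`/`"type"` keys; recover spans by
   exact case-sensitive matching, leftmost uncovered occurrence first; filter
   types to the task schema. Every record is recovered or dropped with a
   reason; sentences with no parseable JSON are counted as failed.
3. **Gold-note selection.** Pick the `n_s` notes whose entity counts are
   closest to the corpus median:
   `S = argmin top-n_s |count_i − median(counts)|`, ties by note id.
4. **Two-stage training.** Fine-tune the tagger on weak labels of the
   `N − n_s` notes, then continue (no re-initialization) on gold labels of
   the `n_s` notes; 80/20 sentence-level train/validation split per stage,
   best validation checkpoint kept, early stop after 8 non-improving epochs.
5. **Evaluation.** Entity-level micro P/R/F1 with strict (exact boundaries
   and label) and lenient (label + any character overlap) matching, one-to-one
   greedy by overlap.
6. **Budgeting.** Per-sentence inference cost
   `FLOPs = n_tokens_out (2N + 2 n_layer n_ctx d_attn)` with `n_ctx`
   estimated from the rendered template, and total GPU time projected by OLS
   of timed subsamples.

## Worked example

Generate a synthetic corpus, label it with a noisy simulated backend,
post-process into weak labels, and score them against gold:

```r
library(weakner)

cfg <- synthetic_corpus_config(n_notes = 50, seed = 42)
notes <- generate_corpus(cfg)
sentences <- unlist(lapply(notes, segment_note), recursive = FALSE)
template <- default_prompt_template(cfg$schema,
                                    fewshot = sample_fewshot(sentences, 8, seed = 42))

backend <- corruptor_backend(notes, template,
                             noise_config(p_format_corrupt = 0.05,
                                          p_hallucinate = 0.1,
                                          p_type_swap = 0.1, seed = 42),
                             cfg$schema)
gens <- generate(backend, build_prompts(sentences, template))
pp <- run_postprocess(gens, sentences, cfg$schema)
pp$report
#> Weak label report
#>   Notes: 50   Sentences: 386
#>   Post-processing failed sentences: 15 (3.89%)
#>   Total entities: 125
#>   Entities per sentence, median [Q1, Q3]: 0 [0, 0]
#>   Entities per note, median [Q1, Q3]: 2 [1, 4]
```

The report is the pre-training sanity check: 5% of generations were format
corrupted and 3.89% of sentences failed post-processing (failures happen only
on corrupted sentences, and some corrupted sentences had nothing to label);
hallucinated and off-schema records were dropped, not recovered.

```r
weak <- weak_labels_to_notes(pp$results, sentences, notes)
evaluate_corpus(notes, weak, "strict")
#> Entity-level evaluation (strict matching)
#>   micro P = 1.0000  R = 0.8562  F1 = 0.9225  (TP 125, FP 0, FN 21)
#>   Frequency    P = 1.0000  R = 0.9091  F1 = 0.9524
#>   Drug         P = 1.0000  R = 0.7561  F1 = 0.8611
#>   Dosage       P = 1.0000  R = 0.8800  F1 = 0.9362
```

Precision 1.0, recall 0.856: this noise model only loses labels (format
corruption, off-schema swaps, unfindable hallucinations), it never fabricates
a findable wrong span — exactly what the drop accounting predicts.

Select 3 representative gold notes and estimate the labeling cost per
sentence for a 13B-parameter, 40-layer decoder with this template:

```r
select_gold_notes(notes, 3)
#> <gold_selection: n_s = 3, median entities = 3>
#>   selected: note0002, note0014, note0029

n_ctx <- estimate_n_ctx(template)   # 259 tokens for this rendered template
profile <- model_profile(13015864320, 40, n_ctx, 4096, 128)
flops_per_sentence(profile)         # 3342924513280
format_flops(flops_per_sentence(profile))
#> [1] "3.342e+12"
```

About 3.3 trillion FLOPs to label one sentence — the quantitative argument
for distilling the LLM's labels into a 110M-parameter tagger instead of
deploying the LLM.

The two-stage-versus-gold-only comparison is packaged as an experiment:

```r
ex <- run_ws_experiment(n_train_notes = 300, n_test_notes = 60, n_s = 3,
                        type_swap_rate = 0.3, seed = 1)
c(two_stage = ex$two_stage_f1, gold_only = ex$gold_only_f1)
#> two_stage gold_only
#>       1.0       0.2
```

A command-line front end over the same functions ships in
`inst/cli/weakner.R` (subcommands `segment`, `synth-corpus`,
`synth-generations`, `generate`, `postprocess`, `select-gold`, `evaluate`,
`flops`).

## Scope

The package deliberately does not ship model weights, GPU training loops, or
protected benchmark data. Real labelers and real encoder taggers plug in
behind two one-method contracts (`backend_generate`, and the
`tagger_fit_epoch`/`tagger_predict`/`tagger_state`/`tagger_restore` family).
See the methods vignette (`vignettes/weak-supervision-pipeline.Rmd`) for the
full design rationale and limitations.
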