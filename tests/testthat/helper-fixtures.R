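# Fixtures shared across test files. Everything is built in code.

demo_schema <- function() task_schema("demo", c("Drug", "Dosage", "Frequency"))

# A tiny hand-built note with known offsets:
# "Took aspirin daily. Gave heparin 40 mg."
#  0123456789012345678901234567890123456789
demo_note <- function() {
  note(
    "demo1",
    "Took aspirin daily. Gave heparin 40 mg.",
    entity_table(
      start = c(5L, 13L, 25L, 33L),
      end = c(12L, 18L, 32L, 38L),
      text = c("aspirin", "daily", "heparin", "40 mg"),
      label = c("Drug", "Frequency", "Drug", "Dosage")
    )
  )
}

demo_dialect <- function() {
  list(instruction_open = "[INST]", instruction_close = "[/INST]")
}

# Small corpus + sentences + template, for pipeline tests.
demo_pipeline <- function(n_notes = 10, seed = 11) {
  cfg <- synthetic_corpus_config(n_notes = n_notes, seed = seed)
  notes <- generate_corpus(cfg)
  sentences <- unlist(lapply(notes, segment_note), recursive = FALSE)
  template <- default_prompt_template(cfg$schema,
                                      fewshot = sample_fewshot(sentences, 4, seed = seed))
  list(cfg = cfg, notes = notes, sentences = sentences, template = template,
       schema = cfg$schema)
}
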