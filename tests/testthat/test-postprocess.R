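test_that("generated text is everything after the last close token", {
  d <- demo_dialect()
  expect_equal(
    extract_generation("prompt [/INST] [{\"text\":\"aspirin\",\"type\":\"Drug\"}]", d),
    " [{\"text\":\"aspirin\",\"type\":\"Drug\"}]"
  )
  # a new open token in the continuation truncates it
  expect_equal(extract_generation("prompt [/INST] [] [INST] next", d), " [] ")
  # few-shot echoes contain earlier close tokens; the last one wins
  raw <- "sys [INST] fs [/INST] [{\"text\":\"a\",\"type\":\"T\"}] [INST] in [/INST] [{\"text\":\"b\",\"type\":\"U\"}]"
  expect_equal(extract_generation(raw, d), " [{\"text\":\"b\",\"type\":\"U\"}]")
})

test_that("missing close token treats the whole string as generation, flagged", {
  out <- extract_generation("no tokens at all []", demo_dialect())
  expect_true(attr(out, "no_close"))
  expect_equal(as.character(out), "no tokens at all []")
  # continuation-only outputs skip extraction
  expect_equal(extract_generation("[] trailing", demo_dialect(), echo = FALSE),
               "[] trailing")
})

test_that("brace patterns parse independently; failures are data, not exceptions", {
  two <- extract_json_objects('[{"text":"a","type":"T"},{"text":"b","type":"U"}]')
  expect_false(two$failed)
  expect_equal(two$records$text, c("a", "b"))
  expect_equal(two$records$type, c("T", "U"))

  none <- extract_json_objects("Sure! here are none.")
  expect_true(none$failed)

  # a bare empty list is a success with zero entities, not a failure
  empty <- extract_json_objects(" [] ")
  expect_false(empty$failed)
  expect_equal(nrow(empty$records), 0L)

  # the non-greedy pattern stops at the first closing brace, so a brace inside
  # a string truncates the object and the fragment drops as bad_object
  nested <- extract_json_objects('[{"text":"x}y","type":"T"},{"text":"ok","type":"T"}]')
  expect_equal(nested$records$text, "ok")
  expect_equal(nested$drops$reason, "bad_object")

  # strict keys: aliases are not accepted
  alias <- extract_json_objects('[{"entity":"a","label":"T"}]')
  expect_equal(nrow(alias$records), 0L)
  expect_equal(alias$drops$reason, "bad_object")
  expect_true(alias$failed) # zero parsed objects and no [] token
})

test_that("span recovery is leftmost-uncovered, exact, and case-sensitive", {
  sent <- "gave aspirin and aspirin again"
  recs <- data.frame(text = c("aspirin", "aspirin"), type = c("Drug", "Drug"))
  out <- recover_spans(recs, sent)
  expect_equal(out$entities$start, c(5L, 17L))
  expect_equal(out$entities$end, c(12L, 24L))
  expect_equal(nrow(out$drops), 0L)

  # case mismatch is not found
  out <- recover_spans(data.frame(text = "Aspirin", type = "Drug"), "gave aspirin")
  expect_equal(nrow(out$entities), 0L)
  expect_equal(out$drops$reason, "text_not_found")

  # a third repeat of an exhausted mention is a duplicate
  out <- recover_spans(data.frame(text = c("aspirin", "aspirin"),
                                  type = c("Drug", "Drug")), "gave aspirin")
  expect_equal(nrow(out$entities), 1L)
  expect_equal(out$drops$reason, "duplicate")

  # record text equal to the whole sentence spans it entirely
  out <- recover_spans(data.frame(text = sent, type = "T"), sent)
  expect_equal(c(out$entities$start, out$entities$end), c(0L, nchar(sent)))

  # every recovered span satisfies exact substring equality
  expect_equal(substr(sent, 18, 24), "aspirin")
})

test_that("type filtering keeps exact schema matches only and is idempotent", {
  schema <- task_schema("t", "Drug")
  ents <- entity_table(c(0L, 5L, 10L, 15L, 20L),
                       c(1L, 6L, 11L, 16L, 21L),
                       c("a", "b", "c", "d", "e"),
                       c("Drug", "Medication", "Drug", "drug", "Drug"))
  out <- filter_types(ents, schema)
  expect_equal(nrow(out$entities), 3L)
  expect_equal(nrow(out$drops), 2L)
  expect_true(all(out$drops$reason == "off_schema_type"))
  again <- filter_types(out$entities, schema)
  expect_equal(again$entities, out$entities)
  expect_equal(nrow(again$drops), 0L)
})

test_that("all-garbage generations fail every sentence with zero entities", {
  pl <- demo_pipeline(n_notes = 3, seed = 53)
  prompts <- build_prompts(pl$sentences, pl$template)
  recs <- generate(static_backend("no structure whatsoever"), prompts)
  pp <- run_postprocess(recs, pl$sentences, pl$schema)
  expect_equal(pp$report$failed_sentences, pp$report$n_sentences)
  expect_equal(pp$report$total_entities, 0L)
  expect_true(all(vapply(pp$results, function(r) nrow(r$entities) == 0L, logical(1))))
})

test_that("accounting conserves: parsed records = recovered + dropped, per sentence", {
  pl <- demo_pipeline(n_notes = 15, seed = 59)
  nz <- noise_config(p_format_corrupt = 0.15, p_hallucinate = 0.3,
                     p_type_swap = 0.2, p_drop = 0.1, p_boundary_jitter = 0.15,
                     seed = 61)
  bk <- corruptor_backend(pl$notes, pl$template, nz, pl$schema)
  pp <- run_postprocess(generate(bk, build_prompts(pl$sentences, pl$template)),
                        pl$sentences, pl$schema)
  for (r in pp$results) {
    non_parse_drops <- sum(r$drop_log$reason != "bad_object")
    expect_equal(r$n_parsed, nrow(r$entities) + non_parse_drops)
  }
})

test_that("cardinality mismatches between generations and sentences error", {
  pl <- demo_pipeline(n_notes = 2, seed = 67)
  prompts <- build_prompts(pl$sentences, pl$template)
  recs <- generate(static_backend(), prompts)
  expect_error(run_postprocess(recs[-1], pl$sentences, pl$schema), "1:1")
})

test_that("the weak label report aggregates counts and quartiles", {
  # three single-sentence notes with 0, 1, 3 entities: per-sentence median 1
  mk <- function(id, n_ent) {
    toks <- c("veltrazine", "morbexol", "zaltorex")
    txt <- paste0("gave ", paste(toks[seq_len(max(1, n_ent))], collapse = " and "), ".")
    ents <- entity_table()
    if (n_ent > 0) {
      for (t in toks[seq_len(n_ent)]) {
        at <- find_all_fixed_pos(txt, t)
        ents <- rbind(ents, entity_table(at, at + nchar(t), t, "Drug"))
      }
    }
    note(id, txt, ents)
  }
  # helper: first occurrence offset
  find_all_fixed_pos <- function(x, pat) {
    as.integer(regexpr(pat, x, fixed = TRUE)) - 1L
  }
  notes <- list(mk("a", 0), mk("b", 1), mk("c", 3))
  sents <- unlist(lapply(notes, segment_note), recursive = FALSE)
  tpl <- default_prompt_template(demo_schema())
  pp <- run_postprocess(generate(oracle_backend(sents), build_prompts(sents, tpl)),
                        sents, demo_schema())
  expect_equal(pp$report$n_notes, 3L)
  expect_equal(pp$report$n_sentences, 3L)
  expect_equal(pp$report$total_entities, 4L)
  expect_equal(unname(pp$report$entities_per_sentence["median"]), 1)
  expect_equal(pp$report$failed_sentences, 0L)
})
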