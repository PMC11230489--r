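test_that("corpora are byte-identical under a fixed seed", {
  cfg <- synthetic_corpus_config(n_notes = 10, seed = 313)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  c <- generate_corpus(synthetic_corpus_config(n_notes = 10, seed = 314))
  expect_false(identical(a, c))
})

test_that("a forced single-entity note satisfies every corpus invariant", {
  cfg <- synthetic_corpus_config(
    n_notes = 1, sentences_per_note = c(1L, 1L), min_entities = 1L,
    p_zero = 1, schema = task_schema("drugs", "Drug"), seed = 3
  )
  n <- generate_corpus(cfg)[[1]]
  expect_gte(nrow(n$entities), 1L)
  expect_silent(validate_entities(n$entities, n$text))
})

test_that("generated entities sit on token boundaries and inside one sentence", {
  notes <- generate_corpus(synthetic_corpus_config(n_notes = 25, seed = 317))
  for (n in notes) {
    toks <- default_tokenizer(n$text)
    for (i in seq_len(nrow(n$entities))) {
      e <- n$entities[i, ]
      expect_true(e$start %in% toks$start)
      expect_true(e$end %in% toks$end)
    }
    # segmentation never needs a merge repair: entities fit inside sentences
    sents <- segment_note(n)
    for (s in sents) {
      expect_true(all(s$entities$end <= nchar(s$text)))
    }
  }
})

test_that("the zero-inflated entity distribution has median 0 at Table-2-like settings", {
  notes <- generate_corpus(synthetic_corpus_config(
    n_notes = 150, sentences_per_note = c(8L, 10L), p_zero = 0.7, lambda = 1.1,
    seed = 331
  ))
  counts <- unlist(lapply(notes, function(n) {
    vapply(segment_note(n), function(s) nrow(s$entities), integer(1))
  }))
  expect_gt(length(counts), 1000)
  expect_equal(median(counts), 0)
  expect_lt(mean(counts), 1)
})

test_that("empty vocabularies for a requested type are rejected", {
  expect_error(
    synthetic_corpus_config(schema = task_schema("t", c("Drug", "Gene")),
                            vocab = list(Drug = "aspirin", Gene = character(0))),
    "empty vocabulary"
  )
  expect_error(
    synthetic_corpus_config(schema = task_schema("t", "Gene")),
    "no vocabulary"
  )
})

test_that("zero noise reproduces gold exactly; full format corruption fails everything", {
  pl <- demo_pipeline(n_notes = 6, seed = 337)
  sim <- simulate_generations(pl$notes, pl$template, noise_config(seed = 1), pl$schema)
  pp <- run_postprocess(sim$records, sim$sentences, pl$schema)
  expect_equal(pp$report$failed_sentences, 0L)
  weak <- weak_labels_to_notes(pp$results, sim$sentences, pl$notes)
  expect_equal(micro_f1(pl$notes, weak, "strict"), 1)
  expect_equal(nrow(sim$ledger), 0L)

  all_bad <- simulate_generations(pl$notes, pl$template,
                                  noise_config(p_format_corrupt = 1, seed = 2),
                                  pl$schema)
  pp2 <- run_postprocess(all_bad$records, all_bad$sentences, pl$schema)
  expect_equal(pp2$report$failed_sentences, pp2$report$n_sentences)
  expect_equal(pp2$report$total_entities, 0L)
})

test_that("hallucinated records are dropped as text_not_found, one per injection", {
  pl <- demo_pipeline(n_notes = 40, seed = 347)
  nz <- noise_config(p_hallucinate = 0.5, seed = 349)
  sim <- simulate_generations(pl$notes, pl$template, nz, pl$schema)
  pp <- run_postprocess(sim$records, sim$sentences, pl$schema)
  drops <- do.call(rbind, lapply(pp$results, function(r) r$drop_log))
  n_halluc <- sum(sim$ledger$channel == "hallucinate")
  expect_gt(n_halluc, 50)
  expect_equal(sum(drops$reason == "text_not_found"), n_halluc)
  expect_equal(pp$report$failed_sentences, 0L)
})

test_that("every injected mutation is explained by a drop or a surviving wrong label", {
  pl <- demo_pipeline(n_notes = 30, seed = 353)
  nz <- noise_config(p_format_corrupt = 0.1, p_hallucinate = 0.2,
                     p_type_swap = 0.2, p_drop = 0.15, p_boundary_jitter = 0.2,
                     seed = 359)
  sim <- simulate_generations(pl$notes, pl$template, nz, pl$schema)
  pp <- run_postprocess(sim$records, sim$sentences, pl$schema)
  results <- stats::setNames(pp$results,
                             vapply(pp$results, `[[`, character(1), "sentence_id"))
  gold <- stats::setNames(sim$sentences,
                          vapply(sim$sentences, `[[`, character(1), "sentence_id"))
  for (i in seq_len(nrow(sim$ledger))) {
    row <- sim$ledger[i, ]
    r <- results[[row$sentence_id]]
    explained <- switch(
      row$channel,
      format_corrupt = r$failed,
      # usually an off_schema_type drop; a neighboring jitter extension can
      # cover the occurrence first, turning it into text_not_found
      type_swap = any(r$drop_log$text == row$text),
      drop = !any(r$entities$text == row$text & r$entities$label == row$type) ||
        # the same surface may legitimately survive via another gold record
        sum(gold[[row$sentence_id]]$entities$text == row$text) >
          sum(r$entities$text == row$text),
      hallucinate = any(r$drop_log$reason == "text_not_found" &
                          r$drop_log$text == row$text),
      boundary_jitter =
        any(r$drop_log$text == row$text) ||          # jittered text unrecoverable
        any(r$entities$text == row$text),            # survived with wrong span
      FALSE
    )
    expect_true(explained, info = paste(row$channel, row$sentence_id, row$text))
  }
})

test_that("failed-sentence fraction calibrates to the corruption probability", {
  pl <- demo_pipeline(n_notes = 120, seed = 367)
  nz <- noise_config(p_format_corrupt = 0.1, seed = 373)
  sim <- simulate_generations(pl$notes, pl$template, nz, pl$schema)
  pp <- run_postprocess(sim$records, sim$sentences, pl$schema)
  n <- pp$report$n_sentences
  frac <- pp$report$failed_sentences / n
  sigma <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * sigma)
})
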