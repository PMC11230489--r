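mk_counted_note <- function(id, k) {
  # a single-sentence note with exactly k Drug entities
  voc <- synthetic_vocab_for_tests()
  words <- rep(voc, length.out = max(1, k))
  txt <- paste0("gave ", paste(words, collapse = " then "), ".")
  ents <- entity_table()
  covered_to <- 0L
  for (w in words[seq_len(k)]) {
    rel <- regexpr(w, substring(txt, covered_to + 1L), fixed = TRUE)
    at <- covered_to + as.integer(rel) - 1L
    ents <- rbind(ents, entity_table(at, at + nchar(w), w, "Drug"))
    covered_to <- at + nchar(w)
  }
  note(id, txt, as_entity_table_for_tests(ents))
}

synthetic_vocab_for_tests <- function() {
  c("veltrazine", "morbexol", "quandipril", "zaltorex", "fexuprame",
    "dormicaine", "relpaxor", "tubrafen")
}

as_entity_table_for_tests <- function(e) {
  entity_table(e$start, e$end, e$text, e$label)
}

test_that("gold-note selection minimizes distance to the median entity count", {
  counts <- c(a = 2, b = 5, c = 7, d = 9, e = 100)
  notes <- lapply(names(counts), function(id) mk_counted_note(id, counts[[id]]))
  sel1 <- select_gold_notes(notes, 1)
  expect_equal(sel1$median_entities, 7)
  expect_equal(sel1$selected_ids, "c")
  sel3 <- select_gold_notes(notes, 3)
  expect_setequal(sel3$selected_ids, c("b", "c", "d"))
  expect_error(select_gold_notes(notes, 6), "exceeds")
})

test_that("equal counts fall back to ascending note id", {
  notes <- lapply(c("n2", "n1", "n3"), function(id) mk_counted_note(id, 4))
  sel <- select_gold_notes(notes, 2)
  expect_equal(sel$selected_ids, c("n1", "n2"))
})

test_that("selection equals brute-force subset minimization on random corpora", {
  set.seed(71)
  for (rep in 1:40) {
    N <- sample(4:12, 1)
    counts <- sample(0:30, N, replace = TRUE)
    notes <- lapply(seq_len(N), function(i) mk_counted_note(sprintf("n%02d", i), counts[i]))
    n_s <- sample(1:min(4, N), 1)
    sel <- select_gold_notes(notes, n_s)
    med <- median(counts)
    best <- min(apply(utils::combn(N, n_s), 2, function(idx) sum(abs(counts[idx] - med))))
    expect_equal(sum(abs(counts[match(sel$selected_ids,
                                      sprintf("n%02d", seq_len(N)))] - med)), best)
  }
})

test_that("weak/gold stages partition the corpus and split 80/20 by sentence", {
  pl <- demo_pipeline(n_notes = 5, seed = 73)
  sel <- select_gold_notes(pl$notes, 2)
  spec <- ws_dataset_spec(pl$notes, sel)
  expect_length(spec$weak_note_ids, 3L)
  expect_length(spec$gold_note_ids, 2L)
  expect_length(intersect(spec$weak_note_ids, spec$gold_note_ids), 0L)
  expect_setequal(c(spec$weak_note_ids, spec$gold_note_ids),
                  vapply(pl$notes, `[[`, character(1), "note_id"))

  ds <- assemble_ws_dataset(spec, pl$notes, pl$notes, seed = 5)
  ids_of <- function(seqs) unique(sub(":\\d+$", "", vapply(seqs, `[[`, character(1),
                                                           "sentence_id")))
  expect_setequal(ids_of(c(ds$stage1$train, ds$stage1$val)), spec$weak_note_ids)
  expect_setequal(ids_of(c(ds$stage2$train, ds$stage2$val)), spec$gold_note_ids)
  for (st in list(ds$stage1, ds$stage2)) {
    n <- length(st$train) + length(st$val)
    expect_lte(abs(length(st$train) - 0.8 * n), 1)
    # every sentence lands in exactly one pool
    expect_length(intersect(vapply(st$train, `[[`, character(1), "sentence_id"),
                            vapply(st$val, `[[`, character(1), "sentence_id")), 0L)
  }
})

test_that("missing weak labels for a weak note error with the ids", {
  pl <- demo_pipeline(n_notes = 4, seed = 79)
  spec <- ws_dataset_spec(pl$notes, select_gold_notes(pl$notes, 1))
  dropped <- spec$weak_note_ids[1]
  weak <- pl$notes[vapply(pl$notes, `[[`, character(1), "note_id") != dropped]
  expect_error(assemble_ws_dataset(spec, weak, pl$notes, seed = 1), dropped)
})

test_that("the memorizing tagger reproduces a memorizable corpus exactly", {
  pl <- demo_pipeline(n_notes = 6, seed = 83)
  seqs <- lapply(pl$sentences, entities_to_bio)
  tg <- tagger_fit_epoch(dict_tagger(), seqs)
  preds <- tagger_predict(tg, seqs)
  for (i in seq_along(seqs)) {
    expect_equal(as.data.frame(preds[[i]]), as.data.frame(bio_to_entities(seqs[[i]])))
  }
})

test_that("oracle weak labels give held-out F1 = 1 with the memorizing tagger", {
  # memorizable held-out set: test sentences also occur in training (the
  # synthetic vocabulary is small, so duplicate sentences exist) — here we
  # simply evaluate on the training notes themselves
  pl <- demo_pipeline(n_notes = 6, seed = 89)
  spec <- ws_dataset_spec(pl$notes, select_gold_notes(pl$notes, 2))
  ds <- assemble_ws_dataset(spec, pl$notes, pl$notes, seed = 2)
  fit <- train_two_stage(dict_tagger(),
                         list(train = c(ds$stage1$train, ds$stage1$val), val = list()),
                         list(train = c(ds$stage2$train, ds$stage2$val), val = list()))
  preds <- predict_notes(fit$tagger, pl$notes)
  expect_equal(micro_f1(pl$notes, preds, "strict"), 1)
})

test_that("training halts after patience+1 epochs when validation is flat", {
  pl <- demo_pipeline(n_notes = 4, seed = 97)
  seqs <- lapply(pl$sentences, entities_to_bio)
  stage <- list(train = seqs, val = seqs)
  fit <- train_two_stage(freq_tagger(), stage,
                         list(train = list(), val = list()),
                         train_config(patience = 8))
  # the count tagger's validation score is constant across epochs, so the
  # best epoch is the first and training stops after exactly 1 + 8 epochs
  expect_equal(nrow(fit$history), 9L)
  expect_equal(max(fit$history$epoch), 9L)
  expect_equal(length(unique(fit$history$val_f1)), 1L)
  expect_true("empty_stage2" %in% fit$flags)
})

test_that("stage 2 continues from stage-1 state rather than re-initializing", {
  pl <- demo_pipeline(n_notes = 8, seed = 101)
  spec <- ws_dataset_spec(pl$notes, select_gold_notes(pl$notes, 2))
  ds <- assemble_ws_dataset(spec, pl$notes, pl$notes, seed = 3)
  fit <- train_two_stage(freq_tagger(), ds$stage1, ds$stage2)
  # tokens seen only in stage-1 notes are still known after stage 2
  stage1_tokens <- unique(unlist(lapply(ds$stage1$train, function(s) s$tokens$token)))
  counts <- tagger_state(fit$tagger)
  expect_true(all(stage1_tokens %in% names(counts)))
})

test_that("two-stage training with noisy weak labels beats tiny gold-only training", {
  ex <- run_ws_experiment(n_train_notes = 120, n_test_notes = 40, n_s = 3,
                          type_swap_rate = 0.3, seed = 7)
  expect_gte(ex$two_stage_f1, ex$gold_only_f1)
  expect_gt(ex$two_stage_f1, 0.5)
})

test_that("gold-only F1 is non-decreasing in the annotation budget (ties allowed)", {
  cfg <- synthetic_corpus_config(n_notes = 80, seed = 103)
  train_notes <- generate_corpus(cfg)
  test_cfg <- cfg; test_cfg$n_notes <- 30L; test_cfg$seed <- 104L
  test_notes <- generate_corpus(test_cfg)
  f1s <- vapply(c(3L, 10L, 50L), function(n_s) {
    sel <- select_gold_notes(train_notes, n_s)
    spec <- ws_dataset_spec(train_notes, sel)
    ds <- assemble_ws_dataset(spec, train_notes, train_notes, seed = 9)
    fit <- train_two_stage(freq_tagger(), list(train = list(), val = list()),
                           ds$stage2)
    micro_f1(test_notes, predict_notes(fit$tagger, test_notes), "strict")
  }, numeric(1))
  expect_true(all(diff(f1s) >= -1e-9))
})
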