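#' Two-stage vs gold-only simulation experiment
#'
#' The desk-scale analogue of the weak-supervision gain study: generate a
#' synthetic training corpus and a held-out test corpus, corrupt the training
#' labels with in-schema type swaps (surviving wrong labels, the harsh noise
#' regime), select \code{n_s} representative gold notes, then compare a
#' lightweight tagger trained weak-then-gold against the same tagger trained
#' on the \code{n_s} gold notes alone, by held-out strict micro F1.
#'
#' @param n_train_notes,n_test_notes Corpus sizes.
#' @param n_s Gold annotation budget.
#' @param type_swap_rate Fraction of weak entity labels swapped to a different
#'   in-schema type.
#' @param seed Integer seed driving corpus generation, noise, and splits.
#' @param corpus_config Optional [synthetic_corpus_config()] template; its
#'   \code{n_notes}/\code{seed} are overridden per corpus.
#' @return List with \code{two_stage_f1}, \code{gold_only_f1}, the
#'   \code{selection}, and both training \code{history} data.frames.
#' @export
run_ws_experiment <- function(n_train_notes = 300L, n_test_notes = 60L,
                              n_s = 3L, type_swap_rate = 0.3, seed = 1L,
                              corpus_config = NULL) {
  base <- corpus_config %||% synthetic_corpus_config()
  make_cfg <- function(n, s) {
    cfg <- base
    cfg$n_notes <- as.integer(n)
    cfg$seed <- as.integer(s)
    cfg
  }
  train_notes <- generate_corpus(make_cfg(n_train_notes, seed))
  test_notes <- generate_corpus(make_cfg(n_test_notes, seed + 1000L))
  schema <- base$schema
  weak_notes <- perturb_entity_types(train_notes, type_swap_rate, schema,
                                     seed = seed + 2000L)
  selection <- select_gold_notes(train_notes, n_s)
  spec <- ws_dataset_spec(train_notes, selection)
  ds <- assemble_ws_dataset(spec, weak_notes, train_notes, seed = seed)
  cfg <- train_config()

  two_stage <- train_two_stage(freq_tagger(), ds$stage1, ds$stage2, cfg)
  gold_only <- train_two_stage(freq_tagger(), list(train = list(), val = list()),
                               ds$stage2, cfg)

  score <- function(fit) {
    preds <- predict_notes(fit$tagger, test_notes)
    micro_f1(test_notes, preds, "strict")
  }
  list(
    two_stage_f1 = score(two_stage),
    gold_only_f1 = score(gold_only),
    selection = selection,
    two_stage_history = two_stage$history,
    gold_only_history = gold_only$history
  )
}
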