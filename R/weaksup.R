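#' Select representative gold notes
#'
#' With an annotation budget of \code{n_s} notes, the selected subset should
#' be representative of the corpus. Notes are ranked by the absolute distance
#' between their entity count and the median entity count over all notes
#' (median of an even count is the mean of the middle two); the \code{n_s}
#' closest are selected, ties broken by ascending note id. This equals the
#' exhaustive minimizer of the summed distance over all size-\code{n_s}
#' subsets.
#'
#' @param notes List of [note()] objects.
#' @param n_s Number of gold notes to select.
#' @param counts Optional named entity counts to rank on (defaults to each
#'   note's gold entity count; weak-label counts can be substituted when
#'   selecting before annotation exists).
#' @return A \code{gold_selection}: \code{n_s}, \code{selected_ids},
#'   \code{median_entities}, \code{distances} (named, all notes).
#' @export
select_gold_notes <- function(notes, n_s, counts = NULL) {
  ids <- vapply(notes, `[[`, character(1), "note_id")
  if (n_s < 1L) stop_weakner("n_s must be >= 1")
  if (n_s > length(notes)) {
    stop_weakner(sprintf("n_s = %d exceeds the %d available notes", n_s, length(notes)))
  }
  if (is.null(counts)) {
    counts <- stats::setNames(vapply(notes, function(n) nrow(n$entities), integer(1)), ids)
  } else {
    counts <- counts[ids]
  }
  med <- stats::median(as.numeric(counts))
  dist <- abs(as.numeric(counts) - med)
  ord <- order(dist, ids)
  structure(
    list(n_s = as.integer(n_s),
         selected_ids = ids[ord][seq_len(n_s)],
         median_entities = med,
         distances = stats::setNames(dist, ids)),
    class = "gold_selection"
  )
}

#' @export
print.gold_selection <- function(x, ...) {
  cat(sprintf("<gold_selection: n_s = %d, median entities = %g>\n",
              x$n_s, x$median_entities))
  cat("  selected:", paste(x$selected_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage dataset specification
#'
#' Partitions the \code{N} training notes into \code{N - n_s} weak notes
#' (stage 1, trained on weak labels) and \code{n_s} gold notes (stage 2,
#' fine-tuned on gold labels). The two sets are disjoint and cover the corpus.
#'
#' @param notes All training [note()]s.
#' @param selection A \code{gold_selection} from [select_gold_notes()], or a
#'   character vector of gold note ids.
#' @param split_fraction Training share of each stage's sentence-level
#'   train/validation split (default 0.8).
#' @return A \code{ws_dataset_spec}: \code{N}, \code{n_s},
#'   \code{weak_note_ids}, \code{gold_note_ids}, \code{split_fraction}.
#' @export
ws_dataset_spec <- function(notes, selection, split_fraction = 0.8) {
  ids <- vapply(notes, `[[`, character(1), "note_id")
  gold_ids <- if (inherits(selection, "gold_selection")) selection$selected_ids else selection
  if (!all(gold_ids %in% ids)) {
    stop_weakner("selection contains note ids outside the corpus")
  }
  structure(
    list(N = length(ids), n_s = length(gold_ids),
         weak_note_ids = setdiff(ids, gold_ids),
         gold_note_ids = gold_ids,
         split_fraction = split_fraction),
    class = "ws_dataset_spec"
  )
}

#' Assemble the two training stages
#'
#' Stage 1 holds the BIO-encoded sentences of the weak notes under their
#' \emph{weak} labels; stage 2 holds the gold notes under their gold labels.
#' Each stage is split by sentence into train/validation at
#' \code{split_fraction}, with a fixed seed.
#'
#' @param spec A [ws_dataset_spec()].
#' @param weak_notes Weakly labeled [note()]s (must cover every weak note id).
#' @param gold_notes Gold [note()]s (must cover every gold note id).
#' @param tokenizer Offset tokenizer for BIO encoding.
#' @param segmenter Sentence segmenter.
#' @param seed Split seed.
#' @return List with \code{stage1} and \code{stage2}, each
#'   \code{list(train, val)} of \code{bio_sequence}s.
#' @export
assemble_ws_dataset <- function(spec, weak_notes, gold_notes,
                                tokenizer = default_tokenizer,
                                segmenter = rule_segmenter, seed = 1L) {
  weak_ids <- vapply(weak_notes, `[[`, character(1), "note_id")
  gold_ids <- vapply(gold_notes, `[[`, character(1), "note_id")
  missing <- setdiff(spec$weak_note_ids, weak_ids)
  if (length(missing) > 0L) {
    stop_weakner(paste("missing weak labels for note(s):",
                       paste(missing, collapse = ", ")))
  }
  missing_gold <- setdiff(spec$gold_note_ids, gold_ids)
  if (length(missing_gold) > 0L) {
    stop_weakner(paste("missing gold labels for note(s):",
                       paste(missing_gold, collapse = ", ")))
  }
  encode <- function(notes, keep_ids) {
    notes <- notes[vapply(notes, `[[`, character(1), "note_id") %in% keep_ids]
    sentences <- unlist(lapply(notes, segment_note, segmenter = segmenter),
                        recursive = FALSE)
    lapply(sentences, entities_to_bio, tokenizer = tokenizer)
  }
  stage1 <- encode(weak_notes, spec$weak_note_ids)
  stage2 <- encode(gold_notes, spec$gold_note_ids)
  split <- function(seqs, seed_offset) {
    n <- length(seqs)
    if (n == 0L) return(list(train = list(), val = list()))
    idx <- local({
      set.seed(seed + seed_offset)
      sample.int(n)
    })
    n_train <- max(1L, round(spec$split_fraction * n))
    list(train = seqs[idx[seq_len(n_train)]],
         val = seqs[idx[-seq_len(n_train)]])
  }
  list(stage1 = split(stage1, 0L), stage2 = split(stage2, 1L))
}

#' Training configuration for the two-stage trainer
#'
#' @param split_fraction Train share of the train/validation split.
#' @param patience Early stop after this many continuous non-improving epochs
#'   (default 8).
#' @param max_epochs Hard epoch cap per stage.
#' @param seed Seed for any tagger-internal randomness.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(split_fraction = 0.8, patience = 8L, max_epochs = 100L,
                         seed = 1L) {
  structure(list(split_fraction = split_fraction, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Two-stage weak-then-gold training
#'
#' Stage 1 fits the tagger on weak labels; stage 2 continues from the stage-1
#' state and fine-tunes on gold labels (no re-initialization). Within each
#' stage the tagger is fit one epoch at a time; after every epoch the strict
#' micro F1 on the stage's validation split is recorded, the best checkpoint
#' is kept, and training halts once \code{patience} continuous non-improving
#' epochs accumulate. The best checkpoint of the final stage is restored
#' before returning. An empty stage 2 runs stage 1 only (flagged).
#'
#' @param tagger A tagger honoring the contract in [tagger_fit_epoch()].
#' @param stage1,stage2 \code{list(train, val)} of \code{bio_sequence}s, from
#'   [assemble_ws_dataset()].
#' @param config A [train_config()].
#' @return List with \code{tagger} (fitted, best checkpoint restored),
#'   \code{history} (data.frame \code{stage}, \code{epoch}, \code{val_f1}),
#'   and \code{flags}.
#' @export
train_two_stage <- function(tagger, stage1, stage2, config = train_config()) {
  history <- data.frame(stage = integer(0), epoch = integer(0), val_f1 = numeric(0))
  flags <- character(0)
  run_stage <- function(tagger, data, stage_no) {
    if (length(data$train) == 0L) return(tagger)
    val <- if (length(data$val) > 0L) data$val else data$train
    best_score <- -Inf
    best_state <- NULL
    since_best <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      tagger <- tagger_fit_epoch(tagger, data$train)
      score <- validation_f1(tagger, val)
      history <<- rbind(history,
                        data.frame(stage = stage_no, epoch = epoch, val_f1 = score))
      if (score > best_score) {
        best_score <- score
        best_state <- tagger_state(tagger)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= config$patience) break
    }
    tagger_restore(tagger, best_state)
  }
  tagger <- run_stage(tagger, stage1, 1L)
  if (length(stage2$train) == 0L) {
    flags <- c(flags, "empty_stage2")
  } else {
    tagger <- run_stage(tagger, stage2, 2L)
  }
  list(tagger = tagger, history = history, flags = flags)
}

# Strict micro F1 of tagger predictions against a validation set's own tags,
# each sequence scored as its own document.
validation_f1 <- function(tagger, sequences) {
  preds <- tagger_predict(tagger, sequences)
  gold_notes <- lapply(seq_along(sequences), function(i) {
    note(paste0("v", i), sequences[[i]]$text, bio_to_entities(sequences[[i]]))
  })
  pred_notes <- lapply(seq_along(sequences), function(i) {
    note(paste0("v", i), sequences[[i]]$text, preds[[i]])
  })
  micro_f1(gold_notes, pred_notes, "strict")
}

#' Tagger predictions for whole notes
#'
#' Segments each note, BIO-tokenizes, predicts per sentence, and lifts the
#' predicted entities back to note-level offsets.
#'
#' @param tagger A fitted tagger.
#' @param notes List of [note()]s (their entities are ignored).
#' @param tokenizer,segmenter As in [assemble_ws_dataset()].
#' @return List of [note()]s carrying predicted entities.
#' @export
predict_notes <- function(tagger, notes, tokenizer = default_tokenizer,
                          segmenter = rule_segmenter) {
  lapply(notes, function(n) {
    bare <- note(n$note_id, n$text, entity_table())
    sentences <- segment_note(bare, segmenter = segmenter)
    seqs <- lapply(sentences, entities_to_bio, tokenizer = tokenizer)
    preds <- tagger_predict(tagger, seqs)
    ents <- entity_table()
    for (i in seq_along(sentences)) {
      e <- preds[[i]]
      if (nrow(e) == 0L) next
      e$start <- e$start + sentences[[i]]$start
      e$end <- e$end + sentences[[i]]$start
      ents <- rbind(ents, e)
    }
    ents <- as_entity_table(ents[order(ents$start, ents$end), ])
    note(n$note_id, n$text, ents)
  })
}
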