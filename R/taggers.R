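# Reference sequence taggers. These stand behind the pluggable tagger
# contract the two-stage trainer orchestrates: fit one epoch at a time on BIO
# sequences, predict entities for sentences, and expose snapshot/restore so
# the trainer can keep the best validation checkpoint. Any encoder model
# honoring the same contract (e.g. a fine-tuned BERT behind an adapter) can
# be dropped in.

#' Reference taggers
#'
#' \describe{
#'   \item{\code{dict_tagger()}}{memorizes whole sentences: an exact lookup
#'     from sentence text to its tag sequence. The test oracle — on a
#'     memorizable corpus it reproduces its training labels exactly.}
#'   \item{\code{freq_tagger()}}{a lightweight trainable tagger: per-token
#'     tag counts with argmax prediction and BIO-grammar repair. Robust to
#'     moderate label noise (majority vote per surface form), which is what
#'     the weak-supervision experiments exercise.}
#' }
#'
#' @return A tagger object (classes \code{dict_tagger} / \code{freq_tagger},
#'   both \code{ner_tagger}).
#' @name taggers
NULL

#' @rdname taggers
#' @export
dict_tagger <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = c("dict_tagger", "ner_tagger"))
}

#' @rdname taggers
#' @export
freq_tagger <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- list()
  structure(list(env = e), class = c("freq_tagger", "ner_tagger"))
}

#' Tagger contract
#'
#' @param tagger A tagger object.
#' @param sequences List of \code{bio_sequence}s (training data).
#' @return \code{tagger_fit_epoch}: the tagger (state updated).
#' @export
tagger_fit_epoch <- function(tagger, sequences) UseMethod("tagger_fit_epoch")

#' @rdname tagger_fit_epoch
#' @return \code{tagger_predict}: list of [entity_table()]s, one per sequence.
#' @export
tagger_predict <- function(tagger, sequences) UseMethod("tagger_predict")

#' @rdname tagger_fit_epoch
#' @return \code{tagger_state}: an opaque snapshot of the tagger state.
#' @export
tagger_state <- function(tagger) UseMethod("tagger_state")

#' @rdname tagger_fit_epoch
#' @param state A snapshot from [tagger_state()].
#' @return \code{tagger_restore}: the tagger with the snapshot restored.
#' @export
tagger_restore <- function(tagger, state) UseMethod("tagger_restore")

#' @export
tagger_fit_epoch.dict_tagger <- function(tagger, sequences) {
  for (s in sequences) assign(s$text, s$tags, envir = tagger$env)
  tagger
}

#' @export
tagger_predict.dict_tagger <- function(tagger, sequences) {
  lapply(sequences, function(s) {
    tags <- if (exists(s$text, envir = tagger$env, inherits = FALSE)) {
      get(s$text, envir = tagger$env)
    } else {
      rep("O", nrow(s$tokens))
    }
    if (length(tags) != nrow(s$tokens)) tags <- rep("O", nrow(s$tokens))
    decode_with_repair(s, tags)
  })
}

#' @export
tagger_state.dict_tagger <- function(tagger) as.list(tagger$env)

#' @export
tagger_restore.dict_tagger <- function(tagger, state) {
  rm(list = ls(tagger$env), envir = tagger$env)
  for (k in names(state)) assign(k, state[[k]], envir = tagger$env)
  tagger
}

#' @export
tagger_fit_epoch.freq_tagger <- function(tagger, sequences) {
  counts <- tagger$env$counts
  for (s in sequences) {
    for (i in seq_along(s$tags)) {
      tok <- s$tokens$token[i]
      tag <- s$tags[i]
      if (is.null(counts[[tok]])) counts[[tok]] <- integer(0)
      counts[[tok]][tag] <- (if (is.na(counts[[tok]][tag])) 0L else counts[[tok]][tag]) + 1L
    }
  }
  tagger$env$counts <- counts
  tagger
}

#' @export
tagger_predict.freq_tagger <- function(tagger, sequences) {
  counts <- tagger$env$counts
  lapply(sequences, function(s) {
    tags <- vapply(s$tokens$token, function(tok) {
      c <- counts[[tok]]
      if (is.null(c) || length(c) == 0L) return("O")
      # argmax; ties broken by tag name for determinism
      names(c)[order(-c, names(c))][1]
    }, character(1), USE.NAMES = FALSE)
    decode_with_repair(s, tags)
  })
}

#' @export
tagger_state.freq_tagger <- function(tagger) tagger$env$counts

#' @export
tagger_restore.freq_tagger <- function(tagger, state) {
  tagger$env$counts <- state
  tagger
}

# Repair BIO grammar (orphan I-X becomes B-X) and decode to entities.
decode_with_repair <- function(s, tags) {
  seq <- structure(list(tokens = s$tokens, tags = tags, text = s$text,
                        sentence_id = s$sentence_id),
                   class = "bio_sequence")
  bio_to_entities(seq)
}
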