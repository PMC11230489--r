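#' Generation settings
#'
#' Decoding settings for the labeling model. Defaults follow the reproducible
#' protocol: \code{top_k = 1} (greedy, disables random token sampling) and a
#' 128-token output cap for speed.
#'
#' @param top_k Top-k decoding parameter.
#' @param max_new_tokens Maximum generated tokens per sentence.
#' @return An object of class \code{generation_settings}.
#' @export
generation_settings <- function(top_k = 1L, max_new_tokens = 128L) {
  stopifnot(top_k >= 1L, max_new_tokens >= 0L)
  structure(list(top_k = as.integer(top_k),
                 max_new_tokens = as.integer(max_new_tokens)),
            class = "generation_settings")
}

#' Supervised fine-tuning configuration
#'
#' Hyperparameters for auto-regressive fine-tuning of the labeling model,
#' emitted alongside the SFT dataset as a manifest any trainer can consume.
#' Defaults: cosine schedule, initial learning rate 2e-5, weight decay 0.1,
#' sequence length 4096 tokens, 2 epochs, batch size 1.
#'
#' @param schedule Learning-rate schedule name.
#' @param initial_lr Initial learning rate.
#' @param weight_decay Weight decay.
#' @param max_seq_len Maximum record length in tokens.
#' @param epochs Training epochs.
#' @param batch_size Batch size.
#' @return An object of class \code{sft_config}.
#' @export
sft_config <- function(schedule = "cosine", initial_lr = 2e-5, weight_decay = 0.1,
                       max_seq_len = 4096L, epochs = 2L, batch_size = 1L) {
  structure(list(schedule = schedule, initial_lr = initial_lr,
                 weight_decay = weight_decay, max_seq_len = as.integer(max_seq_len),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size)),
            class = "sft_config")
}

#' Build labeling prompts for a corpus
#'
#' One prompt per sentence: the sentence text fills the template's input
#' placeholder.
#'
#' @param sentences List of [sentence()] objects.
#' @param template A [prompt_template()].
#' @return data.frame with \code{sentence_id}, \code{prompt},
#'   \code{sentence_text}.
#' @export
build_prompts <- function(sentences, template) {
  data.frame(
    sentence_id = vapply(sentences, `[[`, character(1), "sentence_id"),
    prompt = vapply(sentences, function(s) render_prompt(template, s$text), character(1)),
    sentence_text = vapply(sentences, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
}

#' Generation backends
#'
#' A backend is anything that maps one prompt to generated text through the
#' single-method contract [backend_generate()]. Shipped backends:
#' \describe{
#'   \item{\code{static_backend(text)}}{always returns \code{text}
#'     (default \code{"[]"}): a floor baseline producing zero weak entities.}
#'   \item{\code{oracle_backend(sentences)}}{returns the prompt echo followed
#'     by the sentence's canonical gold [label_json()]: the noise-free path
#'     whose weak labels must equal gold end-to-end.}
#'   \item{\code{replay_backend(store)}}{replays stored generations keyed by a
#'     content hash of the prompt, byte-exactly; the store is a data.frame or
#'     a JSONL path from [write_generation_store()]. Missing prompts yield
#'     error-flagged records (the run continues).}
#' }
#' A corruptor backend that delegates to the synthetic noise model is built
#' with [corruptor_backend()].
#'
#' @param text Fixed output for the static backend.
#' @param sentences Gold sentences for the oracle backend.
#' @param store Replay store (data.frame or JSONL path).
#' @param echo Whether stored/produced outputs include the prompt echo.
#' @name backends
NULL

#' @rdname backends
#' @export
static_backend <- function(text = "[]") {
  structure(list(text = text, echo = FALSE), class = c("static_backend", "ner_backend"))
}

#' @rdname backends
#' @export
oracle_backend <- function(sentences) {
  labels <- stats::setNames(
    vapply(sentences, function(s) label_json(s$entities), character(1)),
    vapply(sentences, `[[`, character(1), "sentence_id")
  )
  structure(list(labels = labels, echo = TRUE),
            class = c("oracle_backend", "ner_backend"))
}

#' @rdname backends
#' @export
replay_backend <- function(store, echo = TRUE) {
  if (is.character(store)) store <- read_generation_store(store)
  if (!is.null(store$echo) && nrow(store) > 0L) echo <- store$echo[1]
  structure(list(store = store, echo = echo),
            class = c("replay_backend", "ner_backend"))
}

#' Single-method backend contract
#'
#' @param backend A backend object.
#' @param prompt The rendered prompt.
#' @param sentence_id Sentence identifier (some backends key on it).
#' @return The generated (decoded) text.
#' @export
backend_generate <- function(backend, prompt, sentence_id) {
  UseMethod("backend_generate")
}

#' @export
backend_generate.static_backend <- function(backend, prompt, sentence_id) {
  backend$text
}

#' @export
backend_generate.oracle_backend <- function(backend, prompt, sentence_id) {
  lab <- backend$labels[[sentence_id]]
  if (is.null(lab)) stop_weakner(sprintf("oracle has no gold labels for %s", sentence_id))
  paste0(prompt, " ", lab)
}

#' @export
backend_generate.replay_backend <- function(backend, prompt, sentence_id) {
  hit <- which(backend$store$prompt_hash == fnv1a32(prompt))
  if (length(hit) == 0L) {
    stop_weakner(sprintf("replay store has no generation for %s", sentence_id))
  }
  backend$store$raw_output[hit[1]]
}

#' Run generation over a prompt set
#'
#' Applies the backend to each prompt in order; the result preserves order and
#' maps prompts to records 1:1. A backend failure on one prompt produces a
#' record with \code{error = TRUE} and the run continues (the failure is
#' accounted downstream as a failed sentence).
#'
#' @param backend A backend (see [backends]).
#' @param prompts data.frame from [build_prompts()].
#' @param settings [generation_settings()].
#' @return List of generation records: \code{sentence_id}, \code{prompt},
#'   \code{raw_output}, \code{echo}, \code{error}, \code{settings}.
#' @export
generate <- function(backend, prompts, settings = generation_settings()) {
  stopifnot(inherits(backend, "ner_backend"), inherits(settings, "generation_settings"))
  lapply(seq_len(nrow(prompts)), function(i) {
    sid <- prompts$sentence_id[i]
    p <- prompts$prompt[i]
    out <- tryCatch(
      list(raw_output = backend_generate(backend, p, sid), error = FALSE),
      error = function(e) list(raw_output = "", error = TRUE)
    )
    list(sentence_id = sid, prompt = p, raw_output = out$raw_output,
         echo = isTRUE(backend$echo), error = out$error, settings = settings)
  })
}

#' Write and read a generation store
#'
#' JSONL, one record per line: \code{sentence_id}, \code{prompt_hash}
#' (content hash of the prompt), \code{raw_output}, \code{echo}, \code{error}.
#' Stored generations can be replayed byte-exactly with [replay_backend()].
#'
#' @param records List of generation records from [generate()].
#' @param path File path.
#' @return The path (write) or a data.frame (read).
#' @export
write_generation_store <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      sentence_id = r$sentence_id, prompt_hash = fnv1a32(r$prompt),
      raw_output = r$raw_output, echo = isTRUE(r$echo), error = isTRUE(r$error)
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_generation_store
#' @export
read_generation_store <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    sentence_id = vapply(rows, `[[`, character(1), "sentence_id"),
    prompt_hash = vapply(rows, `[[`, character(1), "prompt_hash"),
    raw_output = vapply(rows, `[[`, character(1), "raw_output"),
    echo = vapply(rows, function(r) isTRUE(r$echo), logical(1)),
    error = vapply(rows, function(r) isTRUE(r$error), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Export an SFT dataset with its training manifest
#'
#' Writes one JSONL line per record (\code{{"full_text": ...}}) and a JSON
#' manifest of the [sft_config()]. Records longer than \code{max_seq_len}
#' tokens are shortened by removing whole few-shot examples from the left of
#' the few-shot block and re-rendering; the completion is never truncated —
#' if a record cannot fit even with an empty few-shot block, this errors.
#'
#' @param records List of \code{sft_record}s from [build_sft_records()].
#' @param config An [sft_config()].
#' @param data_path,manifest_path Output paths.
#' @param tokenizer Token counter, default [default_tokenizer()].
#' @return Invisibly, a list with the (possibly shortened) records and the ids
#'   of records that required truncation.
#' @export
export_sft_dataset <- function(records, config = sft_config(),
                               data_path, manifest_path,
                               tokenizer = default_tokenizer) {
  truncated <- character(0)
  out <- lapply(records, function(r) {
    n_tok <- nrow(tokenizer(r$full_text))
    if (n_tok <= config$max_seq_len) return(r)
    truncated <<- c(truncated, r$sentence_id)
    tpl <- r$template
    while (n_tok > config$max_seq_len && length(tpl$fewshot) > 0L) {
      tpl$fewshot <- tpl$fewshot[-1]
      prompt <- render_prompt(tpl, r$sentence_text)
      r$full_text <- paste0(prompt, r$completion)
      r$prompt <- prompt
      r$template <- tpl
      n_tok <- nrow(tokenizer(r$full_text))
    }
    if (n_tok > config$max_seq_len) {
      stop_weakner(sprintf(
        "record %s exceeds max_seq_len even with no few-shot examples; refusing to truncate the completion",
        r$sentence_id
      ))
    }
    r
  })
  writeLines(vapply(out, function(r) {
    as.character(jsonlite::toJSON(list(full_text = r$full_text), auto_unbox = TRUE))
  }, character(1)), data_path, useBytes = TRUE)
  jsonlite::write_json(unclass(config), manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(records = out, truncated = truncated))
}
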