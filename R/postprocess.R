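#' Step 1: extract generated text
#'
#' Generated text is everything after the \emph{last} \code{instruction_close}
#' token (the prompt region may contain earlier ones inside few-shot blocks).
#' If the model keeps generating past the intended JSON — e.g. starts a new
#' \code{instruction_open} block — the continuation is truncated at it. When
#' no \code{instruction_close} token is present the whole string is treated as
#' the generation and flagged (attribute \code{no_close}).
#'
#' @param raw_output Decoded model output.
#' @param dialect Special-token dialect (see [prompt_template()]).
#' @param echo Whether \code{raw_output} includes the prompt echo; if FALSE the
#'   string is already the continuation and only truncation applies.
#' @return The generated text.
#' @export
extract_generation <- function(raw_output,
                               dialect = list(instruction_open = "[INST]",
                                              instruction_close = "[/INST]"),
                               echo = TRUE) {
  text <- raw_output
  flagged <- FALSE
  if (echo) {
    closes <- find_all_fixed(text, dialect$instruction_close)
    if (nrow(closes) == 0L) {
      flagged <- TRUE
    } else {
      text <- substr0(text, closes$end[nrow(closes)], nchar(text))
    }
  }
  opens <- find_all_fixed(text, dialect$instruction_open)
  if (nrow(opens) > 0L) {
    text <- substr0(text, 0L, opens$start[1])
  }
  if (flagged) attr(text, "no_close") <- TRUE
  text
}

#' Step 2: parse JSON objects out of the generation
#'
#' Applies the non-greedy brace pattern \code{\\{.*?\\}} and parses each
#' matched substring independently, so one malformed object does not poison
#' the rest. An object must parse and carry non-empty \code{"text"} and
#' \code{"type"} string fields (strict keys, no aliases); anything else is
#' dropped with reason \code{bad_object}. A generation with zero parseable
#' objects and no empty-list token \code{[]} marks the sentence failed
#' (\code{no_json}); a bare \code{[]} is a success with zero entities.
#'
#' @param generated_text Output of [extract_generation()].
#' @return List with \code{records} (data.frame \code{text}, \code{type}),
#'   \code{drops} (data.frame \code{text}, \code{type}, \code{reason}), and
#'   \code{failed} (logical).
#' @export
extract_json_objects <- function(generated_text) {
  records <- data.frame(text = character(0), type = character(0),
                        stringsAsFactors = FALSE)
  drops <- empty_drop_log()
  m <- gregexpr("\\{.*?\\}", generated_text)[[1]]
  chunks <- character(0)
  if (m[1] != -1L) {
    chunks <- substring(generated_text, as.integer(m),
                        as.integer(m) + attr(m, "match.length") - 1L)
  }
  for (chunk in chunks) {
    obj <- tryCatch(jsonlite::fromJSON(chunk), error = function(e) NULL)
    ok <- is.list(obj) && !is.null(obj$text) && !is.null(obj$type) &&
      is.character(obj$text) && is.character(obj$type) &&
      length(obj$text) == 1L && length(obj$type) == 1L && nzchar(obj$text)
    if (ok) {
      records <- rbind(records, data.frame(text = obj$text, type = obj$type,
                                           stringsAsFactors = FALSE))
    } else {
      drops <- rbind(drops, drop_row(chunk, NA_character_, "bad_object"))
    }
  }
  failed <- nrow(records) == 0L && !grepl("\\[\\s*\\]", generated_text)
  list(records = records, drops = drops, failed = failed)
}

#' Step 3: recover character spans by exact matching
#'
#' Each parsed record's text is located in the input sentence by exact,
#' case-sensitive string matching. Records are processed in generation order
#' and each takes the leftmost occurrence not already covered by a previously
#' recovered entity, so repeated mentions are consumed left to right. A record
#' whose text has no free occurrence is dropped: \code{duplicate} if an
#' identical (text, type) was already recovered, else \code{text_not_found}.
#'
#' @param records data.frame from [extract_json_objects()].
#' @param sentence_text The input sentence.
#' @return List with \code{entities} ([entity_table()], sentence-relative) and
#'   \code{drops}.
#' @export
recover_spans <- function(records, sentence_text) {
  entities <- entity_table()
  drops <- empty_drop_log()
  for (i in seq_len(nrow(records))) {
    txt <- records$text[i]
    typ <- records$type[i]
    occ <- find_all_fixed(sentence_text, txt)
    free <- integer(0)
    if (nrow(occ) > 0L) {
      free <- which(vapply(seq_len(nrow(occ)), function(j) {
        nrow(entities) == 0L ||
          !any(occ$start[j] < entities$end & entities$start < occ$end[j])
      }, logical(1)))
    }
    if (length(free) > 0L) {
      j <- free[1]
      entities <- rbind(entities,
                        entity_table(occ$start[j], occ$end[j], txt, typ))
    } else if (nrow(entities) > 0L &&
               any(entities$text == txt & entities$label == typ)) {
      drops <- rbind(drops, drop_row(txt, typ, "duplicate"))
    } else {
      drops <- rbind(drops, drop_row(txt, typ, "text_not_found"))
    }
  }
  list(entities = as_entity_table(entities), drops = drops)
}

#' Step 4: filter entity types to the task schema
#'
#' Generative labelers invent types outside the task definition; only entities
#' whose label matches a schema type exactly are kept. Idempotent.
#'
#' @param entities An [entity_table()].
#' @param schema A [task_schema()].
#' @return List with \code{entities} (kept) and \code{drops}
#'   (reason \code{off_schema_type}).
#' @export
filter_types <- function(entities, schema) {
  keep <- entities$label %in% schema$entity_types
  dropped <- entities[!keep, , drop = FALSE]
  drops <- empty_drop_log()
  if (nrow(dropped) > 0L) {
    drops <- do.call(rbind, lapply(seq_len(nrow(dropped)), function(i) {
      drop_row(dropped$text[i], dropped$label[i], "off_schema_type")
    }))
  }
  list(entities = as_entity_table(entities[keep, , drop = FALSE]), drops = drops)
}

empty_drop_log <- function() {
  data.frame(text = character(0), type = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

drop_row <- function(text, type, reason) {
  data.frame(text = text, type = type, reason = reason, stringsAsFactors = FALSE)
}

#' Run the full four-step post-processing over a generation set
#'
#' Applies, per sentence: generated-text extraction, JSON formatting, entity
#' recovery, and entity-type filtering; accounts every parsed record as either
#' a recovered entity or a logged drop; and aggregates a corpus-level weak
#' label report (totals, per-sentence and per-note quartiles, failed-sentence
#' fraction). A sentence is failed only when no JSON object parses (or its
#' generation errored); failed sentences contribute zero entities.
#'
#' @param generations List of generation records from [generate()].
#' @param sentences List of [sentence()] objects, 1:1 with generations.
#' @param schema A [task_schema()].
#' @param dialect Special-token dialect.
#' @return List with \code{results} (one \code{postprocess_result} per
#'   sentence) and \code{report} (a \code{weak_label_report}).
#' @export
run_postprocess <- function(generations, sentences, schema,
                            dialect = list(instruction_open = "[INST]",
                                           instruction_close = "[/INST]")) {
  gen_ids <- vapply(generations, `[[`, character(1), "sentence_id")
  sent_ids <- vapply(sentences, `[[`, character(1), "sentence_id")
  if (length(gen_ids) != length(sent_ids) || !setequal(gen_ids, sent_ids) ||
      anyDuplicated(gen_ids)) {
    stop_weakner("generations and sentences must correspond 1:1 by sentence_id")
  }
  gen_by_id <- stats::setNames(generations, gen_ids)
  results <- lapply(sentences, function(s) {
    g <- gen_by_id[[s$sentence_id]]
    if (isTRUE(g$error)) {
      return(postprocess_result(s$sentence_id, s$note_id, entity_table(),
                                failed = TRUE, drops = empty_drop_log(),
                                n_parsed = 0L))
    }
    text <- extract_generation(g$raw_output, dialect, echo = isTRUE(g$echo))
    parsed <- extract_json_objects(text)
    if (parsed$failed) {
      return(postprocess_result(s$sentence_id, s$note_id, entity_table(),
                                failed = TRUE, drops = parsed$drops,
                                n_parsed = nrow(parsed$records)))
    }
    rec <- recover_spans(parsed$records, s$text)
    filt <- filter_types(rec$entities, schema)
    postprocess_result(
      s$sentence_id, s$note_id, filt$entities, failed = FALSE,
      drops = rbind(parsed$drops, rec$drops, filt$drops),
      n_parsed = nrow(parsed$records)
    )
  })
  list(results = results, report = weak_label_report(results, sentences))
}

postprocess_result <- function(sentence_id, note_id, entities, failed, drops,
                               n_parsed) {
  structure(
    list(sentence_id = sentence_id, note_id = note_id,
         entities = entities, failed = failed, drop_log = drops,
         n_parsed = n_parsed),
    class = "postprocess_result"
  )
}

#' Weak-label summary report
#'
#' The corpus-level accounting a practitioner inspects before training:
#' note/sentence counts, failed sentences (count and percent), total recovered
#' entities, and median [Q1, Q3] of entities per sentence and per note.
#'
#' @param results List of \code{postprocess_result}s.
#' @param sentences The corresponding sentences.
#' @return An object of class \code{weak_label_report}.
#' @export
weak_label_report <- function(results, sentences) {
  note_ids <- vapply(results, `[[`, character(1), "note_id")
  per_sentence <- vapply(results, function(r) nrow(r$entities), integer(1))
  per_note <- tapply(per_sentence, note_ids, sum)
  failed <- sum(vapply(results, `[[`, logical(1), "failed"))
  q <- function(x) {
    if (length(x) == 0L) return(c(q1 = NA_real_, median = NA_real_, q3 = NA_real_))
    stats::setNames(stats::quantile(as.numeric(x), c(.25, .5, .75), names = FALSE),
                    c("q1", "median", "q3"))
  }
  structure(
    list(
      n_notes = length(unique(note_ids)),
      n_sentences = length(results),
      failed_sentences = failed,
      failed_pct = 100 * failed / max(1L, length(results)),
      total_entities = sum(per_sentence),
      entities_per_sentence = q(per_sentence),
      entities_per_note = q(as.numeric(per_note))
    ),
    class = "weak_label_report"
  )
}

#' @export
print.weak_label_report <- function(x, ...) {
  fmt_q <- function(v) sprintf("%g [%g, %g]", v["median"], v["q1"], v["q3"])
  cat("Weak label report\n")
  cat(sprintf("  Notes: %d   Sentences: %d\n", x$n_notes, x$n_sentences))
  cat(sprintf("  Post-processing failed sentences: %d (%.2f%%)\n",
              x$failed_sentences, x$failed_pct))
  cat(sprintf("  Total entities: %d\n", x$total_entities))
  cat(sprintf("  Entities per sentence, median [Q1, Q3]: %s\n",
              fmt_q(x$entities_per_sentence)))
  cat(sprintf("  Entities per note, median [Q1, Q3]: %s\n",
              fmt_q(x$entities_per_note)))
  invisible(x)
}

#' Lift sentence-level weak labels back to notes
#'
#' Maps sentence-relative entity offsets to note-level offsets and returns one
#' weakly labeled [note()] per input note (text taken from \code{notes}).
#'
#' @param results \code{postprocess_result}s from [run_postprocess()].
#' @param sentences The corresponding sentences.
#' @param notes The original notes (for text and note order).
#' @return List of [note()] objects carrying weak entities.
#' @export
weak_labels_to_notes <- function(results, sentences, notes) {
  sent_by_id <- stats::setNames(sentences,
                                vapply(sentences, `[[`, character(1), "sentence_id"))
  ents_by_note <- list()
  for (r in results) {
    s <- sent_by_id[[r$sentence_id]]
    if (nrow(r$entities) == 0L) next
    e <- r$entities
    e$start <- e$start + s$start
    e$end <- e$end + s$start
    ents_by_note[[s$note_id]] <- rbind(ents_by_note[[s$note_id]], e)
  }
  lapply(notes, function(n) {
    e <- ents_by_note[[n$note_id]]
    e <- if (is.null(e)) entity_table() else as_entity_table(e[order(e$start, e$end), ])
    note(n$note_id, n$text, e)
  })
}
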