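#' Entity tables
#'
#' Entities are stored as plain data frames with one row per entity and
#' columns \code{start}, \code{end}, \code{text}, \code{label}. Offsets are
#' 0-based, half-open, counted in Unicode code points (the BRAT standoff
#' convention), so \code{substr(owning_text, start + 1, end) == text}.
#'
#' @param start,end Integer character offsets (0-based, half-open).
#' @param text Surface strings, exactly as they appear in the owning text.
#' @param label Entity-type names (non-empty, no whitespace).
#' @return A data.frame of class \code{entity_table}.
#' @export
entity_table <- function(start = integer(0), end = integer(0),
                         text = character(0), label = character(0)) {
  df <- data.frame(
    start = as.integer(start), end = as.integer(end),
    text = as.character(text), label = as.character(label),
    stringsAsFactors = FALSE
  )
  class(df) <- c("entity_table", "data.frame")
  df
}

as_entity_table <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(entity_table())
  entity_table(df$start, df$end, df$text, df$label)
}

#' Validate entities against their owning text
#'
#' Enforces the entity invariants: offsets in range, half-open span non-empty,
#' exact (case-sensitive) substring equality, and well-formed labels.
#'
#' @param entities An [entity_table()].
#' @param text The owning text.
#' @param ids Optional identifiers used in error messages (e.g. BRAT T-ids).
#' @return The validated entity table, invisibly.
#' @export
validate_entities <- function(entities, text, ids = NULL) {
  if (nrow(entities) == 0L) return(invisible(entities))
  n <- nchar(text)
  ids <- ids %||% paste0("entity ", seq_len(nrow(entities)))
  for (i in seq_len(nrow(entities))) {
    e <- entities[i, ]
    if (is.na(e$start) || is.na(e$end) || e$start < 0L || e$start >= e$end || e$end > n) {
      stop_weakner(sprintf(
        "%s: invalid span [%s, %s) for text of length %d", ids[i], e$start, e$end, n
      ))
    }
    got <- substr0(text, e$start, e$end)
    if (!identical(got, e$text)) {
      stop_weakner(sprintf(
        "%s: annotation text %s does not match document span %s (case-sensitive)",
        ids[i], dQuote(e$text, FALSE), dQuote(got, FALSE)
      ))
    }
    if (is.na(e$label) || !nzchar(e$label) || grepl("\\s", e$label)) {
      stop_weakner(sprintf("%s: label must be a non-empty token without whitespace", ids[i]))
    }
  }
  invisible(entities)
}

#' Construct a note
#'
#' A note is the unit the pipeline counts as \emph{N} in weak supervision:
#' full text plus gold (or weak) entities with note-level offsets.
#'
#' @param note_id Unique identifier within a corpus.
#' @param text Full note text.
#' @param entities An [entity_table()] with offsets into \code{text}.
#' @param validate Check entity invariants (default TRUE).
#' @return An object of class \code{ner_note}.
#' @export
note <- function(note_id, text, entities = entity_table(), validate = TRUE) {
  entities <- as_entity_table(entities)
  if (validate) validate_entities(entities, text)
  structure(
    list(note_id = as.character(note_id), text = text, entities = entities),
    class = "ner_note"
  )
}

#' @export
print.ner_note <- function(x, ...) {
  cat(sprintf(
    "<ner_note %s: %d chars, %d entities>\n",
    x$note_id, nchar(x$text), nrow(x$entities)
  ))
  invisible(x)
}

#' Construct a sentence
#'
#' Sentences carry their position inside the owning note and entities with
#' sentence-relative offsets, so that \code{start + sentence$start} recovers
#' the note-level offset.
#'
#' @param note_id Owning note id.
#' @param index 0-based ordinal within the note.
#' @param start,end Character offsets of the sentence inside the note.
#' @param text The sentence substring.
#' @param entities [entity_table()] with sentence-relative offsets.
#' @return An object of class \code{ner_sentence}.
#' @export
sentence <- function(note_id, index, start, end, text, entities = entity_table()) {
  entities <- as_entity_table(entities)
  validate_entities(entities, text)
  structure(
    list(
      note_id = as.character(note_id), index = as.integer(index),
      start = as.integer(start), end = as.integer(end),
      text = text, entities = entities,
      sentence_id = paste0(note_id, ":", index)
    ),
    class = "ner_sentence"
  )
}

#' Define a task schema
#'
#' The ordered set of entity types a benchmark task recognizes, e.g. the 9
#' medication-extraction types (drug, strength, form, dosage, frequency,
#' route, duration, reason, ADE). Post-processing filters weak labels to
#' these types.
#'
#' @param task_name Short task name.
#' @param entity_types Character vector of unique, non-empty type names.
#' @return An object of class \code{task_schema}.
#' @export
task_schema <- function(task_name, entity_types) {
  entity_types <- as.character(entity_types)
  if (length(entity_types) == 0L || anyDuplicated(entity_types) ||
      any(!nzchar(entity_types))) {
    stop_weakner("entity_types must be a non-empty set of unique, non-empty names")
  }
  structure(
    list(task_name = as.character(task_name), entity_types = entity_types),
    class = "task_schema"
  )
}

#' @export
print.task_schema <- function(x, ...) {
  cat(sprintf(
    "<task_schema %s: %s>\n", x$task_name, paste(x$entity_types, collapse = ", ")
  ))
  invisible(x)
}
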