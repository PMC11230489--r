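#' Split a note into sentences
#'
#' Sentence-level processing keeps prompts inside the context budget of the
#' labeling model, so every downstream stage works on sentences. The default
#' segmenter is rule-based: a boundary after sentence-final punctuation
#' (\code{. ! ?}) followed by whitespace, and at newlines. A custom segmenter
#' can be injected as a function \code{text -> integer vector} of 0-based
#' boundary offsets (positions where a new sentence may start).
#'
#' Entities are assigned to the sentence containing their start offset. If a
#' gold entity crosses a candidate boundary the two sentences are merged
#' (boundary repair), so no entity is ever split.
#'
#' @param x A [note()].
#' @param segmenter Boundary function; default [rule_segmenter()].
#' @return List of [sentence()] objects with sentence-relative entities.
#' @export
segment_note <- function(x, segmenter = rule_segmenter) {
  stopifnot(inherits(x, "ner_note"))
  spans <- sentence_spans(x$text, segmenter)
  if (nrow(spans) == 0L) {
    spans <- data.frame(start = 0L, end = nchar(x$text))
  }
  spans <- repair_boundaries(spans, x$entities)
  ents <- x$entities
  out <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    keep <- ents$start >= s & ents$start < e
    rel <- ents[keep, , drop = FALSE]
    if (nrow(rel) > 0L) {
      rel$start <- rel$start - s
      rel$end <- rel$end - s
      rel <- rel[order(rel$start, rel$end), , drop = FALSE]
    }
    out[[i]] <- sentence(x$note_id, i - 1L, s, e,
                         substr0(x$text, s, e), as_entity_table(rel))
  }
  out
}

#' @rdname segment_note
#' @param text Raw note text.
#' @return \code{rule_segmenter}: 0-based offsets at which sentences may start.
#' @export
rule_segmenter <- function(text) {
  # boundary after [.!?]+ followed by whitespace, or after a newline run
  m <- gregexpr("([.!?]+(?=[[:space:]]))|\n+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  ends <- as.integer(m) - 1L + attr(m, "match.length")
  sort(unique(ends))
}

# Turn boundary offsets into trimmed sentence spans covering the text.
sentence_spans <- function(text, segmenter) {
  n <- nchar(text)
  cuts <- sort(unique(c(0L, segmenter(text), n)))
  cuts <- cuts[cuts >= 0L & cuts <= n]
  spans <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
  # trim surrounding whitespace, drop empty spans
  keep <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    while (s < e && grepl("^[[:space:]]$", substr0(text, s, s + 1L))) s <- s + 1L
    while (e > s && grepl("^[[:space:]]$", substr0(text, e - 1L, e))) e <- e - 1L
    spans$start[i] <- s; spans$end[i] <- e
    keep[i] <- e > s
  }
  spans[keep, , drop = FALSE]
}

# Merge adjacent sentence spans until no entity crosses a span boundary.
repair_boundaries <- function(spans, entities) {
  repeat {
    merged <- FALSE
    if (nrow(spans) <= 1L || nrow(entities) == 0L) break
    for (i in seq_len(nrow(spans) - 1L)) {
      crossing <- entities$start >= spans$start[i] & entities$start < spans$end[i] &
        entities$end > spans$end[i]
      # also: entity starting in the gap between spans i and i+1
      in_gap <- entities$start >= spans$end[i] & entities$start < spans$start[i + 1]
      if (any(crossing) || any(in_gap)) {
        spans$end[i] <- spans$end[i + 1]
        spans <- spans[-(i + 1L), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(spans) <- NULL
  spans
}
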