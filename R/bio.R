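#' Whitespace + punctuation tokenizer with character offsets
#'
#' The default tokenizer for BIO conversion: maximal runs of word characters
#' become tokens, every other non-space character is a single-character token.
#' Offsets are 0-based half-open into the input text. A downstream tagger's
#' own (e.g. WordPiece) tokenizer can be injected anywhere this one is used.
#'
#' @param text Input string.
#' @return data.frame with columns \code{token}, \code{start}, \code{end}.
#' @export
default_tokenizer <- function(text) {
  m <- gregexpr("[[:alnum:]_]+|[^[:alnum:]_[:space:]]", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0)))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(token = substring(text, start + 1L, end), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Convert sentence entities to BIO token tags
#'
#' Produces the training encoding for sequence taggers: tokens overlapping an
#' entity get \code{B-}/\code{I-} tags, all others \code{O}. Single-layer BIO
#' cannot express overlapping entities, so when two gold entities overlap the
#' longer span is kept and the shorter dropped (logged in the result's
#' \code{dropped_overlaps} attribute). An entity boundary falling strictly
#' inside a token is snapped outward to token boundaries and flagged in the
#' \code{snapped} attribute.
#'
#' @param s A [sentence()].
#' @param tokenizer Offset-returning tokenizer; default [default_tokenizer()].
#' @return A \code{bio_sequence}: list with \code{tokens} (data.frame) and
#'   \code{tags} (character, one per token), plus the sentence text and id.
#' @export
entities_to_bio <- function(s, tokenizer = default_tokenizer) {
  stopifnot(inherits(s, "ner_sentence"))
  toks <- tokenizer(s$text)
  tags <- rep("O", nrow(toks))
  ents <- s$entities
  dropped <- entity_table()
  if (nrow(ents) > 1L) {
    # resolve overlaps: keep longer span; ties by earlier start
    ord <- order(-(ents$end - ents$start), ents$start)
    kept <- entity_table()
    for (i in ord) {
      e <- ents[i, ]
      overlaps <- nrow(kept) > 0L && any(e$start < kept$end & kept$start < e$end)
      if (overlaps) dropped <- rbind(dropped, e) else kept <- rbind(kept, e)
    }
    ents <- kept[order(kept$start), , drop = FALSE]
  }
  snapped <- integer(0)
  if (nrow(toks) > 0L) {
    for (i in seq_len(nrow(ents))) {
      e <- ents[i, ]
      hit <- which(toks$start < e$end & toks$end > e$start)
      if (length(hit) == 0L) next
      if (toks$start[hit[1]] < e$start || toks$end[hit[length(hit)]] > e$end) {
        snapped <- c(snapped, i)
      }
      tags[hit[1]] <- paste0("B-", e$label)
      if (length(hit) > 1L) tags[hit[-1]] <- paste0("I-", e$label)
    }
  }
  structure(
    list(tokens = toks, tags = tags, text = s$text,
         sentence_id = s$sentence_id),
    class = "bio_sequence",
    dropped_overlaps = as_entity_table(dropped),
    snapped = snapped
  )
}

#' Decode BIO tags back to entities
#'
#' Maximal contiguous \code{B-X (I-X)*} runs become entities spanning the
#' first token's start to the last token's end. An \code{I-X} tag without a
#' preceding \code{B-X}/\code{I-X} of the same type is repaired to \code{B-X}
#' (a fresh entity), so any tag sequence decodes.
#'
#' @param seq A \code{bio_sequence}.
#' @return An [entity_table()] with offsets into the sequence's text.
#' @export
bio_to_entities <- function(seq) {
  toks <- seq$tokens
  tags <- seq$tags
  stopifnot(length(tags) == nrow(toks))
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (!is.null(cur)) out[[length(out) + 1L]] <- cur
    out
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O" || is.na(t)) {
      out <- flush(cur, out); cur <- NULL
    } else {
      prefix <- substr(t, 1, 1)
      label <- substring(t, 3)
      continues <- identical(prefix, "I") && !is.null(cur) && cur$label == label
      if (continues) {
        cur$end <- toks$end[i]
      } else {
        out <- flush(cur, out)
        cur <- list(start = toks$start[i], end = toks$end[i], label = label)
      }
    }
  }
  out <- flush(cur, out)
  if (length(out) == 0L) return(entity_table())
  starts <- vapply(out, `[[`, integer(1), "start")
  ends <- vapply(out, `[[`, integer(1), "end")
  labels <- vapply(out, `[[`, character(1), "label")
  entity_table(starts, ends, substring(seq$text, starts + 1L, ends), labels)
}

#' @export
print.bio_sequence <- function(x, ...) {
  cat(sprintf("<bio_sequence %s: %d tokens, %d tagged>\n",
              x$sentence_id %||% "?", nrow(x$tokens), sum(x$tags != "O")))
  invisible(x)
}
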