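#' Read a note from BRAT standoff files
#'
#' Reads a plain-text note and its standoff annotation file. Only T-lines
#' (text-bound annotations) are consumed: \code{Tn <TAB> Label start end
#' <TAB> text}; a space-separated dialect is accepted too. Every entity is
#' validated against the text (exact, case-sensitive substring equality).
#' Discontinuous spans (\code{;}-separated fragments) are not supported.
#'
#' @param text_path Path to the \code{.txt} file.
#' @param ann_path Path to the \code{.ann} file.
#' @param schema Optional [task_schema()]; entities whose label is outside the
#'   schema are retained but recorded in the note's \code{off_schema}
#'   attribute (annotation ids).
#' @param note_id Note identifier; defaults to the text file's base name.
#' @return A [note()].
#' @export
read_standoff <- function(text_path, ann_path, schema = NULL, note_id = NULL) {
  text <- read_text_file(text_path)
  note_id <- note_id %||% sub("\\.txt$", "", basename(text_path))
  lines <- if (file.exists(ann_path)) readLines(ann_path, warn = FALSE) else character(0)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0)
  ents <- entity_table()
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!startsWith(line, "T")) next # relations/attributes/events are ignored
    parsed <- parse_t_line(line, k)
    ids <- c(ids, parsed$id)
    ents <- rbind(ents, entity_table(parsed$start, parsed$end, parsed$text, parsed$label))
  }
  ents <- as_entity_table(ents)
  validate_entities(ents, text, ids = ids)
  n <- note(note_id, text, ents, validate = FALSE)
  if (!is.null(schema)) {
    attr(n, "off_schema") <- ids[!(ents$label %in% schema$entity_types)]
  }
  n
}

parse_t_line <- function(line, line_no) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) >= 3L) {
    id <- parts[1]
    mid <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    text <- paste(parts[-(1:2)], collapse = "\t")
  } else {
    # space-separated dialect: id label start end text...
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) < 5L) {
      stop_weakner(sprintf("line %d: cannot parse standoff T-line: %s", line_no, line))
    }
    id <- toks[1]
    mid <- toks[2:4]
    # recover the text verbatim: everything after the 4th field
    m <- regexpr(sprintf("^\\s*%s\\s+%s\\s+%s\\s+%s\\s", toks[1], toks[2], toks[3], toks[4]),
                 line)
    text <- substring(line, attr(m, "match.length") + 1L)
  }
  if (length(mid) != 3L || is.na(suppressWarnings(as.integer(mid[2]))) ||
      is.na(suppressWarnings(as.integer(mid[3])))) {
    stop_weakner(sprintf("line %d: cannot parse standoff T-line: %s", line_no, line))
  }
  list(
    id = id, label = mid[1],
    start = as.integer(mid[2]), end = as.integer(mid[3]), text = text
  )
}

#' Write a note to BRAT standoff files
#'
#' Inverse of [read_standoff()]: emits the note text and one tab-separated
#' T-line per entity. Re-reading the emitted files yields an equal note.
#'
#' @param x A [note()].
#' @param text_path,ann_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_standoff <- function(x, text_path, ann_path) {
  stopifnot(inherits(x, "ner_note"))
  writeLines(x$text, text_path, sep = "", useBytes = TRUE)
  ents <- x$entities
  t_lines <- character(0)
  if (nrow(ents) > 0L) {
    t_lines <- sprintf("T%d\t%s %d %d\t%s",
                       seq_len(nrow(ents)), ents$label, ents$start, ents$end, ents$text)
  }
  writeLines(t_lines, ann_path, useBytes = TRUE)
  invisible(c(text = text_path, ann = ann_path))
}

read_text_file <- function(path) {
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  raw
}

#' Write and read a corpus as JSONL
#'
#' One note per line: \code{{"note_id": ..., "text": ..., "entities": [...]}}.
#' This is the interchange format between pipeline stages.
#'
#' @param notes List of [note()] objects.
#' @param path Output (or input) file path.
#' @return \code{write_corpus_jsonl}: the path, invisibly.
#' @export
write_corpus_jsonl <- function(notes, path) {
  lines <- vapply(notes, function(n) {
    ents <- n$entities
    jsonlite::toJSON(list(
      note_id = n$note_id, text = n$text,
      entities = data.frame(start = ents$start, end = ents$end,
                            text = ents$text, label = ents$label)
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @return \code{read_corpus_jsonl}: a list of [note()] objects.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
    ents <- if (length(obj$entities) == 0L) entity_table() else
      entity_table(obj$entities$start, obj$entities$end,
                   obj$entities$text, obj$entities$label)
    note(obj$note_id, obj$text, ents)
  })
}
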