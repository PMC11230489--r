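#' Canonical label JSON
#'
#' Weak labels travel between the prompt builder, the labeling model, and the
#' post-processor as a JSON array of \code{{"text": ..., "type": ...}} objects
#' in that key order, entities sorted by start offset, no whitespace variance.
#' Keeping one canon makes SFT completions and parsing exactly symmetric.
#'
#' @param entities An [entity_table()].
#' @return A single JSON string, \code{"[]"} when empty.
#' @export
label_json <- function(entities) {
  if (nrow(entities) == 0L) return("[]")
  ents <- entities[order(entities$start, entities$end), , drop = FALSE]
  objs <- lapply(seq_len(nrow(ents)), function(i) {
    list(text = ents$text[i], type = ents$label[i])
  })
  as.character(jsonlite::toJSON(objs, auto_unbox = TRUE))
}

#' Prompt templates
#'
#' The labeling prompt has exactly four sections in fixed order: a system
#' prompt (assigns the assistant a role), an instruction (task narrative:
#' entity types and the expected JSON output), few-shot examples (sentence and
#' gold label JSON pairs), and the input placeholder \code{{input}}. The
#' special-token dialect (\code{instruction_open}/\code{instruction_close},
#' default \code{[INST]}/\code{[/INST]}) wraps each sentence so generation
#' continues after the final \code{instruction_close}.
#'
#' @param system_prompt,instruction Section texts.
#' @param fewshot List of few-shot examples from [sample_fewshot()] (possibly
#'   empty).
#' @param dialect Named list with \code{instruction_open} and
#'   \code{instruction_close} strings.
#' @return An object of class \code{prompt_template}.
#' @export
prompt_template <- function(system_prompt, instruction, fewshot = list(),
                            dialect = list(instruction_open = "[INST]",
                                           instruction_close = "[/INST]")) {
  stopifnot(is.character(system_prompt), is.character(instruction),
            is.list(fewshot),
            nzchar(dialect$instruction_open), nzchar(dialect$instruction_close))
  structure(
    list(system_prompt = system_prompt, instruction = instruction,
         fewshot = fewshot, dialect = dialect),
    class = "prompt_template"
  )
}

#' @rdname prompt_template
#' @param schema A [task_schema()]; the instruction enumerates its types.
#' @return \code{default_prompt_template}: a neutral template for the schema.
#' @export
default_prompt_template <- function(schema, fewshot = list()) {
  prompt_template(
    system_prompt = paste(
      "You are an annotation assistant for clinical research text.",
      "You label de-identified notes for an approved study."
    ),
    instruction = paste0(
      "The input is one sentence from a clinical note. Identify every mention ",
      "of the following entity types: ", paste(schema$entity_types, collapse = ", "),
      ". Respond with a JSON list of objects, each with keys \"text\" (the exact ",
      "sentence substring) and \"type\" (one of the listed types). ",
      "Respond with [] if the sentence contains none."
    ),
    fewshot = fewshot
  )
}

#' Sample few-shot examples from a corpus
#'
#' Uniform sampling without replacement over all candidate sentences
#' (entity-free sentences included), reproducible for a fixed seed. Each
#' example pairs the sentence text with its canonical gold [label_json()].
#'
#' @param sentences List of [sentence()] objects (the candidate pool).
#' @param k Number of examples (default 8).
#' @param seed Integer seed.
#' @return List of examples, each \code{list(sentence_text, label_json)}.
#' @export
sample_fewshot <- function(sentences, k = 8L, seed = 1L) {
  if (k > length(sentences)) {
    stop_weakner(sprintf("k = %d exceeds the %d candidate sentences", k, length(sentences)))
  }
  if (k == 0L) return(list())
  idx <- local({
    set.seed(seed)
    sample.int(length(sentences), k)
  })
  lapply(sentences[idx], function(s) {
    list(sentence_text = s$text, label_json = label_json(s$entities))
  })
}

#' Render a prompt
#'
#' Deterministically renders the four sections. With \code{input = NULL} the
#' \code{{input}} placeholder is left unfilled (exactly one occurrence);
#' otherwise the input sentence is substituted and the rendered prompt ends at
#' \code{instruction_close}, so the model's generation continues after it.
#'
#' @param template A [prompt_template()].
#' @param input Input sentence text, or NULL to keep the placeholder.
#' @return The prompt string.
#' @export
render_prompt <- function(template, input = NULL) {
  d <- template$dialect
  fs <- vapply(template$fewshot, function(ex) {
    paste0(d$instruction_open, " ", ex$sentence_text, " ",
           d$instruction_close, " ", ex$label_json)
  }, character(1))
  body <- paste0(d$instruction_open, " {input} ", d$instruction_close)
  rendered <- paste(
    c(template$system_prompt, template$instruction, fs, body),
    collapse = "\n"
  )
  if (is.null(input)) {
    if (count_fixed(rendered, "{input}") != 1L) {
      stop_weakner("template must contain exactly one {input} placeholder")
    }
    return(rendered)
  }
  out <- sub("{input}", input, rendered, fixed = TRUE)
  if (count_fixed(out, "{input}") != 0L) {
    stop_weakner("unfilled {input} placeholder remains after rendering")
  }
  out
}

count_fixed <- function(x, pattern) {
  nrow(find_all_fixed(x, pattern))
}

#' Estimate the prompt context length in tokens
#'
#' The inference-cost formula needs the input context length n_ctx; following
#' the budgeting convention, it is estimated from the rendered prompt
#' template. Counted with the injected tokenizer (default the package's
#' word-level tokenizer; a subword tokenizer gives model-accurate counts).
#'
#' @param template A [prompt_template()].
#' @param input Representative input sentence (default: placeholder left in).
#' @param tokenizer Offset tokenizer; default [default_tokenizer()].
#' @return Integer token count.
#' @export
estimate_n_ctx <- function(template, input = NULL, tokenizer = default_tokenizer) {
  nrow(tokenizer(render_prompt(template, input)))
}

#' Build supervised fine-tuning records
#'
#' SFT trains the labeling model auto-regressively on prompt + completion:
#' each sentence of the gold notes is placed in the input placeholder and the
#' canonical gold label JSON is appended directly after the final
#' \code{instruction_close} token. Splitting a record's \code{full_text} at
#' the last \code{instruction_close} recovers the completion exactly.
#'
#' @param notes List of gold [note()] objects.
#' @param template A [prompt_template()].
#' @param segmenter Sentence segmenter, default [rule_segmenter()].
#' @return List of \code{sft_record}s: \code{full_text}, \code{prompt},
#'   \code{completion}, \code{sentence_text}, \code{sentence_id}.
#' @export
build_sft_records <- function(notes, template, segmenter = rule_segmenter) {
  sentences <- unlist(lapply(notes, segment_note, segmenter = segmenter),
                      recursive = FALSE)
  lapply(sentences, function(s) {
    prompt <- render_prompt(template, s$text)
    completion <- paste0(" ", label_json(s$entities))
    structure(
      list(full_text = paste0(prompt, completion),
           prompt = prompt, completion = completion,
           sentence_text = s$text, sentence_id = s$sentence_id,
           template = template),
      class = "sft_record"
    )
  })
}
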