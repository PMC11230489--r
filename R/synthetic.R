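# Synthetic clinical-style corpora with planted entities.
#
# Vocabularies are constructed so that no word (entity, filler, hallucination)
# is a substring of any other word in play. Sentences are plain token joins,
# so exact-string span recovery is collision-free by construction: the oracle
# path is exactly invertible and the noise audit is an exact accounting
# identity rather than an approximate one.

synthetic_vocab <- function() {
  list(
    Drug = c("veltrazine", "morbexol", "quandipril", "zaltorex", "fexuprame",
             "dormicaine", "relpaxor", "tubrafen", "ceftoral", "mivandol",
             "parvexin", "lomuzane", "bextramil", "soquilar", "denthrava",
             "ruvalixen", "capsorine", "wenotrab", "glanforide", "hespirol"),
    Dosage = paste(c("10", "25", "40", "75", "90", "35", "65", "85"), "mg"),
    Frequency = c("twice daily", "once weekly", "every morning",
                  "each evening", "four hourly", "once nightly")
  )
}

synthetic_filler <- function() {
  c("patient", "was", "given", "with", "for", "stable", "continued", "review",
    "noted", "tolerated", "started", "after", "admission", "course", "remains",
    "improved", "without", "complication", "today", "plan", "follow", "clinic",
    "discharged", "home", "condition", "good")
}

synthetic_hallucination_vocab <- function() {
  c("xqzuvor", "kblentha", "vrugnosk", "pzarquel", "jxovrand", "qmelfitz")
}

#' Synthetic corpus configuration
#'
#' Describes the corpus the generator emits. Entities per sentence follow a
#' zero-inflated Poisson: with probability \code{p_zero} a sentence has no
#' entities, otherwise a Poisson(\code{lambda}) count — the shape of real
#' sentence-level entity distributions, whose medians sit at 0 with
#' occasional dense sentences. Defaults (\code{p_zero = 0.7},
#' \code{lambda = 1.1}) reproduce a median [Q1, Q3] of 0 [0, 0] with mean
#' about 0.5, the sparse regime of medication-extraction corpora.
#'
#' @param n_notes Number of notes.
#' @param sentences_per_note Integer (min, max); uniform per note.
#' @param p_zero Zero-inflation probability.
#' @param lambda Poisson mean of the non-zero component.
#' @param min_entities Floor on entities per sentence (default 0).
#' @param schema [task_schema()]; must have a vocabulary per type.
#' @param vocab Named list of per-type surface-form vectors.
#' @param filler Filler word vector.
#' @param seed Integer seed; fixes the corpus byte-exactly.
#' @return An object of class \code{synthetic_corpus_config}.
#' @export
synthetic_corpus_config <- function(n_notes = 20L,
                                    sentences_per_note = c(4L, 12L),
                                    p_zero = 0.7, lambda = 1.1,
                                    min_entities = 0L,
                                    schema = task_schema("synthetic_meds",
                                                         c("Drug", "Dosage", "Frequency")),
                                    vocab = synthetic_vocab(),
                                    filler = synthetic_filler(),
                                    seed = 1L) {
  stopifnot(n_notes >= 1L, length(sentences_per_note) == 2L,
            sentences_per_note[1] >= 1L,
            sentences_per_note[2] >= sentences_per_note[1],
            p_zero >= 0, p_zero <= 1, lambda >= 0)
  missing_vocab <- setdiff(schema$entity_types, names(vocab))
  if (length(missing_vocab) > 0L) {
    stop_weakner(sprintf("no vocabulary for entity type(s): %s",
                         paste(missing_vocab, collapse = ", ")))
  }
  if (any(vapply(vocab[schema$entity_types], length, integer(1)) == 0L)) {
    stop_weakner("empty vocabulary for a requested entity type")
  }
  structure(
    list(n_notes = as.integer(n_notes),
         sentences_per_note = as.integer(sentences_per_note),
         p_zero = p_zero, lambda = lambda, min_entities = as.integer(min_entities),
         schema = schema, vocab = vocab, filler = filler, seed = as.integer(seed)),
    class = "synthetic_corpus_config"
  )
}

#' Generate a synthetic corpus
#'
#' Notes are sequences of sentences; each sentence interleaves filler words
#' with whole-token entity phrases drawn from per-type vocabularies, ends with
#' a period, and never lets an entity cross a sentence boundary. Gold offsets
#' are tracked during construction, so every note satisfies the entity
#' invariants by construction. Reproducible: a fixed seed yields a
#' byte-identical corpus.
#'
#' @param config A [synthetic_corpus_config()].
#' @return List of [note()] objects with gold entities.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_corpus_config"))
  set.seed(config$seed)
  types <- config$schema$entity_types
  lapply(seq_len(config$n_notes), function(i) {
    note_id <- sprintf("note%04d", i)
    n_sent <- sample(config$sentences_per_note[1]:config$sentences_per_note[2], 1L)
    text <- ""
    ents <- entity_table()
    pos <- 0L
    for (s in seq_len(n_sent)) {
      n_ent <- if (stats::runif(1) < config$p_zero) 0L else stats::rpois(1, config$lambda)
      n_ent <- max(config$min_entities, n_ent)
      sen <- build_sentence(n_ent, types, config$vocab, config$filler)
      if (nzchar(text)) {
        text <- paste0(text, " ")
        pos <- pos + 1L
      }
      if (nrow(sen$entities) > 0L) {
        sen$entities$start <- sen$entities$start + pos
        sen$entities$end <- sen$entities$end + pos
        ents <- rbind(ents, sen$entities)
      }
      text <- paste0(text, sen$text)
      pos <- pos + nchar(sen$text)
    }
    note(note_id, text, as_entity_table(ents))
  })
}

# One sentence: filler words with entity phrases inserted at random slots.
build_sentence <- function(n_ent, types, vocab, filler) {
  n_fill <- sample(3:8, 1L)
  items <- data.frame(text = sample(filler, n_fill, replace = TRUE),
                      label = NA_character_, stringsAsFactors = FALSE)
  if (n_ent > 0L) {
    for (k in seq_len(n_ent)) {
      typ <- types[sample.int(length(types), 1L)]
      surface <- vocab[[typ]][sample.int(length(vocab[[typ]]), 1L)]
      at <- sample.int(nrow(items) + 1L, 1L)
      items <- rbind(items[seq_len(at - 1L), , drop = FALSE],
                     data.frame(text = surface, label = typ, stringsAsFactors = FALSE),
                     items[seq(at, length.out = nrow(items) - at + 1L), , drop = FALSE])
    }
  }
  pos <- 0L
  starts <- integer(nrow(items))
  for (i in seq_len(nrow(items))) {
    if (i > 1L) pos <- pos + 1L
    starts[i] <- pos
    pos <- pos + nchar(items$text[i])
  }
  is_ent <- !is.na(items$label)
  list(
    text = paste0(paste(items$text, collapse = " "), "."),
    entities = entity_table(starts[is_ent], starts[is_ent] + nchar(items$text[is_ent]),
                            items$text[is_ent], items$label[is_ent])
  )
}

#' Noise configuration for simulated generations
#'
#' Probabilities of the error modes observed qualitatively in generative
#' labelers: \code{p_format_corrupt} replaces the whole output with free text
#' (no JSON at all); the remaining channels mutate individual label records —
#' \code{p_drop} omits a gold record, \code{p_type_swap} replaces the type
#' with an off-schema name, \code{p_boundary_jitter} truncates or extends the
#' record text by one token. \code{p_hallucinate} adds, once per sentence, a
#' record whose text is drawn from a vocabulary disjoint from the corpus (so
#' it can never be found in the sentence). Per-record channels are mutually
#' exclusive (drop, then swap, then jitter), which keeps the injected-noise
#' ledger in 1:1 correspondence with post-processing outcomes.
#'
#' @param p_format_corrupt,p_hallucinate,p_type_swap,p_drop,p_boundary_jitter
#'   Channel probabilities in \code{[0, 1]}.
#' @param seed Integer seed.
#' @return An object of class \code{noise_config}.
#' @export
noise_config <- function(p_format_corrupt = 0, p_hallucinate = 0,
                         p_type_swap = 0, p_drop = 0, p_boundary_jitter = 0,
                         seed = 1L) {
  p <- c(p_format_corrupt, p_hallucinate, p_type_swap, p_drop, p_boundary_jitter)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(
    list(p_format_corrupt = p_format_corrupt, p_hallucinate = p_hallucinate,
         p_type_swap = p_type_swap, p_drop = p_drop,
         p_boundary_jitter = p_boundary_jitter, seed = as.integer(seed)),
    class = "noise_config"
  )
}

#' Simulate noisy labeler generations for a corpus
#'
#' Produces generation records exactly as a real backend would (prompt echo,
#' label payload, then a spurious new instruction block so generated-text
#' extraction and truncation are exercised), with noise injected per
#' [noise_config()]. Every injected mutation is logged in the returned
#' \code{ledger}, enabling exact accounting audits against post-processing
#' drop reasons.
#'
#' @param notes List of gold [note()] objects.
#' @param template A [prompt_template()].
#' @param noise A [noise_config()].
#' @param schema [task_schema()] used to type hallucinated records (in-schema,
#'   so only their unfindable text rejects them).
#' @param segmenter Sentence segmenter.
#' @return List with \code{records} (generation records), \code{sentences},
#'   and \code{ledger} (data.frame \code{sentence_id}, \code{channel},
#'   \code{text}, \code{type}).
#' @export
simulate_generations <- function(notes, template, noise = noise_config(),
                                 schema = task_schema("synthetic_meds",
                                                      c("Drug", "Dosage", "Frequency")),
                                 segmenter = rule_segmenter) {
  sentences <- unlist(lapply(notes, segment_note, segmenter = segmenter),
                      recursive = FALSE)
  set.seed(noise$seed)
  d <- template$dialect
  off_schema_names <- c("Medication", "Procedure", "Observation", "BodyPart")
  halluc <- synthetic_hallucination_vocab()
  ledger <- data.frame(sentence_id = character(0), channel = character(0),
                       text = character(0), type = character(0),
                       stringsAsFactors = FALSE)
  log_row <- function(sid, channel, text = NA_character_, type = NA_character_) {
    data.frame(sentence_id = sid, channel = channel, text = text, type = type,
               stringsAsFactors = FALSE)
  }
  records <- lapply(sentences, function(s) {
    prompt <- render_prompt(template, s$text)
    sid <- s$sentence_id
    if (stats::runif(1) < noise$p_format_corrupt) {
      ledger <<- rbind(ledger, log_row(sid, "format_corrupt"))
      payload <- "I am sorry, I could not find structured output for this sentence."
    } else {
      ents <- s$entities
      recs <- list()
      for (i in seq_len(nrow(ents))) {
        u <- stats::runif(1)
        txt <- ents$text[i]; typ <- ents$label[i]
        if (u < noise$p_drop) {
          ledger <<- rbind(ledger, log_row(sid, "drop", txt, typ))
          next
        } else if (u < noise$p_drop + noise$p_type_swap) {
          typ <- off_schema_names[sample.int(length(off_schema_names), 1L)]
          ledger <<- rbind(ledger, log_row(sid, "type_swap", txt, typ))
        } else if (u < noise$p_drop + noise$p_type_swap + noise$p_boundary_jitter) {
          txt <- jitter_text(txt, s$text, ents$start[i], ents$end[i])
          ledger <<- rbind(ledger, log_row(sid, "boundary_jitter", txt, typ))
        }
        recs[[length(recs) + 1L]] <- list(text = txt, type = typ)
      }
      if (stats::runif(1) < noise$p_hallucinate) {
        txt <- halluc[sample.int(length(halluc), 1L)]
        typ <- schema$entity_types[sample.int(length(schema$entity_types), 1L)]
        ledger <<- rbind(ledger, log_row(sid, "hallucinate", txt, typ))
        recs[[length(recs) + 1L]] <- list(text = txt, type = typ)
      }
      payload <- if (length(recs) == 0L) "[]" else
        as.character(jsonlite::toJSON(recs, auto_unbox = TRUE))
    }
    raw <- paste0(prompt, " ", payload, " ", d$instruction_open,
                  " Label the next sentence.")
    list(sentence_id = sid, prompt = prompt, raw_output = raw,
         echo = TRUE, error = FALSE, settings = generation_settings())
  })
  list(records = records, sentences = sentences, ledger = ledger)
}

# Truncate multi-token texts by their last token; extend single-token texts
# with the sentence's following characters up to the next token boundary.
jitter_text <- function(text, sentence_text, start, end) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  if (length(toks) >= 2L) {
    return(paste(toks[-length(toks)], collapse = " "))
  }
  rest <- substr0(sentence_text, end, nchar(sentence_text))
  m <- regexpr("^.[^ ]*", rest)
  if (m[1] == -1L) return(text)
  paste0(text, substr(rest, 1, attr(m, "match.length")))
}

#' @rdname backends
#' @param notes,template,noise,schema Arguments for [simulate_generations()];
#'   the corruptor backend precomputes noisy generations for the whole corpus
#'   and serves them by sentence id.
#' @export
corruptor_backend <- function(notes, template, noise = noise_config(),
                              schema = task_schema("synthetic_meds",
                                                   c("Drug", "Dosage", "Frequency"))) {
  sim <- simulate_generations(notes, template, noise, schema)
  outputs <- stats::setNames(
    vapply(sim$records, `[[`, character(1), "raw_output"),
    vapply(sim$records, `[[`, character(1), "sentence_id")
  )
  structure(list(outputs = outputs, echo = TRUE, ledger = sim$ledger),
            class = c("corruptor_backend", "ner_backend"))
}

#' @export
backend_generate.corruptor_backend <- function(backend, prompt, sentence_id) {
  out <- backend$outputs[[sentence_id]]
  if (is.null(out)) stop_weakner(sprintf("corruptor has no output for %s", sentence_id))
  out
}

#' Swap entity types within a schema
#'
#' Label-noise helper for weak-supervision experiments: each entity's type is
#' replaced, with probability \code{rate}, by a different type drawn uniformly
#' from the schema — a surviving wrong label rather than a dropped one.
#'
#' @param notes List of [note()] objects.
#' @param rate Swap probability per entity.
#' @param schema A [task_schema()].
#' @param seed Integer seed.
#' @return Notes with perturbed entity labels.
#' @export
perturb_entity_types <- function(notes, rate, schema, seed = 1L) {
  set.seed(seed)
  types <- schema$entity_types
  lapply(notes, function(n) {
    ents <- n$entities
    for (i in seq_len(nrow(ents))) {
      if (stats::runif(1) < rate) {
        others <- setdiff(types, ents$label[i])
        if (length(others) > 0L) {
          ents$label[i] <- others[sample.int(length(others), 1L)]
        }
      }
    }
    note(n$note_id, n$text, as_entity_table(ents))
  })
}
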