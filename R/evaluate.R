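#' Match gold and predicted entities
#'
#' One-to-one greedy matching within a note. Candidate pairs require label
#' equality and, under \code{strict}, identical (start, end); under
#' \code{lenient} (the "relaxed" convention), at least one character of
#' overlap. Candidates are taken in order of (overlap length descending, gold
#' start ascending, pred start ascending); each entity matches at most once.
#'
#' @param gold,pred [entity_table()]s scoped to one note.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return List with \code{tp} (data.frame of matched gold/pred row indices),
#'   \code{fp} (unmatched pred indices), \code{fn} (unmatched gold indices).
#' @export
match_entities <- function(gold, pred, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  pairs <- data.frame(g = integer(0), p = integer(0), overlap = integer(0))
  if (ng > 0L && np > 0L) {
    for (i in seq_len(ng)) {
      for (j in seq_len(np)) {
        if (gold$label[i] != pred$label[j]) next
        ov <- min(gold$end[i], pred$end[j]) - max(gold$start[i], pred$start[j])
        hit <- if (mode == "strict") {
          gold$start[i] == pred$start[j] && gold$end[i] == pred$end[j]
        } else {
          ov >= 1L
        }
        if (hit) {
          pairs <- rbind(pairs, data.frame(g = i, p = j, overlap = ov))
        }
      }
    }
  }
  tp <- data.frame(g = integer(0), p = integer(0))
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order(-pairs$overlap, gold$start[pairs$g], pred$start[pairs$p]), ]
    used_g <- logical(ng); used_p <- logical(np)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$g[k]; j <- pairs$p[k]
      if (!used_g[i] && !used_p[j]) {
        used_g[i] <- TRUE; used_p[j] <- TRUE
        tp <- rbind(tp, data.frame(g = i, p = j))
      }
    }
    fp <- which(!used_p); fn <- which(!used_g)
  } else {
    fp <- seq_len(np); fn <- seq_len(ng)
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Entity-level micro precision/recall/F1 over a corpus
#'
#' TP/FP/FN are pooled over notes and entity types before computing P, R and
#' F1 (micro averaging), with per-type rows alongside. The 0/0 convention is
#' 0 throughout, and F1 = 2PR/(P+R).
#'
#' @param gold_notes,pred_notes Lists of [note()] objects, aligned by
#'   \code{note_id}.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return An \code{eval_report}: \code{per_type} data.frame and micro
#'   \code{precision}, \code{recall}, \code{f1}, plus pooled counts.
#' @export
evaluate_corpus <- function(gold_notes, pred_notes, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  pred_by_id <- stats::setNames(pred_notes,
                                vapply(pred_notes, `[[`, character(1), "note_id"))
  types <- character(0)
  counts <- list()
  bump <- function(counts, label, what, by = 1L) {
    if (is.null(counts[[label]])) counts[[label]] <- c(tp = 0L, fp = 0L, fn = 0L)
    counts[[label]][what] <- counts[[label]][what] + by
    counts
  }
  for (gn in gold_notes) {
    pn <- pred_by_id[[gn$note_id]]
    pred <- if (is.null(pn)) entity_table() else pn$entities
    m <- match_entities(gn$entities, pred, mode)
    for (k in seq_len(nrow(m$tp))) {
      counts <- bump(counts, gn$entities$label[m$tp$g[k]], "tp")
    }
    for (j in m$fp) counts <- bump(counts, pred$label[j], "fp")
    for (i in m$fn) counts <- bump(counts, gn$entities$label[i], "fn")
  }
  per_type <- do.call(rbind, lapply(names(counts), function(lab) {
    cnt <- counts[[lab]]
    p <- prf(cnt[["tp"]], cnt[["fp"]])[["p"]]
    r <- prf(cnt[["tp"]], cnt[["fn"]])[["p"]]
    data.frame(label = lab, tp = cnt[["tp"]], fp = cnt[["fp"]], fn = cnt[["fn"]],
               precision = p, recall = r, f1 = f1_of(p, r),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(per_type)) {
    per_type <- data.frame(label = character(0), tp = integer(0), fp = integer(0),
                           fn = integer(0), precision = numeric(0),
                           recall = numeric(0), f1 = numeric(0))
  }
  tp <- sum(per_type$tp); fp <- sum(per_type$fp); fn <- sum(per_type$fn)
  p <- prf(tp, fp)[["p"]]
  r <- prf(tp, fn)[["p"]]
  structure(
    list(mode = mode, per_type = per_type, tp = tp, fp = fp, fn = fn,
         precision = p, recall = r, f1 = f1_of(p, r)),
    class = "eval_report"
  )
}

prf <- function(tp, other) {
  c(p = if (tp + other == 0) 0 else tp / (tp + other))
}

f1_of <- function(p, r) {
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' @rdname evaluate_corpus
#' @return \code{micro_f1}: the micro F1 number alone.
#' @export
micro_f1 <- function(gold_notes, pred_notes, mode = c("strict", "lenient")) {
  evaluate_corpus(gold_notes, pred_notes, mode)$f1
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Entity-level evaluation (%s matching)\n", x$mode))
  cat(sprintf("  micro P = %.4f  R = %.4f  F1 = %.4f  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  if (nrow(x$per_type) > 0L) {
    for (i in seq_len(nrow(x$per_type))) {
      r <- x$per_type[i, ]
      cat(sprintf("  %-12s P = %.4f  R = %.4f  F1 = %.4f\n",
                  r$label, r$precision, r$recall, r$f1))
    }
  }
  invisible(x)
}
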