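#' Decoder-model inference profile
#'
#' The architecture constants entering the closed-form inference cost of a
#' decoder-only transformer: total parameters N, layer count, input context
#' length in tokens (estimated from the rendered prompt template, see
#' [estimate_n_ctx()]), attention output dimension, and the number of tokens
#' generated per sentence.
#'
#' @param n_params Total parameters N.
#' @param n_layer Number of layers.
#' @param n_ctx Input context length (tokens).
#' @param d_attn Attention output dimension.
#' @param n_tokens_out Generated tokens per sentence.
#' @return An object of class \code{model_profile}.
#' @export
model_profile <- function(n_params, n_layer, n_ctx, d_attn, n_tokens_out) {
  vals <- c(n_params = n_params, n_layer = n_layer, n_ctx = n_ctx,
            d_attn = d_attn, n_tokens_out = n_tokens_out)
  if (any(vals < 0) || any(vals != trunc(vals))) {
    stop_weakner("model profile fields must be non-negative integers")
  }
  structure(as.list(vals), class = "model_profile")
}

#' Inference FLOPs per input sentence
#'
#' Closed-form cost of generating one sentence's labels with a decoder-only
#' transformer: each generated token costs about \code{2N} FLOPs for the
#' forward pass through the weights plus \code{2 n_layer n_ctx d_attn} for
#' attention over the context, so
#' \deqn{FLOPs = n_{tokens\_out} (2N + 2\, n_{layer} n_{ctx} d_{attn}).}
#' Computed in exact (double) integer arithmetic; all quantities here stay
#' far below 2^53 so no precision is lost.
#'
#' @param profile A [model_profile()].
#' @return The FLOPs count (a double holding an exact integer).
#' @export
flops_per_sentence <- function(profile) {
  stopifnot(inherits(profile, "model_profile"))
  profile$n_tokens_out *
    (2 * profile$n_params + 2 * profile$n_layer * profile$n_ctx * profile$d_attn)
}

#' Scientific rendering of a FLOPs count
#'
#' Renders with 4 significant digits, truncating (not rounding) the mantissa —
#' the convention of reported cost tables, e.g. 3,348,838,481,920 renders as
#' \code{"3.348e+12"}.
#'
#' @param x FLOPs count.
#' @param digits Significant digits (default 4).
#' @return A string like \code{"3.348e+12"}.
#' @export
format_flops <- function(x, digits = 4L) {
  if (x == 0) return("0")
  e <- floor(log10(abs(x)))
  mantissa <- trunc(x / 10^(e - digits + 1)) / 10^(digits - 1)
  sprintf("%.*fe+%02d", digits - 1L, mantissa, e)
}

#' Project total GPU time by linear regression
#'
#' Inference cost is linear in the number of processed notes, so total GPU
#' time for a large collection is projected from timed subsamples by ordinary
#' least squares of \code{gpu_seconds ~ n_notes}.
#'
#' @param samples data.frame with columns \code{n_notes}, \code{gpu_seconds}.
#' @param target_notes Collection size to project to.
#' @return List with \code{slope}, \code{intercept}, \code{projected_seconds},
#'   and the underlying \code{lm} fit.
#' @export
project_gpu_time <- function(samples, target_notes) {
  stopifnot(is.data.frame(samples),
            all(c("n_notes", "gpu_seconds") %in% names(samples)))
  if (nrow(samples) < 2L) stop_weakner("need at least 2 timing samples")
  if (length(unique(samples$n_notes)) < 2L) {
    stop_weakner("timing samples must include at least 2 distinct n_notes")
  }
  if (any(samples$n_notes < 0) || any(samples$gpu_seconds < 0)) {
    stop_weakner("timing samples must be non-negative")
  }
  fit <- stats::lm(gpu_seconds ~ n_notes, data = samples)
  co <- stats::coef(fit)
  list(
    slope = unname(co["n_notes"]),
    intercept = unname(co["(Intercept)"]),
    projected_seconds = unname(co["(Intercept)"] + co["n_notes"] * target_notes),
    fit = fit
  )
}
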