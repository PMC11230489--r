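# Internal helpers shared across modules.

# Substring by 0-based, half-open character offsets (the standoff convention
# used throughout the package). substr0("Took aspirin.", 5, 12) == "aspirin".
substr0 <- function(x, start, end) {
  substr(x, start + 1L, end)
}

# All occurrences of `pattern` (fixed string) in `x`, as a data.frame of
# 0-based half-open spans. Empty data.frame when absent.
find_all_fixed <- function(x, pattern) {
  if (nchar(pattern) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- as.integer(m) - 1L
  data.frame(start = start, end = start + nchar(pattern))
}

# 32-bit FNV-1a content hash, rendered as 8 hex digits. Used to key the
# replay generation store by prompt content. Arithmetic is done on doubles
# split into 16-bit halves so every intermediate stays exact (< 2^53).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_weakner <- function(...) stop(..., call. = FALSE)
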