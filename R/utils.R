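# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, keeping the
# result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# FNV-1a 32-bit hash of a character scalar; used to stamp outputs with a
# configuration fingerprint without external dependencies.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits (h and b are < 2^32; b < 256)
    lo <- bitwXor(h %% 65536, b)
    h <- (h %/% 65536) * 65536 + lo
    # exact 32-bit multiply by the FNV prime in double arithmetic
    h0 <- h %% 65536; h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Simple structured logging: messages are emitted via message() and can be
# suppressed; stage functions also return counts in their results.
kc_log <- function(fmt, ..., verbose = getOption("kelpcanopy.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
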