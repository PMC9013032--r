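# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `expr` is lazily evaluated after set.seed() runs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  expr
}

# Cheap deterministic content hash for run manifests (position-weighted
# byte sum, 31-bit). Not cryptographic; only used to detect rerun drift.
text_hash <- function(path) {
  bytes <- as.numeric(readBin(path, "raw", n = file.size(path)))
  m <- 2147483647
  w <- (seq_along(bytes) - 1) %% 9973 + 1
  h <- (sum(bytes * w) + 31 * length(bytes)) %% m
  sprintf("%08x", h)
}

stop_fatal <- function(...) stop(..., call. = FALSE)
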