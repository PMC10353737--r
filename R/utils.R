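# Internal helpers: seeded evaluation and seed-stream derivation.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# `seed = NULL` leaves the current RNG stream untouched, so nested seeded
# calls can share one stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based splitting of one master seed into independent sub-streams,
# so per-subject / per-repeat seeds do not depend on generation order.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647
  x <- as.double(seed) %% m
  for (k in c(as.double(index), as.double(stream))) {
    x <- (x * 48271 + (k + 1) * 8191 + 7) %% m
  }
  as.integer(x)
}

stop_insufficient <- function(...) {
  stop(structure(class = c("semgait_insufficient_data", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
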