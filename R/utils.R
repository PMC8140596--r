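# Internal helpers: seeded evaluation and seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a character scalar (portable across sessions).
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

# Derive a child seed (in [1, 2^31 - 1]) from a master seed and a stream of
# integer or character discriminators. Pure double arithmetic; all
# intermediates stay well below 2^53 so the result is exact.
derive_seed <- function(master, ...) {
  h <- abs(as.double(master)) %% 2147483647
  for (x in list(...)) {
    if (is.character(x)) x <- string_hash(x)
    h <- (h * 48271 + abs(as.double(x)) + 1) %% 2147483647
  }
  as.integer(h + 1)
}

detect_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","
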