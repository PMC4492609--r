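# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a base seed and one or more keys,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  keys <- c(seed, unlist(lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(k) else as.numeric(k)
  })))
  h <- 0
  for (k in keys) h <- (h * 31 + (k %% 100000)) %% 2147483629
  as.integer(h) + 1L
}

# Small polynomial content hash (for checkpoint <-> architecture pairing).
content_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 1000000007
  sprintf("%09d", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
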