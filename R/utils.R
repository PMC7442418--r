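# Internal helpers: scoped RNG seeding and a small config checksum.

# evaluate `expr` under set.seed(seed), restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# derive a child seed from a base seed and a stream label, kept < 2^31
.child_seed <- function(seed, label) {
  h <- .fnv1a(paste0(seed, ":", label))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a checksum of a character string (reproducibility stamp for
# run manifests; not cryptographic). Arithmetic in doubles, split into
# 16-bit halves so every intermediate stays exactly representable.
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  h
}

.config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 17)),
             collapse = "\n")
  h <- .fnv1a(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
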