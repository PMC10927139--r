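# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps classifier/CV randomness (fold shuffling,
# KNN tie-breaking) from consuming draws of the swarm's stream.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# FNV-1a over a string; used only to stamp a short reproducibility hash of the
# effective configuration into output files.
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    lo <- h %% 256  # xor touches only the low byte; keeps h a safe double
    h <- (h - lo) + bitwXor(as.integer(lo), b)
    # h * 16777619 mod 2^32, split as 403 + 2^24 to stay within double precision
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  keys <- sort(names(config))
  s <- paste(keys, vapply(config[keys], function(v) paste(format(v, digits = 12), collapse = ";"),
                          character(1)), sep = "=", collapse = "|")
  fnv1a_hash(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) stop(..., call. = FALSE)
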