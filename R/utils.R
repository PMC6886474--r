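# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards, so every stochastic operation is a pure
# function of its explicit seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seeds (always below 2^31) from a parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Cheap content digest (FNV-1a over the serialized object) used for
# provenance stamps in manifests and trained models.
content_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    h <- (sum(chunk * seq_along(chunk)) + h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment: per class, a seeded permutation dealt
# round-robin over folds; k = n degenerates to leave-one-out.
# Deterministic given (labels, k, seed).
stratified_folds <- function(labels, k, seed = NULL) {
  n <- length(labels)
  if (k > n) stop("fold count exceeds number of rows", call. = FALSE)
  if (k == n) return(seq_len(n))
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
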