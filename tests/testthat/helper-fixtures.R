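# Fixtures are built in code; no data files.

# A tiny fully-specified labeled table for closed-form checks.
tiny_table <- function() {
  vals <- cbind(
    f_sep  = c(0, 0, 0, 1, 1, 1),            # equals the class
    f_cont = c(1.2, 0.4, -0.3, 2.5, 1.9, 3.1),
    f_bit  = c(0, 1, 0, 1, 1, 0),
    f_zero = rep(2, 6))
  rownames(vals) <- paste0("c", 1:6)
  feature_table(vals,
                labels = rep(c("inactive", "active"), each = 3),
                ic50 = c(NA, NA, NA, 0.5, 2.2, 8.0),
                source = rep(c("decoy", "active_source"), each = 3))
}

# Random labeled table with d iid continuous columns (no planted signal
# unless effect > 0 on the first n_signal columns).
random_table <- function(n = 60, d = 8, effect = 0, n_signal = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  vals <- matrix(rnorm(n * d), n, d,
                 dimnames = list(sprintf("r%03d", 1:n), sprintf("v%02d", 1:d)))
  if (n_signal > 0) {
    vals[, seq_len(n_signal)] <- vals[, seq_len(n_signal)] + effect * y
  }
  feature_table(vals, labels = ifelse(y == 1, "active", "inactive"))
}

# Independent O(n^2) pair-counting Kendall tau-a oracle.
tau_a_oracle <- function(x, y) {
  n <- length(x)
  cd <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cd <- cd + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  cd / (n * (n - 1) / 2)
}

# Literal transcription of the CFS merit, computed from first
# principles (no shared code with the package implementation).
merit_oracle <- function(values, y01, cols) {
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    s <- sqrt(sum(am^2) * sum(bm^2))
    if (s == 0) 0 else sum(am * bm) / s
  }
  k <- length(cols)
  rcf <- mean(vapply(cols, function(j) abs(pearson(values[, j], y01)),
                     numeric(1)))
  rff <- 0
  if (k > 1) {
    pairs <- utils::combn(cols, 2)
    rff <- mean(apply(pairs, 2, function(p) {
      abs(pearson(values[, p[1]], values[, p[2]]))
    }))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# All-pairs concordance AUC oracle (ties count one half).
auc_oracle <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Popcount Tanimoto oracle.
tanimoto_oracle <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

# Deterministic label permutation for null-distribution checks.
with_seed_labels <- function(labels, seed) {
  set.seed(seed)
  sample(labels)
}
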