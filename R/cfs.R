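#' Feature-class correlation magnitude
#'
#' Absolute Pearson correlation between one feature column and the
#' class encoded as \{0, 1\} (point-biserial for continuous columns, phi
#' for binary ones). A zero-variance column is defined to have
#' correlation 0.
#'
#' @param table a labeled [feature_table()].
#' @param col a column identifier (name or index).
#' @return a magnitude in \[0, 1\].
#' @export
class_feature_correlation <- function(table, col) {
  y <- class01(table)
  x <- table$values[, col]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(x, y))
}

# Precomputed correlation structure reused by every search strategy:
# rcf (feature-class magnitudes) and rff (feature-feature |Pearson|).
cfs_cache <- function(table) {
  y <- class01(table)
  X <- table$values
  sds <- apply(X, 2, stats::sd)
  rcf <- rep(0, ncol(X))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) rcf[ok] <- abs(stats::cor(X[, ok, drop = FALSE], y))
  names(rcf) <- colnames(X)
  rff <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  if (any(ok)) {
    rff[ok, ok] <- abs(stats::cor(X[, ok, drop = FALSE]))
  }
  diag(rff) <- 1
  list(rcf = rcf, rff = rff, ids = colnames(X))
}

# Merit of a subset given the cache; `cols` are integer indices.
merit_from_cache <- function(cache, cols) {
  k <- length(cols)
  rcf_bar <- mean(cache$rcf[cols])
  rff_bar <- if (k < 2) 0 else {
    sub <- cache$rff[cols, cols]
    sum(sub[upper.tri(sub)]) / (k * (k - 1) / 2)
  }
  denom <- sqrt(k + k * (k - 1) * rff_bar)
  list(merit = k * rcf_bar / denom, k = k,
       mean_class_corr = rcf_bar, mean_inter_corr = rff_bar)
}

#' CFS merit of a feature subset
#'
#' The correlation-based feature selection heuristic
#' \deqn{Merit_S = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}}
#' where `k` is the subset size, `r_cf` the mean feature-class
#' correlation magnitude and `r_ff` the mean within-subset
#' feature-feature |Pearson| correlation (0 when `k = 1`). High merit
#' rewards relevance and penalizes redundancy.
#'
#' @param table a labeled [feature_table()].
#' @param columns non-empty vector of column identifiers.
#' @return a `merit_score`: list with `merit`, `k`, `mean_class_corr`,
#'   `mean_inter_corr`.
#' @export
merit <- function(table, columns) {
  if (length(columns) == 0) stop("empty subset", call. = FALSE)
  idx <- if (is.character(columns)) match(columns, col_ids(table)) else columns
  if (anyNA(idx)) {
    stop("unknown column(s): ",
         paste(columns[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("duplicate columns in subset", call. = FALSE)
  structure(merit_from_cache(cfs_cache(table), idx), class = "merit_score")
}

new_feature_subset <- function(cache, cols, selector, dataset_name = NA_character_) {
  sc <- merit_from_cache(cache, cols)
  structure(list(columns = cache$ids[cols],
                 score = structure(sc, class = "merit_score"),
                 selector = selector, dataset_name = dataset_name),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %s: k=%d merit=%.4f (rcf=%.3f, rff=%.3f)\n",
              x$selector, x$score$k, x$score$merit,
              x$score$mean_class_corr, x$score$mean_inter_corr))
  cat("  ", paste(x$columns, collapse = ", "), "\n")
  invisible(x)
}

# Global subset ordering: higher merit, then smaller k, then
# lexicographically smallest (by column position sequence). Merits
# within 1e-12 relative tolerance count as tied so that floating-point
# fuzz (e.g. cor(x, x) != 1 exactly) cannot defeat the size tie-break.
better_than <- function(merit_a, cols_a, merit_b, cols_b) {
  if (is.infinite(merit_a) || is.infinite(merit_b)) {
    if (merit_a != merit_b) return(merit_a > merit_b)
  } else if (abs(merit_a - merit_b) >
             1e-12 * max(1, abs(merit_a), abs(merit_b))) {
    return(merit_a > merit_b)
  }
  if (length(cols_a) != length(cols_b)) return(length(cols_a) < length(cols_b))
  a <- sort(cols_a); b <- sort(cols_b)
  diff <- which(a != b)
  if (!length(diff)) return(FALSE)
  a[diff[1]] < b[diff[1]]
}

#' Exhaustive subset search (test oracle)
#'
#' Enumerates every non-empty column subset and returns the one with
#' maximal merit; refuses more than `max_dim` columns. Ties are broken
#' by smaller size, then lexicographically. Intended as the oracle
#' against which the heuristic searchers are validated.
#'
#' @param table a labeled [feature_table()].
#' @param max_dim guard on the number of candidate columns (default 15).
#' @return a `feature_subset` with selector `"EXHAUSTIVE"`.
#' @export
exhaustive_search <- function(table, max_dim = 15) {
  d <- ncol(table$values)
  if (d > max_dim) {
    stop("exhaustive_search: ", d, " columns exceed max_dim = ", max_dim,
         "; use a heuristic searcher (best_first_search, ssfs_search, ...)",
         call. = FALSE)
  }
  cache <- cfs_cache(table)
  best_cols <- NULL; best_merit <- -Inf
  for (mask in seq_len(2^d - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
    m <- merit_from_cache(cache, cols)$merit
    if (is.null(best_cols) || better_than(m, cols, best_merit, best_cols)) {
      best_cols <- cols; best_merit <- m
    }
  }
  new_feature_subset(cache, best_cols, "EXHAUSTIVE")
}

#' Best-first search configuration
#' @param patience consecutive non-improving expansions before stopping
#'   (default 5).
#' @param backtracking whether to fall back to the next-best open node
#'   (default `TRUE`; `FALSE` degenerates to greedy forward selection).
#' @return a `bf_config` object.
#' @export
bf_config <- function(patience = 5, backtracking = TRUE) {
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  structure(list(patience = patience, backtracking = backtracking),
            class = "bf_config")
}

#' Best-first forward search over the subset lattice
#'
#' Starts from the empty set, expands the best open node by all
#' single-column additions, backtracks to the next-best open node when
#' an expansion yields no improvement, and stops after `patience`
#' consecutive expansions that fail to improve the best subset seen.
#'
#' @param table a labeled [feature_table()].
#' @param config a [bf_config()].
#' @return a `feature_subset` with selector `"BF"`.
#' @export
best_first_search <- function(table, config = bf_config()) {
  d <- ncol(table$values)
  if (d < 1) stop("no candidate columns", call. = FALSE)
  cache <- cfs_cache(table)
  # open list keyed by subset signature; start from the empty set
  open <- list(list(cols = integer(0), merit = -Inf))
  seen <- new.env(hash = TRUE)
  assign("s:", TRUE, envir = seen)
  best_cols <- NULL; best_merit <- -Inf
  stale <- 0
  while (length(open) > 0 && stale < config$patience) {
    pick <- 1
    for (i in seq_along(open)) {
      if (better_than(open[[i]]$merit, open[[i]]$cols,
                      open[[pick]]$merit, open[[pick]]$cols)) pick <- i
    }
    node <- open[[pick]]
    open[[pick]] <- NULL
    improved <- FALSE
    for (j in setdiff(seq_len(d), node$cols)) {
      cols <- sort(c(node$cols, j))
      key <- paste0("s:", paste(cols, collapse = ","))
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      m <- merit_from_cache(cache, cols)$merit
      open[[length(open) + 1]] <- list(cols = cols, merit = m)
      if (is.null(best_cols) || better_than(m, cols, best_merit, best_cols)) {
        best_cols <- cols; best_merit <- m; improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
    if (!config$backtracking && length(open) > 0) {
      # greedy mode: keep only children of the current node
      keep <- vapply(open, function(nd) length(nd$cols) > length(node$cols),
                     logical(1))
      open <- open[keep]
    }
  }
  new_feature_subset(cache, best_cols, "BF")
}

#' Genetic search configuration
#' @param generations,population GA loop sizes (defaults 20 / 20).
#' @param p_crossover single-point crossover probability (default 0.6).
#' @param p_mutation per-individual mutation rate: with this
#'   probability one uniformly chosen bit is flipped (default 0.33).
#' @param seed RNG seed.
#' @return a `gs_config` object.
#' @export
gs_config <- function(generations = 20, population = 20,
                      p_crossover = 0.6, p_mutation = 0.33, seed = 1L) {
  stopifnot(generations >= 1, population >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(generations = generations, population = population,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 seed = as.integer(seed)),
            class = "gs_config")
}

# merit of a bitstring individual (repairing empty ones to a random singleton)
ga_fitness <- function(cache, bits) {
  if (!any(bits)) bits[sample.int(length(bits), 1)] <- TRUE
  list(bits = bits, merit = merit_from_cache(cache, which(bits))$merit)
}

#' Genetic search over inclusion bitstrings
#'
#' Fitness-proportional (roulette) selection, single-point crossover,
#' per-individual single-bit mutation, and one-elitism; returns the
#' best subset encountered across all generations. Fully reproducible
#' from the config seed.
#'
#' @param table a labeled [feature_table()].
#' @param config a [gs_config()].
#' @return a `feature_subset` with selector `"GS"`.
#' @export
genetic_search <- function(table, config = gs_config()) {
  d <- ncol(table$values)
  cache <- cfs_cache(table)
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i) {
      ga_fitness(cache, stats::runif(d) < 0.5)
    })
    best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "merit"))]]
    for (gen in seq_len(config$generations)) {
      fit <- vapply(pop, `[[`, numeric(1), "merit")
      w <- fit - min(fit) + 1e-9
      parents <- sample.int(length(pop), 2 * length(pop),
                            replace = TRUE, prob = w)
      nxt <- vector("list", length(pop))
      for (i in seq_along(pop)) {
        a <- pop[[parents[2 * i - 1]]]$bits
        b <- pop[[parents[2 * i]]]$bits
        child <- a
        if (stats::runif(1) < config$p_crossover && d > 1) {
          cut <- sample.int(d - 1, 1)
          child <- c(a[seq_len(cut)], b[(cut + 1):d])
        }
        if (stats::runif(1) < config$p_mutation) {
          flip <- sample.int(d, 1)
          child[flip] <- !child[flip]
        }
        nxt[[i]] <- ga_fitness(cache, child)
      }
      # one-elitism: carry the best-so-far into the new generation
      worst <- which.min(vapply(nxt, `[[`, numeric(1), "merit"))
      nxt[[worst]] <- best
      pop <- nxt
      cand <- pop[[which.max(vapply(pop, `[[`, numeric(1), "merit"))]]
      if (better_than(cand$merit, which(cand$bits), best$merit,
                      which(best$bits))) {
        best <- cand
      }
    }
    new_feature_subset(cache, which(best$bits), "GS")
  })
}

#' Geometric PSO configuration
#'
#' Convex weights for the three-parent mask recombination: inertia
#' (`w1`, keep the current position's bit), social (`w2`, inherit from
#' the global best) and individual (`w3`, inherit from the particle's
#' own best). Must be positive and sum to 1 (defaults 0.33/0.33/0.34).
#'
#' @param w1,w2,w3 convex weights.
#' @param particles,iterations swarm size and rounds (defaults 20 / 20).
#' @param p_bitflip optional per-bit mutation rate after recombination
#'   (default 0: pure convex-combination updates).
#' @param seed RNG seed.
#' @return a `gpso_config` object.
#' @export
gpso_config <- function(w1 = 0.33, w2 = 0.33, w3 = 0.34,
                        particles = 20, iterations = 20,
                        p_bitflip = 0, seed = 1L) {
  if (w1 < 0 || w2 < 0 || w3 < 0 || abs(w1 + w2 + w3 - 1) > 1e-9) {
    stop("configuration error: GPSO weights must be >= 0 and sum to 1",
         call. = FALSE)
  }
  stopifnot(particles >= 1, iterations >= 0)
  structure(list(w1 = w1, w2 = w2, w3 = w3, particles = particles,
                 iterations = iterations, p_bitflip = p_bitflip,
                 seed = as.integer(seed)),
            class = "gpso_config")
}

#' Geometric particle swarm search in binary subset space
#'
#' Each particle is an inclusion bitstring; its update is the
#' three-parent convex mask recombination
#' `x_i <- CX((x_i, w1), (g, w2), (p_i, w3))`: per bit, the new value is
#' inherited from the current position with probability `w1`, from the
#' global best `g` with probability `w2`, or from the particle's own
#' best `p_i` with probability `w3`. Bests are updated by merit.
#'
#' @param table a labeled [feature_table()].
#' @param config a [gpso_config()].
#' @return a `feature_subset` with selector `"PSO"`.
#' @export
gpso_search <- function(table, config = gpso_config()) {
  d <- ncol(table$values)
  cache <- cfs_cache(table)
  with_seed(config$seed, {
    pos <- lapply(seq_len(config$particles), function(i) {
      ga_fitness(cache, stats::runif(d) < 0.5)
    })
    pbest <- pos
    gi <- which.max(vapply(pos, `[[`, numeric(1), "merit"))
    gbest <- pos[[gi]]
    for (it in seq_len(config$iterations)) {
      for (i in seq_len(config$particles)) {
        u <- stats::runif(d)
        bits <- ifelse(u < config$w1, pos[[i]]$bits,
                       ifelse(u < config$w1 + config$w2,
                              gbest$bits, pbest[[i]]$bits))
        if (config$p_bitflip > 0) {
          flip <- stats::runif(d) < config$p_bitflip
          bits[flip] <- !bits[flip]
        }
        if (!any(bits)) bits <- pos[[i]]$bits  # keep position; empty is invalid
        cand <- list(bits = bits,
                     merit = merit_from_cache(cache, which(bits))$merit)
        pos[[i]] <- cand
        if (better_than(cand$merit, which(cand$bits),
                        pbest[[i]]$merit, which(pbest[[i]]$bits))) {
          pbest[[i]] <- cand
        }
        if (better_than(cand$merit, which(cand$bits),
                        gbest$merit, which(gbest$bits))) {
          gbest <- cand
        }
      }
    }
    new_feature_subset(cache, which(gbest$bits), "PSO")
  })
}

#' Subset-size forward selection configuration
#' @param top_k size of the rank-filtered search space (default 50).
#' @param folds cross-validation folds used to choose the subset size
#'   (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return a `ssfs_config` object.
#' @export
ssfs_config <- function(top_k = 50, folds = 5, seed = 1L) {
  stopifnot(top_k >= 1, folds >= 2)
  structure(list(top_k = top_k, folds = folds, seed = as.integer(seed)),
            class = "ssfs_config")
}

# greedy forward path within `space` (integer indices); returns list of
# cumulative subsets of size 1..length(space)
forward_path <- function(cache, space) {
  sel <- integer(0)
  path <- vector("list", length(space))
  remaining <- space
  for (s in seq_along(space)) {
    best_j <- NA_integer_; best_m <- -Inf; best_cols <- NULL
    for (j in remaining) {
      cols <- c(sel, j)
      m <- merit_from_cache(cache, cols)$merit
      if (is.na(best_j) || better_than(m, cols, best_m, best_cols)) {
        best_j <- j; best_m <- m; best_cols <- cols
      }
    }
    sel <- c(sel, best_j)
    remaining <- setdiff(remaining, best_j)
    path[[s]] <- sel
  }
  path
}

#' Subset-size forward selection (SSFS)
#'
#' Linear forward selection restricted to the `top_k` columns ranked by
#' feature-class correlation, with the subset size chosen by k-fold
#' cross-validation: per fold, correlations are recomputed on the
#' training portion, the forward path rebuilt, and each size's subset
#' scored by its merit on the held-out portion; the chosen size is the
#' smallest whose mean held-out merit lies within one standard error of
#' the maximum (the 1-SE rule, which keeps subsets compact under fold
#' noise). The returned subset is the full-data forward path cut at
#' that size.
#'
#' @param table a labeled [feature_table()].
#' @param config a [ssfs_config()].
#' @return a `feature_subset` with selector `"SSFS"`.
#' @export
ssfs_search <- function(table, config = ssfs_config()) {
  d <- ncol(table$values)
  if (d < 1) stop("no candidate columns", call. = FALSE)
  top_k <- config$top_k
  if (top_k > d) {
    warning("ssfs: top_k = ", top_k, " clamped to ", d, " available columns")
    top_k <- d
  }
  cache <- cfs_cache(table)
  rank_space <- function(ca) order(ca$rcf, decreasing = TRUE)[seq_len(top_k)]
  space <- rank_space(cache)
  if (top_k == 1) {
    return(new_feature_subset(cache, space, "SSFS"))
  }
  folds <- stratified_folds(table$labels, config$folds, config$seed)
  heldout <- matrix(NA_real_, config$folds, top_k)
  for (f in seq_len(config$folds)) {
    tr <- ft_subset(table, rows = folds != f)
    te <- ft_subset(table, rows = folds == f)
    ca_tr <- cfs_cache(tr)
    ca_te <- cfs_cache(te)
    path <- forward_path(ca_tr, rank_space(ca_tr))
    for (s in seq_len(top_k)) {
      heldout[f, s] <- merit_from_cache(ca_te, path[[s]])$merit
    }
  }
  mean_heldout <- colMeans(heldout)
  # one-standard-error rule: the smallest size whose mean held-out merit
  # is within 1 SE of the best keeps the subset compact under fold noise
  s_max <- which.max(mean_heldout)
  se <- stats::sd(heldout[, s_max]) / sqrt(config$folds)
  s_star <- which(mean_heldout >= mean_heldout[s_max] - se)[1]
  full_path <- forward_path(cache, space)
  new_feature_subset(cache, sort(full_path[[s_star]]), "SSFS")
}

#' Feature-reduction rate
#'
#' Fraction of features removed by a selection step:
#' `(n_before - n_selected) / n_before`.
#'
#' @param n_before feature count before selection (>= 1).
#' @param n_selected selected feature count (0 <= n_selected <= n_before).
#' @return a fraction in \[0, 1\].
#' @export
reduction_rate <- function(n_before, n_selected) {
  if (n_before < 1 || n_selected < 0 || n_selected > n_before) {
    stop("need 0 <= n_selected <= n_before and n_before >= 1", call. = FALSE)
  }
  (n_before - n_selected) / n_before
}
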