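#' Specification for a synthetic compound dataset
#'
#' Describes a labeled compound-by-feature table with planted structure:
#' class-informative columns, near-duplicate (redundant) columns,
#' zero-variance columns and pure-noise columns, in a configurable mix
#' of binary "fingerprint bits" and continuous "descriptors". Defaults
#' mirror the study composition this package was built around: 266
#' actives vs 136 decoys (402 compounds), roughly half the columns
#' binary (the descriptor/fingerprint split of a typical 2D feature
#' matrix), and a standardized effect size of 1.
#'
#' Continuous features are Normal(0, 1) for inactives and
#' Normal(`effect_size`, 1) for actives; binary bits are Bernoulli(0.3)
#' vs Bernoulli(0.3 + gap) with `gap = min(0.2 * effect_size, 0.6)`.
#' Simulated IC50 values for actives are log-uniform on
#' \[0.05, 11.4\] uM so that all five canonical activity thresholds
#' partition the actives nontrivially; decoys carry no IC50.
#'
#' @param n_active,n_inactive class sizes (defaults 266 / 136).
#' @param n_informative,n_redundant,n_zero_variance,n_noise column
#'   counts by role.
#' @param frac_binary share of columns emitted as binary bits.
#' @param effect_size standardized active-vs-inactive mean shift
#'   (continuous) and the knob behind the Bernoulli rate gap (binary).
#' @param redundancy_noise per-entry corruption rate applied when
#'   copying a source column into a redundant near-duplicate; must be
#'   in \[0, 0.5).
#' @param ic50_range range (uM) of the log-uniform simulated IC50.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 266, n_inactive = 136,
                           n_informative = 20, n_redundant = 10,
                           n_zero_variance = 10, n_noise = 60,
                           frac_binary = 0.46, effect_size = 1,
                           redundancy_noise = 0.01,
                           ic50_range = c(0.05, 11.4), seed = 1L) {
  spec <- structure(
    list(n_active = n_active, n_inactive = n_inactive,
         n_informative = n_informative, n_redundant = n_redundant,
         n_zero_variance = n_zero_variance, n_noise = n_noise,
         frac_binary = frac_binary, effect_size = effect_size,
         redundancy_noise = redundancy_noise,
         ic50_range = ic50_range, seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  cnt <- c("n_active", "n_inactive", "n_informative", "n_redundant",
           "n_zero_variance", "n_noise")
  for (f in cnt) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      stop("invalid synthetic_spec: `", f, "` must be a non-negative count",
           call. = FALSE)
    }
  }
  d <- spec$n_informative + spec$n_redundant + spec$n_zero_variance + spec$n_noise
  if (d < 1) {
    stop("invalid synthetic_spec: total column count must be >= 1 ",
         "(n_informative + n_redundant + n_zero_variance + n_noise)",
         call. = FALSE)
  }
  if (spec$frac_binary < 0 || spec$frac_binary > 1) {
    stop("invalid synthetic_spec: `frac_binary` must be in [0, 1]", call. = FALSE)
  }
  if (spec$effect_size < 0) {
    stop("invalid synthetic_spec: `effect_size` must be >= 0", call. = FALSE)
  }
  if (spec$redundancy_noise < 0 || spec$redundancy_noise >= 0.5) {
    stop("invalid synthetic_spec: `redundancy_noise` must be in [0, 0.5)",
         call. = FALSE)
  }
  if (spec$n_redundant > 0 && spec$n_informative < 1) {
    stop("invalid synthetic_spec: `n_redundant` requires n_informative >= 1",
         call. = FALSE)
  }
  invisible(spec)
}

# Column layout (ids, role tags, kinds, redundant sources) is drawn from
# its own seed block so that changing one block's count does not perturb
# the values generated in another block.
synthetic_layout <- function(spec) {
  d <- spec$n_informative + spec$n_redundant + spec$n_zero_variance + spec$n_noise
  role <- rep(c("informative", "redundant", "zero-variance", "noise"),
              c(spec$n_informative, spec$n_redundant,
                spec$n_zero_variance, spec$n_noise))
  ids <- sprintf("%s_%03d", c(informative = "inf", redundant = "red",
                              `zero-variance` = "zv", noise = "nse")[role],
                 as.integer(stats::ave(seq_len(d), role, FUN = seq_along)))
  seeds <- derive_seeds(spec$seed, 6L)
  n_bin <- round(spec$frac_binary * d)
  kind <- rep("continuous", d)
  src <- rep(NA_character_, d)
  with_seed(seeds[1], {
    if (n_bin > 0) kind[sample.int(d, n_bin)] <- "binary"
    if (spec$n_redundant > 0) {
      inf_idx <- which(role == "informative")
      # near-duplicates of *continuous* sources where possible: duplicated
      # binary bits are invisible to a tau-a redundancy filter (ties count
      # as neither concordant nor discordant)
      pool <- inf_idx[kind[inf_idx] == "continuous"]
      if (!length(pool)) pool <- inf_idx
      pick <- pool[sample.int(length(pool), spec$n_redundant, replace = TRUE)]
      src[role == "redundant"] <- ids[pick]
      kind[role == "redundant"] <- kind[pick]
    }
  })
  list(d = d, role = role, ids = ids, kind = kind, src = src, seeds = seeds)
}

# Draw one column block. `cls` is the 0/1 class vector.
synthetic_block <- function(spec, lay, which_role, cls, seed) {
  idx <- which(lay$role == which_role)
  n <- length(cls)
  out <- matrix(0, n, length(idx))
  gap <- min(0.2 * spec$effect_size, 0.6)
  with_seed(seed, {
    for (j in seq_along(idx)) {
      k <- lay$kind[idx[j]]
      out[, j] <- switch(
        which_role,
        informative = if (k == "binary") {
          stats::rbinom(n, 1, 0.3 + gap * cls)
        } else {
          stats::rnorm(n, spec$effect_size * cls, 1)
        },
        noise = if (k == "binary") stats::rbinom(n, 1, 0.3) else stats::rnorm(n),
        `zero-variance` = rep(if (k == "binary") 1 else 7.5, n),
        stop("unknown role"))
    }
  })
  out
}

# Corrupt a copy of `src_col`: binary entries flip, continuous entries are
# re-drawn from the class-conditional marginal.
corrupt_copy <- function(spec, src_col, kind, cls) {
  n <- length(src_col)
  hit <- stats::runif(n) < spec$redundancy_noise
  out <- src_col
  if (any(hit)) {
    if (kind == "binary") {
      out[hit] <- 1 - out[hit]
    } else {
      out[hit] <- stats::rnorm(sum(hit), spec$effect_size * cls[hit], 1)
    }
  }
  out
}

#' Generate a labeled synthetic training dataset
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `generated_dataset`: a list with `table`
#'   (a labeled [feature_table()] carrying simulated IC50s for actives),
#'   `truth` (a data.frame of per-column role tags, with
#'   `redundant-of:<col>` pointers for near-duplicates) and `ic50`
#'   (the per-active simulated IC50 in uM).
#' @export
generate_training_dataset <- function(spec) {
  validate_synthetic_spec(spec)
  lay <- synthetic_layout(spec)
  n <- spec$n_active + spec$n_inactive
  cls <- rep(c(1, 0), c(spec$n_active, spec$n_inactive))
  vals <- matrix(NA_real_, n, lay$d,
                 dimnames = list(sprintf("cmpd_%05d", seq_len(n)), lay$ids))
  vals[, lay$role == "informative"] <-
    synthetic_block(spec, lay, "informative", cls, lay$seeds[2])
  vals[, lay$role == "zero-variance"] <-
    synthetic_block(spec, lay, "zero-variance", cls, lay$seeds[4])
  vals[, lay$role == "noise"] <-
    synthetic_block(spec, lay, "noise", cls, lay$seeds[5])
  if (spec$n_redundant > 0) {
    red_idx <- which(lay$role == "redundant")
    with_seed(lay$seeds[3], {
      for (j in red_idx) {
        vals[, j] <- corrupt_copy(spec, vals[, lay$src[j]], lay$kind[j], cls)
      }
    })
  }
  ic50 <- rep(NA_real_, n)
  with_seed(lay$seeds[6], {
    lo <- log(spec$ic50_range[1]); hi <- log(spec$ic50_range[2])
    ic50[cls == 1] <- exp(stats::runif(spec$n_active, lo, hi))
  })
  tbl <- feature_table(
    vals, col_kind = lay$kind,
    labels = ifelse(cls == 1, "active", "inactive"),
    ic50 = ic50,
    source = ifelse(cls == 1, "active_source", "decoy"))
  truth <- data.frame(
    col_id = lay$ids,
    role = ifelse(lay$role == "redundant",
                  paste0("redundant-of:", lay$src), lay$role),
    stringsAsFactors = FALSE)
  structure(list(table = tbl, truth = truth, ic50 = ic50, spec = spec),
            class = "generated_dataset")
}

#' Generate an unlabeled synthetic screening library
#'
#' Rows are drawn from the same generative model as
#' [generate_training_dataset()] under the same `spec` (so the column
#' schema is identical); a `planted_active_fraction` share of rows
#' (rounded to the nearest count) is drawn from the active-class
#' distribution, the rest from the inactive one. The returned table is
#' unlabeled; the planted-row mask is kept separately for evaluation.
#'
#' @param spec the [synthetic_spec()] the training dataset was built from.
#' @param n_compounds number of library rows (>= 1).
#' @param planted_active_fraction fraction in \[0, 1\].
#' @param schema_from optional training `feature_table` whose column set
#'   the library must match; a mismatch with the spec layout is an error.
#' @return a `generated_dataset` whose `truth` carries `planted_active`.
#' @export
generate_screening_library <- function(spec, n_compounds,
                                       planted_active_fraction,
                                       schema_from = NULL) {
  validate_synthetic_spec(spec)
  if (n_compounds < 1) stop("`n_compounds` must be >= 1", call. = FALSE)
  if (planted_active_fraction < 0 || planted_active_fraction > 1) {
    stop("`planted_active_fraction` must be in [0, 1]", call. = FALSE)
  }
  lay <- synthetic_layout(spec)
  if (!is.null(schema_from)) {
    if (!identical(col_ids(schema_from), lay$ids)) {
      stop("schema error: library columns do not match the training table",
           call. = FALSE)
    }
  }
  n_act <- round(n_compounds * planted_active_fraction)
  lib_seeds <- derive_seeds(spec$seed + 1L, 4L)
  cls <- rep(0, n_compounds)
  with_seed(lib_seeds[1], {
    if (n_act > 0) cls[sample.int(n_compounds, n_act)] <- 1
  })
  vals <- matrix(NA_real_, n_compounds, lay$d,
                 dimnames = list(sprintf("lib_%07d", seq_len(n_compounds)),
                                 lay$ids))
  vals[, lay$role == "informative"] <-
    synthetic_block(spec, lay, "informative", cls, lib_seeds[2])
  vals[, lay$role == "zero-variance"] <-
    synthetic_block(spec, lay, "zero-variance", cls, lib_seeds[3])
  vals[, lay$role == "noise"] <-
    synthetic_block(spec, lay, "noise", cls, lib_seeds[4])
  if (spec$n_redundant > 0) {
    red_idx <- which(lay$role == "redundant")
    with_seed(lib_seeds[1] + 1L, {
      for (j in red_idx) {
        vals[, j] <- corrupt_copy(spec, vals[, lay$src[j]], lay$kind[j], cls)
      }
    })
  }
  tbl <- feature_table(vals, col_kind = lay$kind)
  truth <- data.frame(row_id = rownames(vals), planted_active = cls == 1,
                      stringsAsFactors = FALSE)
  structure(list(table = tbl, truth = truth, spec = spec),
            class = "generated_dataset")
}

#' @export
print.generated_dataset <- function(x, ...) {
  cat("<generated_dataset>\n")
  print(x$table)
  if ("role" %in% names(x$truth)) {
    cat("  roles:", paste(sprintf("%s=%d", names(table(sub(":.*", "", x$truth$role))),
                                  table(sub(":.*", "", x$truth$role))),
                          collapse = " "), "\n")
  }
  invisible(x)
}
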