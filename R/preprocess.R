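#' Canonical activity thresholds
#'
#' The five IC50 cutoffs (uM) used to binarize activity into five
#' datasets: SET01 = 4, SET02 = 3, SET03 = 2, SET04 = 1 and
#' SET05 = 11.4 (the maximum observed IC50, under which every assayed
#' compound is active and every decoy inactive).
#'
#' @param cutoff_um IC50 cutoff in uM (> 0).
#' @param name dataset label, e.g. `"SET01"`.
#' @return an `activity_threshold` object.
#' @export
activity_threshold <- function(cutoff_um, name = sprintf("T%.3g", cutoff_um)) {
  if (!is.numeric(cutoff_um) || length(cutoff_um) != 1 || cutoff_um <= 0) {
    stop("`cutoff_um` must be a single positive number", call. = FALSE)
  }
  structure(list(cutoff_um = cutoff_um, name = name),
            class = "activity_threshold")
}

#' @rdname activity_threshold
#' @export
canonical_thresholds <- function() {
  mapply(activity_threshold,
         cutoff_um = c(4, 3, 2, 1, 11.4),
         name = c("SET01", "SET02", "SET03", "SET04", "SET05"),
         SIMPLIFY = FALSE)
}

#' Binarize activity under an IC50 threshold
#'
#' Rows from the assayed (non-decoy) source are labeled `active` iff
#' their IC50 is less than or equal to the cutoff; decoy rows stay
#' `inactive` regardless. All feature data is left untouched.
#'
#' @param table a [feature_table()] with IC50s on every non-decoy row.
#' @param threshold an [activity_threshold()].
#' @return the relabeled `feature_table`.
#' @export
binarize_activity <- function(table, threshold) {
  stopifnot(inherits(table, "feature_table"),
            inherits(threshold, "activity_threshold"))
  is_decoy <- if (is.null(table$source)) rep(FALSE, nrow(table$values)) else
    !is.na(table$source) & table$source == "decoy"
  ic50 <- table$ic50 %||% rep(NA_real_, nrow(table$values))
  missing <- which(!is_decoy & is.na(ic50))
  if (length(missing)) {
    stop("data error: missing IC50 on non-decoy row '",
         row_ids(table)[missing[1]], "'", call. = FALSE)
  }
  table$labels <- ifelse(!is_decoy & ic50 <= threshold$cutoff_um,
                         "active", "inactive")
  validate_feature_table(table)
  table
}

#' Configuration of the two-stage feature filter
#'
#' @param tau_threshold magnitude cutoff on Kendall tau-a above which
#'   the later of a column pair is dropped (default 0.9, strict `>`).
#' @param variance_threshold minimum post-normalization variance; the
#'   default 0 removes exactly the constant columns.
#' @return a `correlation_filter_config` object.
#' @export
correlation_filter_config <- function(tau_threshold = 0.9,
                                      variance_threshold = 0) {
  if (tau_threshold <= 0 || tau_threshold > 1) {
    stop("`tau_threshold` must be in (0, 1]", call. = FALSE)
  }
  if (variance_threshold < 0) {
    stop("`variance_threshold` must be >= 0", call. = FALSE)
  }
  structure(list(tau_threshold = tau_threshold,
                 variance_threshold = variance_threshold),
            class = "correlation_filter_config")
}

filter_report <- function(n_initial, n_removed_low_variance,
                          n_removed_high_correlation,
                          removed_pairs = NULL) {
  rep <- structure(
    list(n_initial = n_initial,
         n_removed_low_variance = n_removed_low_variance,
         n_removed_high_correlation = n_removed_high_correlation,
         n_remaining = n_initial - n_removed_low_variance -
           n_removed_high_correlation,
         removed_pairs = removed_pairs %||%
           data.frame(kept_col = character(), dropped_col = character(),
                      tau = numeric(), stringsAsFactors = FALSE)),
    class = "filter_report")
  stopifnot(rep$n_remaining ==
              rep$n_initial - rep$n_removed_low_variance -
              rep$n_removed_high_correlation)
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> %d initial - %d low-variance - %d high-correlation = %d remaining\n",
    x$n_initial, x$n_removed_low_variance, x$n_removed_high_correlation,
    x$n_remaining))
  invisible(x)
}

#' Min-max normalize every column to the unit interval
#'
#' Non-constant columns are linearly rescaled to \[0, 1\]; constant
#' columns map to 0. The recorded per-column `(min, max)` allows exact
#' de-normalization of retained columns after filtering.
#'
#' @param table a [feature_table()].
#' @return list with `table` (normalized) and `ranges` (a 2-row matrix
#'   `min`/`max` per column; `max == min` flags a constant column).
#' @export
normalize_minmax <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  lo <- apply(table$values, 2, min)
  hi <- apply(table$values, 2, max)
  span <- hi - lo
  vals <- sweep(table$values, 2, lo, "-")
  vals <- sweep(vals, 2, ifelse(span > 0, span, 1), "/")
  vals[, span == 0] <- 0
  out <- table
  out$values <- vals
  # binary columns stay 0/1 (constants map to all-0), so col_kind is stable
  list(table = out, ranges = rbind(min = lo, max = hi))
}

#' @rdname normalize_minmax
#' @param normalized the normalized table (or a filtered subset of it).
#' @param ranges the `ranges` matrix returned by `normalize_minmax`.
#' @export
denormalize_minmax <- function(normalized, ranges) {
  stopifnot(inherits(normalized, "feature_table"))
  keep <- col_ids(normalized)
  lo <- ranges["min", keep]
  hi <- ranges["max", keep]
  vals <- sweep(normalized$values, 2, ifelse(hi > lo, hi - lo, 0), "*")
  vals <- sweep(vals, 2, lo, "+")
  out <- normalized
  out$values <- vals
  out$col_kind <- ifelse(apply(vals, 2, function(x) all(x %in% c(0, 1))),
                         out$col_kind, "continuous")
  validate_feature_table(out)
  out
}

#' Remove low-variance columns
#'
#' Drops every column whose variance is `<=` the configured threshold
#' (default: exactly the constant columns), preserving the order of
#' survivors.
#'
#' @param table a (normalized) [feature_table()].
#' @param config a [correlation_filter_config()].
#' @return list with `table` (survivors) and `removed` (dropped col_ids).
#' @export
remove_low_variance <- function(table, config = correlation_filter_config()) {
  stopifnot(inherits(table, "feature_table"))
  v <- apply(table$values, 2, stats::var)
  drop <- v <= config$variance_threshold
  list(table = ft_subset(table, cols = !drop),
       removed = col_ids(table)[drop])
}

#' Kendall tau-a rank correlation
#'
#' `(concordant - discordant) / (n (n - 1) / 2)`; tied pairs count as
#' neither concordant nor discordant (so heavily tied vectors cannot
#' reach |tau-a| = 1). Computed by an O(n log n) merge-sort inversion
#' counter in C++.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return tau-a in \[-1, 1\].
#' @export
kendall_tau_a <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need n >= 2", call. = FALSE)
  .kendall_tau_a_cpp(as.numeric(x), as.numeric(y))
}

#' Pairwise Kendall tau-a matrix over the columns of a table
#'
#' @param table a [feature_table()] or numeric matrix.
#' @return a d-by-d symmetric matrix with unit diagonal.
#' @export
kendall_tau_a_matrix <- function(table) {
  X <- if (inherits(table, "feature_table")) table$values else table
  out <- .kendall_tau_a_matrix_cpp(X)
  dimnames(out) <- list(colnames(X), colnames(X))
  out
}

#' Remove highly tau-a-correlated columns
#'
#' Greedy left-to-right sweep: for every pair with |tau-a| strictly
#' above the threshold, the later column (in current column order) is
#' dropped and the drop recorded with the kept partner and the tau that
#' triggered it.
#'
#' @param table a [feature_table()] that already passed the low-variance
#'   filter.
#' @param config a [correlation_filter_config()].
#' @return list with `table` (survivors), `removed` (dropped col_ids)
#'   and `removed_pairs` (data.frame `kept_col`, `dropped_col`, `tau`).
#' @export
remove_high_correlation <- function(table,
                                    config = correlation_filter_config()) {
  stopifnot(inherits(table, "feature_table"))
  d <- ncol(table$values)
  if (d < 2) {
    return(list(table = table, removed = character(),
                removed_pairs = filter_report(d, 0, 0)$removed_pairs))
  }
  tau <- kendall_tau_a_matrix(table)
  keep <- rep(TRUE, d)
  kept_by <- character(0); dropped <- character(0); tau_rec <- numeric(0)
  ids <- col_ids(table)
  for (j in seq_len(d - 1)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(d) > j & abs(tau[j, ]) > config$tau_threshold)
    if (length(later)) {
      keep[later] <- FALSE
      kept_by <- c(kept_by, rep(ids[j], length(later)))
      dropped <- c(dropped, ids[later])
      tau_rec <- c(tau_rec, tau[j, later])
    }
  }
  list(table = ft_subset(table, cols = keep),
       removed = ids[!keep],
       removed_pairs = data.frame(kept_col = kept_by, dropped_col = dropped,
                                  tau = tau_rec, stringsAsFactors = FALSE))
}

#' Two-stage feature filtering
#'
#' The full preprocessing sweep: min-max normalize, drop low-variance
#' columns, drop |tau-a|-redundant columns, then de-normalize the
#' survivors back to their original scale for further processing.
#'
#' @param table a [feature_table()].
#' @param config a [correlation_filter_config()].
#' @return list with `table` (filtered, original scale) and `report`
#'   (a `filter_report` with conservation
#'   `n_initial - removals = n_remaining` and the per-drop tau records).
#' @export
filter_features <- function(table, config = correlation_filter_config()) {
  nm <- normalize_minmax(table)
  lv <- remove_low_variance(nm$table, config)
  hc <- remove_high_correlation(lv$table, config)
  out <- denormalize_minmax(hc$table, nm$ranges)
  report <- filter_report(
    n_initial = ncol(table$values),
    n_removed_low_variance = length(lv$removed),
    n_removed_high_correlation = length(hc$removed),
    removed_pairs = hc$removed_pairs)
  list(table = out, report = report)
}
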