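#' Consensus-screening configuration
#'
#' @param prob_threshold active-probability cutoff; a model "votes" for
#'   a compound only when its probability is strictly greater than this
#'   (default 0.9).
#' @param require_unanimous call a hit only when every panel model
#'   votes (default `TRUE`); otherwise `min_votes` models suffice.
#' @param min_votes minimum number of voting models in non-unanimous
#'   mode.
#' @param chunk_size rows held in memory per streamed block
#'   (default 250000, the subset scale used for multi-million-row
#'   libraries).
#' @return a `consensus_config` object.
#' @export
consensus_config <- function(prob_threshold = 0.9, require_unanimous = TRUE,
                             min_votes = 1, chunk_size = 250000) {
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop("`prob_threshold` must be in (0, 1)", call. = FALSE)
  }
  if (chunk_size < 1) stop("`chunk_size` must be >= 1", call. = FALSE)
  structure(list(prob_threshold = prob_threshold,
                 require_unanimous = require_unanimous,
                 min_votes = min_votes, chunk_size = chunk_size),
            class = "consensus_config")
}

#' Consensus vote on one probability vector
#'
#' @param probs per-model active probabilities (length >= 1).
#' @param config a [consensus_config()].
#' @return `TRUE` iff the compound is a consensus hit.
#' @export
consensus_vote <- function(probs, config = consensus_config()) {
  if (!length(probs)) stop("empty probability vector", call. = FALSE)
  votes <- sum(probs > config$prob_threshold)
  if (config$require_unanimous) votes == length(probs) else
    votes >= config$min_votes
}

#' Tanimoto similarity of two binary fingerprints
#'
#' Intersection over union of the on-bits; defined as 0 when neither
#' vector has an on-bit.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints must have equal length", call. = FALSE)
  }
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(0)
  inter / uni
}

# Tanimoto of each query row against each active row, over binary
# columns only, fully vectorized via cross products.
tanimoto_cross <- function(Q, A) {
  inter <- Q %*% t(A)
  uni <- outer(rowSums(Q), rowSums(A), "+") - inter
  out <- inter / ifelse(uni == 0, 1, uni)
  out[uni == 0] <- 0
  out
}

#' Nearest-neighbor Tanimoto similarity to the training actives
#'
#' Linear scan over the actives (binary/fingerprint columns only); ties
#' broken by first row order.
#'
#' @param query a [feature_table()] of query rows (or a single named
#'   numeric row vector).
#' @param actives the training actives as a [feature_table()].
#' @return data.frame with `nn_id` and `nn_similarity` per query row.
#' @export
nearest_neighbor_similarity <- function(query, actives) {
  stopifnot(inherits(actives, "feature_table"))
  if (nrow(actives$values) == 0) stop("no training actives", call. = FALSE)
  bin_cols <- col_ids(actives)[actives$col_kind == "binary"]
  if (inherits(query, "feature_table")) {
    bin_cols <- intersect(bin_cols,
                          col_ids(query)[query$col_kind == "binary"])
    Q <- query$values[, bin_cols, drop = FALSE]
    q_ids <- row_ids(query)
  } else {
    bin_cols <- intersect(bin_cols, names(query))
    Q <- matrix(query[bin_cols], nrow = 1)
    q_ids <- "query"
  }
  if (!length(bin_cols)) {
    stop("configuration error: no shared binary (fingerprint) columns",
         call. = FALSE)
  }
  A <- actives$values[, bin_cols, drop = FALSE]
  sim <- tanimoto_cross(Q, A)
  nn <- apply(sim, 1, which.max)   # which.max = first maximum (tie rule)
  data.frame(row_id = q_ids,
             nn_id = row_ids(actives)[nn],
             nn_similarity = sim[cbind(seq_along(nn), nn)],
             stringsAsFactors = FALSE)
}

#' Screening hit rate
#'
#' `100 * n_hits / n_screened`, reported to 3 significant figures (the
#' convention used when quoting hit rates as percentages).
#'
#' @param n_hits,n_screened hit and library counts,
#'   `0 <= n_hits <= n_screened`, `n_screened >= 1`.
#' @return percentage.
#' @export
hit_rate <- function(n_hits, n_screened) {
  if (n_screened < 1 || n_hits < 0 || n_hits > n_screened) {
    stop("need 0 <= n_hits <= n_screened and n_screened >= 1", call. = FALSE)
  }
  signif(100 * n_hits / n_screened, 3)
}

#' Screen a compound library with a model panel
#'
#' Processes the library chunk by chunk (peak resident rows bounded by
#' `chunk_size`): per chunk, every model predicts an active
#' probability, the consensus vote is applied, and hits only are
#' annotated with their nearest-neighbor Tanimoto similarity to the
#' training actives. Output row order equals input order and is
#' invariant to the chunk size.
#'
#' @param library a [feature_table()], or a path to a delimited
#'   feature-table file streamed in chunks.
#' @param models non-empty list of `trained_model`s.
#' @param training_actives [feature_table()] of the active training
#'   compounds (for novelty annotation); `NULL` skips annotation.
#' @param config a [consensus_config()].
#' @return a `screening_result`: data.frame with `row_id`, one
#'   `prob_<i>` column per model, `hit`, `nn_id`, `nn_similarity`;
#'   attribute `summary` holds `n_screened`, `n_hits`, `hit_rate`.
#' @export
screen_library <- function(library, models, training_actives = NULL,
                           config = consensus_config()) {
  if (!length(models)) stop("model panel is empty", call. = FALSE)
  model_names <- names(models) %||% sprintf("model_%d", seq_along(models))
  if (is.null(names(models))) names(models) <- model_names

  needed <- unique(unlist(lapply(models, `[[`, "columns")))
  check_schema <- function(tbl) {
    missing <- setdiff(needed, col_ids(tbl))
    if (length(missing)) {
      stop("schema error: library lacks feature column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  screen_chunk <- function(tbl, chunk_index) {
    out <- tryCatch({
      probs <- vapply(models, function(m) predict_proba(m, tbl),
                      numeric(nrow(tbl$values)))
      if (nrow(tbl$values) == 1) {
        probs <- matrix(probs, nrow = 1, dimnames = list(NULL, names(models)))
      }
      hit <- apply(probs, 1, consensus_vote, config = config)
      res <- data.frame(row_id = row_ids(tbl), stringsAsFactors = FALSE)
      for (mi in seq_along(models)) {
        res[[paste0("prob_", names(models)[mi])]] <- probs[, mi]
      }
      res$hit <- hit
      res$nn_id <- NA_character_
      res$nn_similarity <- NA_real_
      if (any(hit) && !is.null(training_actives)) {
        nn <- nearest_neighbor_similarity(ft_subset(tbl, rows = hit),
                                          training_actives)
        res$nn_id[hit] <- nn$nn_id
        res$nn_similarity[hit] <- nn$nn_similarity
      }
      res
    }, error = function(e) {
      stop("screening failed at chunk ", chunk_index, ": ",
           conditionMessage(e), call. = FALSE)
    })
    out
  }

  chunks <- list()
  if (inherits(library, "feature_table")) {
    check_schema(library)
    n <- nrow(library$values)
    starts <- seq(1, n, by = config$chunk_size)
    for (ci in seq_along(starts)) {
      rows <- starts[ci]:min(starts[ci] + config$chunk_size - 1, n)
      chunks[[ci]] <- screen_chunk(ft_subset(library, rows = rows), ci)
    }
  } else {
    n <- count_table_rows(library)
    first <- read_feature_table(library, n_max = 1)
    check_schema(first)
    starts <- seq(0, n - 1, by = config$chunk_size)
    for (ci in seq_along(starts)) {
      tbl <- read_feature_table(library,
                                n_max = min(config$chunk_size, n - starts[ci]),
                                skip_rows = starts[ci])
      chunks[[ci]] <- screen_chunk(tbl, ci)
    }
  }
  res <- do.call(rbind, chunks)
  rownames(res) <- NULL
  attr(res, "summary") <- list(
    n_screened = nrow(res), n_hits = sum(res$hit),
    hit_rate = hit_rate(sum(res$hit), nrow(res)))
  class(res) <- c("screening_result", "data.frame")
  res
}

#' @export
print.screening_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<screening_result> %d screened, %d hits (hit rate %.3g%%)\n",
              s$n_screened, s$n_hits, s$hit_rate))
  NextMethod()
}
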