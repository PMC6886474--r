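#' Read a feature table from delimited text
#'
#' The pipeline's dialect is comma-separated UTF-8 with a header row.
#' Reserved column names carry row metadata: `__id` (compound
#' identifier), `__ic50_um` (IC50 in uM, empty where unknown),
#' `__label` (`active`/`inactive`), `__source`
#' (`active_source`/`decoy`). All other columns are features; a feature
#' column is typed binary iff every observed value is 0 or 1, unless a
#' sidecar schema (same path with extension `.schema`, lines
#' `name,kind`) declares it.
#'
#' @param path file to read.
#' @param n_max maximum number of data rows to read (`Inf` = all).
#' @param skip_rows data rows to skip after the header (used by the
#'   chunked screening reader).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, n_max = Inf, skip_rows = 0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("parse error: duplicate column name '",
         header[duplicated(header)][1], "' in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        skip = if (skip_rows > 0) skip_rows + 1L else 0L,
                        nrows = if (is.finite(n_max)) n_max else -1,
                        header = (skip_rows == 0))
  if (skip_rows > 0) {
    if (ncol(df) != length(header)) {
      stop("parse error: ragged chunk at data row ", skip_rows + 1, call. = FALSE)
    }
    names(df) <- header
  }
  meta_cols <- intersect(c("__id", "__ic50_um", "__label", "__source"), header)
  feat_cols <- setdiff(header, meta_cols)
  if (!length(feat_cols)) stop("parse error: no feature columns in ", path, call. = FALSE)
  vals <- suppressWarnings(
    vapply(feat_cols, function(cn) as.numeric(df[[cn]]), numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, feat_cols))
  for (cn in feat_cols) {
    bad <- which(is.na(vals[, cn]) & !(df[[cn]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric cell in column '%s', line %d",
                   cn, bad[1] + 1 + skip_rows), call. = FALSE)
    }
  }
  if (anyNA(vals)) {
    stop("parse error: missing feature value in ", path, call. = FALSE)
  }
  ids <- if ("__id" %in% meta_cols) df[["__id"]] else
    sprintf("row_%06d", skip_rows + seq_len(nrow(df)))
  rownames(vals) <- ids
  kind <- NULL
  schema_path <- paste0(path, ".schema")
  if (file.exists(schema_path)) {
    sc <- utils::read.csv(schema_path, header = FALSE,
                          col.names = c("name", "kind"))
    kind <- infer_col_kind(vals)
    kind[match(sc$name, feat_cols)] <- sc$kind
  }
  ic50 <- if ("__ic50_um" %in% meta_cols) {
    suppressWarnings(as.numeric(df[["__ic50_um"]]))
  } else NULL
  labels <- if ("__label" %in% meta_cols && !all(df[["__label"]] == "")) {
    df[["__label"]]
  } else NULL
  src <- if ("__source" %in% meta_cols) {
    s <- df[["__source"]]; s[s == ""] <- NA; s
  } else NULL
  feature_table(vals, col_kind = kind, labels = labels, ic50 = ic50, source = src)
}

#' Write a feature table as delimited text
#'
#' Inverse of [read_feature_table()]: metadata columns first, then
#' features; a `.schema` sidecar records each column's kind so that
#' binary typing round-trips even for degenerate columns.
#'
#' @param ft a [feature_table()].
#' @param path destination file.
#' @param schema write the `.schema` sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, schema = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(`__id` = row_ids(ft), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(ft$ic50))   df[["__ic50_um"]] <- ft$ic50
  if (!is.null(ft$labels)) df[["__label"]]   <- ft$labels
  if (!is.null(ft$source)) df[["__source"]]  <- ft$source
  df <- cbind(df, as.data.frame(ft$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (schema) {
    utils::write.table(
      data.frame(name = col_ids(ft), kind = ft$col_kind),
      paste0(path, ".schema"), sep = ",", row.names = FALSE,
      col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Number of data rows in a delimited feature-table file.
count_table_rows <- function(path) {
  length(readLines(path)) - 1L
}
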