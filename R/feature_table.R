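#' Compound-by-feature table
#'
#' The universal currency of the pipeline: a numeric matrix of compounds
#' (rows) by features (columns), where every column is typed either
#' `"binary"` (a fingerprint bit, values in \{0, 1\}) or `"continuous"`
#' (a molecular descriptor). Rows may optionally carry an activity label
#' (`"active"` / `"inactive"`), an IC50 in micromolar, and a provenance
#' tag (`"active_source"` for assayed compounds, `"decoy"` for presumed
#' inactives mixed in to supply the negative class).
#'
#' @param values numeric matrix with unique row and column names.
#' @param col_kind optional character vector (`"binary"`/`"continuous"`),
#'   one per column; inferred when `NULL`: a column is binary iff every
#'   observed value is 0 or 1.
#' @param labels optional character vector of `"active"`/`"inactive"`,
#'   one per row; must cover every row when present.
#' @param ic50 optional numeric vector of IC50 values in uM, one per row
#'   (`NA` where unknown, e.g. decoys).
#' @param source optional character vector of `"active_source"`/`"decoy"`
#'   per row.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, col_kind = NULL, labels = NULL,
                          ic50 = NULL, source = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cmpd_%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate row_ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate col_ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(col_kind)) {
    col_kind <- infer_col_kind(values)
  }
  col_kind <- unname(rep_len(as.character(col_kind), ncol(values)))
  ft <- structure(
    list(values = values, col_kind = col_kind,
         labels = if (is.null(labels)) NULL else unname(as.character(labels)),
         ic50 = if (is.null(ic50)) NULL else unname(as.numeric(ic50)),
         source = if (is.null(source)) NULL else unname(as.character(source))),
    class = "feature_table")
  validate_feature_table(ft)
  ft
}

infer_col_kind <- function(values) {
  ifelse(apply(values, 2, function(x) all(x %in% c(0, 1))),
         "binary", "continuous")
}

validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$values)
  d <- ncol(ft$values)
  if (length(ft$col_kind) != d ||
      !all(ft$col_kind %in% c("binary", "continuous"))) {
    stop("col_kind must be 'binary'/'continuous', one per column",
         call. = FALSE)
  }
  bad <- which(ft$col_kind == "binary" &
                 apply(ft$values, 2, function(x) !all(x %in% c(0, 1))))
  if (length(bad)) {
    stop("binary column(s) with values outside {0,1}: ",
         paste(colnames(ft$values)[bad], collapse = ", "), call. = FALSE)
  }
  for (fld in c("labels", "ic50", "source")) {
    if (!is.null(ft[[fld]]) && length(ft[[fld]]) != n) {
      stop(sprintf("`%s` must have one entry per row", fld), call. = FALSE)
    }
  }
  if (!is.null(ft$labels)) {
    if (anyNA(ft$labels) || !all(ft$labels %in% c("active", "inactive"))) {
      stop("labels must cover every row with 'active'/'inactive'",
           call. = FALSE)
    }
  }
  if (!is.null(ft$source) &&
      !all(ft$source %in% c("active_source", "decoy") | is.na(ft$source))) {
    stop("source entries must be 'active_source'/'decoy'/NA", call. = FALSE)
  }
  invisible(ft)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  n_bin <- sum(x$col_kind == "binary")
  cat(sprintf("<feature_table> %d compounds x %d features (%d binary, %d continuous)\n",
              nrow(x$values), ncol(x$values), n_bin, ncol(x$values) - n_bin))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d active / %d inactive\n",
                sum(x$labels == "active"), sum(x$labels == "inactive")))
  }
  if (!is.null(x$ic50)) {
    cat(sprintf("  ic50: %d rows with measured IC50 (uM)\n", sum(!is.na(x$ic50))))
  }
  invisible(x)
}

row_ids <- function(ft) rownames(ft$values)
col_ids <- function(ft) colnames(ft$values)

#' Subset a feature table
#'
#' @param ft a `feature_table`.
#' @param rows,cols row / column indices, names or logical masks;
#'   `NULL` keeps everything.
#' @return a `feature_table` with row metadata subset alongside.
#' @export
ft_subset <- function(ft, rows = NULL, cols = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(rows)) rows <- seq_len(nrow(ft$values))
  if (is.null(cols)) cols <- seq_len(ncol(ft$values))
  if (is.character(rows)) rows <- match(rows, row_ids(ft))
  if (is.character(cols)) cols <- match(cols, col_ids(ft))
  if (is.logical(rows)) rows <- which(rows)
  if (is.logical(cols)) cols <- which(cols)
  if (anyNA(rows) || anyNA(cols)) {
    stop("unknown row or column identifier in subset", call. = FALSE)
  }
  feature_table(ft$values[rows, cols, drop = FALSE],
                col_kind = ft$col_kind[cols],
                labels = if (is.null(ft$labels)) NULL else ft$labels[rows],
                ic50 = if (is.null(ft$ic50)) NULL else ft$ic50[rows],
                source = if (is.null(ft$source)) NULL else ft$source[rows])
}

# 0/1 class vector (active = 1); errors when labels are absent
class01 <- function(ft) {
  if (is.null(ft$labels)) {
    stop("feature table carries no activity labels", call. = FALSE)
  }
  as.numeric(ft$labels == "active")
}
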