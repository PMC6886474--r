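#' Classifier model specification
#'
#' @param classifier `"DT"` (single decision tree, Gini splits,
#'   cost-complexity post-pruning), `"RF"` (bagged forest,
#'   information-gain-ratio splits, per-node feature sampling of size
#'   `ceiling(sqrt(d))`) or `"NB"` (naive Bayes: Gaussian likelihoods
#'   for continuous columns, Laplace-smoothed Bernoulli for binary).
#' @param max_depth tree-depth bound (DT/RF).
#' @param num_trees forest size (RF only).
#' @param feature_subset a `feature_subset`, a character vector of
#'   column ids, or `"all"`.
#' @param cp complexity parameter of the DT post-pruning (default 0.01).
#' @param bootstrap RF only: draw a bootstrap sample per tree (default
#'   `TRUE`; `FALSE` with `mtry = d` makes a 1-tree forest coincide
#'   with a single unpruned gain-ratio tree).
#' @param mtry RF only: per-node feature-sample size (default
#'   `ceiling(sqrt(d))`).
#' @param seed RNG seed for bootstrap/feature sampling.
#' @return a `model_spec` object.
#' @export
model_spec <- function(classifier = c("RF", "DT", "NB"), max_depth = 5,
                       num_trees = 50, feature_subset = "all",
                       cp = 0.01, bootstrap = TRUE, mtry = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  if (classifier %in% c("DT", "RF") && max_depth < 1) {
    stop("configuration error: `max_depth` must be >= 1", call. = FALSE)
  }
  if (classifier == "RF" && num_trees < 1) {
    stop("configuration error: `num_trees` must be >= 1", call. = FALSE)
  }
  cols <- if (inherits(feature_subset, "feature_subset")) {
    feature_subset$columns
  } else feature_subset
  structure(list(classifier = classifier, max_depth = max_depth,
                 num_trees = num_trees, feature_subset = cols,
                 split_criterion = switch(classifier, DT = "gini",
                                          RF = "gain_ratio", NB = NA),
                 cp = cp, bootstrap = bootstrap, mtry = mtry,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Train/test split and cross-validation configuration
#'
#' @param train_fraction share of rows in the training partition
#'   (default 0.65, i.e. a 65/35 split).
#' @param cv_folds folds for cross-validation (default 10).
#' @param stratified stratify by class (default `TRUE`).
#' @param seed RNG seed.
#' @return a `split_config` object.
#' @export
split_config <- function(train_fraction = 0.65, cv_folds = 10,
                         stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
  structure(list(train_fraction = train_fraction, cv_folds = cv_folds,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_config")
}

#' Stratified train/test split
#'
#' The training partition has `floor(train_fraction * n)` rows; per
#' class, `floor(fraction * n_class)` rows are taken first and the
#' remainder is distributed to the classes with the largest fractional
#' parts, so class proportions in both partitions stay within one
#' compound of the global proportion.
#'
#' @param table a labeled [feature_table()].
#' @param config a [split_config()].
#' @return list with `train` and `test` feature tables.
#' @export
split_train_test <- function(table, config = split_config()) {
  y <- table$labels
  if (is.null(y)) stop("labels required for splitting", call. = FALSE)
  classes <- unique(y)
  if (any(table(y) < 2)) {
    stop("stratification error: every class needs >= 2 members", call. = FALSE)
  }
  n <- length(y)
  target <- floor(config$train_fraction * n)
  per_cls <- floor(config$train_fraction * table(y)[classes])
  frac <- config$train_fraction * table(y)[classes] - per_cls
  extra <- target - sum(per_cls)
  if (extra > 0) {
    give <- order(frac, decreasing = TRUE)[seq_len(extra)]
    per_cls[give] <- per_cls[give] + 1
  }
  train_idx <- integer(0)
  with_seed(config$seed, {
    for (ci in seq_along(classes)) {
      idx <- which(y == classes[ci])
      take <- if (config$stratified) per_cls[ci] else
        round(config$train_fraction * length(idx))
      train_idx <- c(train_idx, idx[sample.int(length(idx))][seq_len(take)])
    }
  })
  train_idx <- sort(train_idx)
  list(train = ft_subset(table, rows = train_idx),
       test = ft_subset(table, rows = setdiff(seq_len(n), train_idx)))
}

resolve_subset_cols <- function(table, cols) {
  if (identical(cols, "all")) return(col_ids(table))
  missing <- setdiff(cols, col_ids(table))
  if (length(missing)) {
    stop("schema error: missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cols
}

#' Train a classifier
#'
#' @param table a labeled [feature_table()].
#' @param spec a [model_spec()].
#' @return a `trained_model`: the spec, an opaque fitted state, the
#'   feature columns used, and a digest of the training rows/columns
#'   for provenance.
#' @export
train <- function(table, spec) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "model_spec"))
  cols <- resolve_subset_cols(table, spec$feature_subset)
  X <- table$values[, cols, drop = FALSE]
  y <- class01(table)
  fitted <- switch(
    spec$classifier,
    DT = with_seed(spec$seed, {
      tree <- grow_tree(X, y, criterion = "gini", max_depth = spec$max_depth)
      prune_tree(tree, spec$cp, length(y))
    }),
    RF = with_seed(spec$seed, {
      mtry <- spec$mtry %||% ceiling(sqrt(ncol(X)))
      lapply(seq_len(spec$num_trees), function(b) {
        boot <- if (spec$bootstrap) {
          sample.int(nrow(X), replace = TRUE)
        } else seq_len(nrow(X))
        grow_tree(X[boot, , drop = FALSE], y[boot],
                  criterion = "gain_ratio", max_depth = spec$max_depth,
                  mtry = mtry)
      })
    }),
    NB = fit_naive_bayes(X, y, table$col_kind[match(cols, col_ids(table))]),
    stop("configuration error: unknown classifier '", spec$classifier, "'",
         call. = FALSE))
  structure(list(spec = spec, columns = cols, fitted_state = fitted,
                 training_digest = content_digest(list(X, y, cols))),
            class = "trained_model")
}

fit_naive_bayes <- function(X, y, kind) {
  stats_for <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    list(n = nrow(Xi),
         mu = colMeans(Xi),
         sd = pmax(apply(Xi, 2, stats::sd), 1e-6),
         # Laplace-smoothed on-bit rates for binary columns
         p1 = (colSums(Xi) + 1) / (nrow(Xi) + 2))
  }
  list(kind = kind, prior1 = mean(y),
       active = stats_for(1), inactive = stats_for(0))
}

predict_naive_bayes <- function(fit, X) {
  loglik <- function(st) {
    ll <- numeric(nrow(X))
    for (j in seq_len(ncol(X))) {
      ll <- ll + if (fit$kind[j] == "binary") {
        ifelse(X[, j] == 1, log(st$p1[j]), log(1 - st$p1[j]))
      } else {
        stats::dnorm(X[, j], st$mu[j], st$sd[j], log = TRUE)
      }
    }
    ll
  }
  la <- loglik(fit$active) + log(fit$prior1)
  li <- loglik(fit$inactive) + log(1 - fit$prior1)
  m <- pmax(la, li)
  exp(la - m) / (exp(la - m) + exp(li - m))
}

#' Active-class probability predictions
#'
#' RF: fraction of trees whose leaf majority votes active (ties count
#' half). DT: leaf class frequency. NB: normalized posterior. Row order
#' of the output matches the input; batching is irrelevant.
#'
#' @param model a `trained_model`.
#' @param table a [feature_table()] whose columns cover the model's
#'   feature subset.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, table) {
  stopifnot(inherits(model, "trained_model"))
  cols <- resolve_subset_cols(table, model$columns)
  X <- table$values[, cols, drop = FALSE]
  switch(model$spec$classifier,
         DT = predict_tree(model$fitted_state, X),
         RF = {
           votes <- vapply(model$fitted_state, function(tr) {
             p <- predict_tree(tr, X)
             ifelse(p > 0.5, 1, ifelse(p < 0.5, 0, 0.5))
           }, numeric(nrow(X)))
           if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
           rowMeans(votes)
         },
         NB = predict_naive_bayes(model$fitted_state, X))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the
#' probability that a uniformly chosen active is scored above a
#' uniformly chosen inactive, ties counting one half.
#'
#' @param scores per-row scores (higher = more active).
#' @param labels per-row classes (`"active"`/`"inactive"`, or 0/1).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) labels else as.numeric(labels == "active")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("metric error: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a probability threshold
#'
#' @param scores per-row active probabilities.
#' @param labels per-row classes.
#' @param threshold score above which a row is called active (default
#'   0.5, strict `>`).
#' @return a `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  y <- if (is.numeric(labels)) labels else as.numeric(labels == "active")
  pred <- as.numeric(scores > threshold)
  structure(list(tp = sum(pred == 1 & y == 1), tn = sum(pred == 0 & y == 0),
                 fp = sum(pred == 1 & y == 0), fn = sum(pred == 0 & y == 1)),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0
#' whenever a denominator factor vanishes.
#'
#' @param confusion a [confusion_counts()] (or a list with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(confusion) {
  tp <- confusion$tp; tn <- confusion$tn
  fp <- confusion$fp; fn <- confusion$fn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

validation_report <- function(scores, labels, mode,
                              threshold = 0.5) {
  conf <- confusion_counts(scores, labels, threshold)
  structure(list(auc = roc_auc(scores, labels), mcc = mcc(conf),
                 confusion = conf, mode = mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report %s> AUC=%.3f MCC=%.3f (TP=%d TN=%d FP=%d FN=%d)\n",
              x$mode, x$auc, x$mcc, x$confusion$tp, x$confusion$tn,
              x$confusion$fp, x$confusion$fn))
  invisible(x)
}

#' Evaluate a trained model on a labeled test set
#'
#' @param model a `trained_model`.
#' @param table a labeled [feature_table()].
#' @return a `validation_report` with mode `"test_set"`.
#' @export
validate_test_set <- function(model, table) {
  validation_report(predict_proba(model, table), table$labels, "test_set")
}

#' Stratified k-fold cross-validation
#'
#' Out-of-fold probabilities are pooled and a single AUC and MCC (at
#' threshold 0.5) computed on the pooled predictions. Fold assignment
#' is deterministic from the config seed.
#'
#' @param table a labeled [feature_table()].
#' @param spec a [model_spec()].
#' @param config a [split_config()] (its `cv_folds` and `seed` are used).
#' @return a `validation_report` with mode `"cross_validation"` and an
#'   extra `pooled_scores` element.
#' @export
cross_validate <- function(table, spec, config = split_config()) {
  y <- table$labels
  if (is.null(y)) stop("labels required", call. = FALSE)
  k <- config$cv_folds
  folds <- if (config$stratified) stratified_folds(y, k, config$seed) else
    with_seed(config$seed, sample(rep_len(seq_len(k), length(y))))
  scores <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- ft_subset(table, rows = folds != f)
    te <- ft_subset(table, rows = folds == f)
    m <- train(tr, spec)
    scores[folds == f] <- predict_proba(m, te)
  }
  out <- validation_report(scores, y, "cross_validation")
  out$pooled_scores <- scores
  out
}

#' Grid search for classifier hyperparameters
#'
#' Full grid over `max_depth` (DT/RF) and `num_trees` (RF), scored by
#' cross-validated AUC on the supplied (training) table; ties are broken
#' toward the cheaper model (smaller `num_trees`, then smaller
#' `max_depth`). The default grid spans the depth/tree ranges observed
#' across the tuned forest models this pipeline emulates (maxDepth
#' 2-10, numTrees 13-245).
#'
#' @param table the labeled training portion.
#' @param classifier `"DT"`, `"RF"` or `"NB"`.
#' @param grid list with `max_depth` and (RF) `num_trees` vectors.
#' @param config a [split_config()] (cross-validation settings).
#' @param feature_subset columns the candidate models train on.
#' @return the winning [model_spec()] with attributes `cv_auc` (its
#'   score) and `grid_scores` (a data.frame of every grid point).
#' @export
optimize_hyperparameters <- function(table, classifier = "RF",
                                     grid = default_grid(classifier),
                                     config = split_config(),
                                     feature_subset = "all") {
  if (classifier == "NB") {
    grid_pts <- data.frame(max_depth = NA, num_trees = NA)
  } else if (classifier == "DT") {
    if (!length(grid$max_depth)) stop("configuration error: empty grid", call. = FALSE)
    grid_pts <- data.frame(max_depth = grid$max_depth, num_trees = NA)
  } else {
    if (!length(grid$max_depth) || !length(grid$num_trees)) {
      stop("configuration error: empty grid", call. = FALSE)
    }
    grid_pts <- expand.grid(max_depth = grid$max_depth,
                            num_trees = grid$num_trees)
  }
  grid_pts$cv_auc <- NA_real_
  specs <- vector("list", nrow(grid_pts))
  for (i in seq_len(nrow(grid_pts))) {
    specs[[i]] <- model_spec(classifier,
                             max_depth = grid_pts$max_depth[i] %|NA|% 5,
                             num_trees = grid_pts$num_trees[i] %|NA|% 50,
                             feature_subset = feature_subset,
                             seed = config$seed)
    grid_pts$cv_auc[i] <- cross_validate(table, specs[[i]], config)$auc
  }
  ord <- order(-grid_pts$cv_auc, grid_pts$num_trees, grid_pts$max_depth,
               na.last = FALSE)
  win <- ord[1]
  spec <- specs[[win]]
  attr(spec, "cv_auc") <- grid_pts$cv_auc[win]
  attr(spec, "grid_scores") <- grid_pts
  spec
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

#' @rdname optimize_hyperparameters
#' @export
default_grid <- function(classifier = "RF") {
  switch(classifier,
         RF = list(max_depth = 2:10,
                   num_trees = c(10, 25, 50, 75, 100, 150, 200, 250)),
         DT = list(max_depth = 2:10),
         list())
}
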