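#' Pipeline configuration
#'
#' Describes one end-to-end run: binarize the labeled input under each
#' activity threshold, filter features, select subsets with each
#' requested selector (plus the `"none"` control that keeps every
#' filtered feature), tune and train each requested classifier, and
#' validate the full threshold x selector x classifier grid. The
#' default grid is the 5 thresholds x 4 selectors x 3 classifiers
#' design (60 models) plus the 15 `"none"` controls.
#'
#' @param thresholds list of [activity_threshold()]s (default the five
#'   canonical SET cutoffs).
#' @param selectors subset of `c("BF", "GS", "PSO", "SSFS", "none")`.
#' @param classifiers subset of `c("DT", "RF", "NB")`.
#' @param split a [split_config()].
#' @param filter a [correlation_filter_config()].
#' @param consensus a [consensus_config()].
#' @param grids named list of hyperparameter grids per classifier
#'   (defaults from [default_grid()]).
#' @param selector_configs named list overriding per-selector configs
#'   (`bf_config()`, `gs_config()`, `gpso_config()`, `ssfs_config()`).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(thresholds = canonical_thresholds(),
                            selectors = c("BF", "GS", "PSO", "SSFS", "none"),
                            classifiers = c("DT", "RF", "NB"),
                            split = split_config(),
                            filter = correlation_filter_config(),
                            consensus = consensus_config(),
                            grids = NULL,
                            selector_configs = list(),
                            seed = 1L) {
  if (!length(thresholds) || !length(selectors) || !length(classifiers)) {
    stop("configuration error: need at least one threshold, one selector ",
         "(or 'none') and one classifier", call. = FALSE)
  }
  stopifnot(all(selectors %in% c("BF", "GS", "PSO", "SSFS", "none")),
            all(classifiers %in% c("DT", "RF", "NB")))
  structure(list(thresholds = thresholds, selectors = selectors,
                 classifiers = classifiers, split = split, filter = filter,
                 consensus = consensus, grids = grids,
                 selector_configs = selector_configs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_selector <- function(selector, table, cfgs, seed) {
  switch(selector,
         none = {
           cache <- cfs_cache(table)
           new_feature_subset(cache, seq_len(ncol(table$values)), "none")
         },
         BF = best_first_search(table, cfgs$BF %||% bf_config()),
         GS = genetic_search(table, cfgs$GS %||% gs_config(seed = seed)),
         PSO = gpso_search(table, cfgs$PSO %||% gpso_config(seed = seed)),
         SSFS = ssfs_search(table, cfgs$SSFS %||% ssfs_config(seed = seed)),
         stop("unknown selector: ", selector, call. = FALSE))
}

#' Run the full model-development pipeline
#'
#' For every activity threshold: binarize, filter, split 65/35, select
#' features with every requested selector on the training portion, tune
#' each classifier's hyperparameters by cross-validated AUC, train the
#' winning spec, and validate by both test set and cross-validation.
#' Artifacts (datasets, subsets, reports, the validation grid and a run
#' manifest) are written under `out_dir` when given.
#'
#' @param table a [feature_table()] with IC50s (the labeled input).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return a `pipeline_result`: list with `grid` (one row per threshold
#'   x selector x classifier: feature counts, CV/test AUC and MCC),
#'   `models` (trained models keyed `threshold|selector|classifier`),
#'   `subsets`, `filter_reports`, and `manifest`.
#' @export
run_pipeline <- function(table, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  grid_rows <- list()
  models <- list()
  subsets <- list()
  filter_reports <- list()
  stage_seed <- derive_seeds(config$seed, length(config$thresholds))

  for (ti in seq_along(config$thresholds)) {
    thr <- config$thresholds[[ti]]
    labeled <- binarize_activity(table, thr)
    filt <- filter_features(labeled, config$filter)
    filter_reports[[thr$name]] <- filt$report
    split_cfg <- config$split
    split_cfg$seed <- stage_seed[ti]
    parts <- split_train_test(filt$table, split_cfg)

    for (sel in config$selectors) {
      fs <- run_selector(sel, parts$train, config$selector_configs,
                         stage_seed[ti])
      fs$dataset_name <- thr$name
      subsets[[paste(thr$name, sel, sep = "|")]] <- fs
      for (clf in config$classifiers) {
        grid <- (config$grids %||% list())[[clf]] %||% default_grid(clf)
        spec <- optimize_hyperparameters(parts$train, clf, grid, split_cfg,
                                         feature_subset = fs$columns)
        model <- train(parts$train, spec)
        cv <- cross_validate(parts$train, spec, split_cfg)
        ts <- validate_test_set(model, parts$test)
        key <- paste(thr$name, sel, clf, sep = "|")
        models[[key]] <- model
        grid_rows[[key]] <- data.frame(
          threshold = thr$name, cutoff_um = thr$cutoff_um, selector = sel,
          classifier = clf, n_features = length(fs$columns),
          merit = fs$score$merit,
          max_depth = spec$max_depth,
          num_trees = if (clf == "RF") spec$num_trees else NA,
          cv_auc = cv$auc, cv_mcc = cv$mcc,
          test_auc = ts$auc, test_mcc = ts$mcc,
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL
  manifest <- list(
    version = as.character(utils::packageVersion("cfscreen")),
    seed = config$seed,
    thresholds = vapply(config$thresholds, `[[`, numeric(1), "cutoff_um"),
    selectors = config$selectors,
    classifiers = config$classifiers,
    input_digest = content_digest(table),
    grid_digest = content_digest(grid),
    timestamp = format(Sys.time(), tz = "UTC"))
  result <- structure(list(grid = grid, models = models, subsets = subsets,
                           filter_reports = filter_reports,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    utils::write.csv(grid, file.path(out_dir, "validation_grid.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (key in names(subsets)) {
      write_feature_subset(subsets[[key]],
                           file.path(out_dir, paste0(
                             "subset_", gsub("\\|", "_", key), ".json")))
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d models over %d thresholds\n",
              nrow(x$grid), length(unique(x$grid$threshold))))
  print(utils::head(x$grid, 10))
  invisible(x)
}

#' Serialize / read a feature subset
#'
#' Small structured text (JSON) bundle so trained models can be
#' re-linked to the columns they were built on.
#'
#' @param subset a `feature_subset`.
#' @param path destination / source file.
#' @return `write_feature_subset`: `path` invisibly;
#'   `read_feature_subset`: the `feature_subset`.
#' @export
write_feature_subset <- function(subset, path) {
  jsonlite::write_json(
    list(selector = subset$selector, dataset = subset$dataset_name,
         columns = subset$columns,
         merit = subset$score$merit, k = subset$score$k,
         mean_class_corr = subset$score$mean_class_corr,
         mean_inter_corr = subset$score$mean_inter_corr),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_subset
#' @export
read_feature_subset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(columns = obj$columns,
                 score = structure(list(merit = obj$merit, k = obj$k,
                                        mean_class_corr = obj$mean_class_corr,
                                        mean_inter_corr = obj$mean_inter_corr),
                                   class = "merit_score"),
                 selector = obj$selector, dataset_name = obj$dataset),
            class = "feature_subset")
}

#' Select the top model panel from a validation grid
#'
#' The default rule reproduces the consensus-panel recipe this pipeline
#' emulates: keep the RF classifier with the BF and SSFS selectors and
#' drop the 1 uM threshold, yielding a 4-threshold x 2-selector panel
#' of 8 forests. A custom rule `"top_n_auc"` takes the `n` best models
#' by test AUC (ties by MCC, then fewer trees, then shallower depth).
#'
#' @param result a `pipeline_result`.
#' @param rule `"paper_default"` or `"top_n_auc"`.
#' @param n panel size for `"top_n_auc"`.
#' @param drop_cutoff_um threshold(s) excluded by the default rule
#'   (default 1 uM).
#' @return named list of `trained_model`s.
#' @export
select_top_models <- function(result, rule = c("paper_default", "top_n_auc"),
                              n = 8, drop_cutoff_um = 1) {
  rule <- match.arg(rule)
  g <- result$grid
  keys <- if (rule == "paper_default") {
    sel <- g$classifier == "RF" & g$selector %in% c("BF", "SSFS") &
      !(g$cutoff_um %in% drop_cutoff_um)
    if (!any(sel)) {
      stop("selection error: no RF/BF+SSFS models in the grid", call. = FALSE)
    }
    paste(g$threshold[sel], g$selector[sel], g$classifier[sel], sep = "|")
  } else {
    ord <- order(-g$test_auc, -g$test_mcc, g$num_trees, g$max_depth,
                 na.last = FALSE)
    if (n > nrow(g)) stop("selection error: grid smaller than n", call. = FALSE)
    paste(g$threshold[ord], g$selector[ord], g$classifier[ord],
          sep = "|")[seq_len(n)]
  }
  missing <- setdiff(keys, names(result$models))
  if (length(missing)) {
    stop("selection error: grid incomplete for requested rule (missing ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  }
  result$models[keys]
}
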