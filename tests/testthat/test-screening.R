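panel_fixture <- function(effect = 2, seed = 1, n_models = 2) {
  spec <- synthetic_spec(n_active = 80, n_inactive = 80, n_informative = 6,
                         n_redundant = 0, n_zero_variance = 0, n_noise = 8,
                         effect_size = effect, seed = seed)
  ds <- generate_training_dataset(spec)
  tbl <- binarize_activity(ds$table, activity_threshold(11.4, "SET05"))
  fs <- best_first_search(tbl)
  models <- lapply(seq_len(n_models), function(i) {
    train(tbl, model_spec("RF", max_depth = 5, num_trees = 25,
                          feature_subset = fs, seed = 100 + i))
  })
  names(models) <- paste0("rf", seq_len(n_models))
  list(spec = spec, table = tbl, models = models,
       actives = ft_subset(tbl, rows = tbl$labels == "active"))
}

test_that("consensus_vote applies the strict > rule", {
  cfg <- consensus_config(prob_threshold = 0.9)
  expect_true(consensus_vote(c(0.95, 0.99, 0.91), cfg))
  expect_false(consensus_vote(c(0.95, 0.9, 0.99), cfg))   # boundary not a hit
  expect_false(consensus_vote(c(0.95, 0.5), cfg))
  expect_error(consensus_vote(numeric(0), cfg), "empty")

  quorum <- consensus_config(prob_threshold = 0.9, require_unanimous = FALSE,
                             min_votes = 2)
  expect_true(consensus_vote(c(0.95, 0.91, 0.2), quorum))
  expect_false(consensus_vote(c(0.95, 0.2, 0.2), quorum))
})

test_that("tanimoto matches the popcount oracle", {
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)     # no on-bits convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "equal length")

  set.seed(61)
  for (i in 1:20) {
    a <- rbinom(166, 1, 0.3); b <- rbinom(166, 1, 0.3)
    expect_equal(tanimoto(a, b), tanimoto_oracle(a, b))
  }
})

test_that("nearest neighbor equals the brute-force scan", {
  fx <- panel_fixture(seed = 3)
  lib <- generate_screening_library(fx$spec, 50, 0.2)$table
  nn <- nearest_neighbor_similarity(lib, fx$actives)
  bin <- col_ids(fx$actives)[fx$actives$col_kind == "binary"]
  A <- fx$actives$values[, bin]
  for (i in seq_len(50)) {
    sims <- apply(A, 1, tanimoto_oracle, a = lib$values[i, bin])
    expect_equal(nn$nn_similarity[i], max(sims))
    expect_equal(nn$nn_id[i], row_ids(fx$actives)[which.max(sims)])
  }
  # a query equal to some active has similarity 1 with it
  self <- nearest_neighbor_similarity(ft_subset(fx$actives, rows = 1),
                                      fx$actives)
  expect_equal(self$nn_similarity, 1)
  expect_equal(self$nn_id, row_ids(fx$actives)[1])

  no_bits <- feature_table(matrix(rnorm(10), 5, 2))
  expect_error(nearest_neighbor_similarity(no_bits, no_bits),
               "labels|binary")
})

test_that("hit_rate reports 3 significant figures", {
  expect_equal(hit_rate(46, 6447184), 0.000713)
  expect_equal(hit_rate(0, 100), 0)
  expect_equal(hit_rate(100, 100), 100)
  expect_error(hit_rate(5, 4), "n_hits")
})

test_that("screening output is invariant to chunk size", {
  fx <- panel_fixture(seed = 7)
  lib <- generate_screening_library(fx$spec, 400, 0.05)$table
  r_small <- screen_library(lib, fx$models, fx$actives,
                            consensus_config(chunk_size = 37))
  r_big <- screen_library(lib, fx$models, fx$actives,
                          consensus_config(chunk_size = 10000))
  expect_identical(r_small, r_big)
  expect_equal(r_small$row_id, row_ids(lib))   # output order = input order

  # file streaming equals in-memory screening
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(lib, path)
  r_file <- screen_library(path, fx$models, fx$actives,
                           consensus_config(chunk_size = 111))
  expect_equal(r_file$hit, r_small$hit)
  expect_equal(r_file[[paste0("prob_rf1")]], r_small[[paste0("prob_rf1")]])
})

test_that("hit sets shrink with threshold and panel size", {
  fx <- panel_fixture(seed = 9, n_models = 3)
  lib <- generate_screening_library(fx$spec, 300, 0.1)$table
  hits_at <- function(thr, models) {
    r <- screen_library(lib, models, NULL, consensus_config(prob_threshold = thr))
    r$row_id[r$hit]
  }
  h_low <- hits_at(0.6, fx$models)
  h_high <- hits_at(0.9, fx$models)
  expect_true(all(h_high %in% h_low))
  # adding a model never grows the unanimous hit set
  h_two <- hits_at(0.8, fx$models[1:2])
  h_three <- hits_at(0.8, fx$models)
  expect_true(all(h_three %in% h_two))
  # unanimity hits are a subset of every single model's hits
  for (m in seq_along(fx$models)) {
    expect_true(all(h_three %in% hits_at(0.8, fx$models[m])))
  }
})

test_that("strong-effect panels recover planted actives", {
  # Strict unanimous P > 0.9 voting is precision-first: the false-hit
  # rate stays tiny at any effect size, while recall of planted actives
  # crosses 0.8 only once classes separate clearly (effect ~2.5+; at the
  # moderate effect = 2 world it plateaus near 0.7 because borderline
  # actives rarely get >90% of bootstrap trees in every panel model).
  # 5 seeds per world keep the RF cost inside the suite budget.
  run_world <- function(effect, seeds) {
    recalls <- fprs <- numeric(0)
    for (s in seeds) {
      fx <- panel_fixture(effect = effect, seed = 20 + s)
      gen <- generate_screening_library(fx$spec, 400, 0.05)
      res <- screen_library(gen$table, fx$models, fx$actives)
      planted <- gen$truth$planted_active
      recalls <- c(recalls, mean(res$hit[planted]))
      fprs <- c(fprs, mean(res$hit[!planted]))
      # hits carry similarity annotation, non-hits do not
      expect_true(all(!is.na(res$nn_similarity[res$hit])))
      expect_true(all(is.na(res$nn_similarity[!res$hit])))
    }
    c(recall = mean(recalls), fpr = mean(fprs))
  }
  strong <- run_world(3, 1:5)
  expect_gte(strong["recall"], 0.8)
  expect_lte(strong["fpr"], 0.01)
  moderate <- run_world(2, 1:5)
  expect_gte(moderate["recall"], 0.55)
  expect_lte(moderate["fpr"], 0.01)
})

test_that("degenerate screens behave", {
  fx <- panel_fixture(seed = 31)
  lib <- generate_screening_library(fx$spec, 60, 0)$table
  res <- screen_library(lib, fx$models, fx$actives,
                        consensus_config(prob_threshold = 0.999))
  s <- attr(res, "summary")
  if (s$n_hits == 0) expect_equal(s$hit_rate, 0)

  expect_error(screen_library(ft_subset(lib, cols = 1:2), fx$models),
               "schema error")
  expect_error(screen_library(lib, list()), "empty")
})
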