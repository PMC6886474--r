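test_that("class_feature_correlation handles the closed-form cases", {
  ft <- tiny_table()
  expect_equal(class_feature_correlation(ft, "f_sep"), 1)   # equals the class
  expect_equal(class_feature_correlation(ft, "f_zero"), 0)  # constant column

  set.seed(77)
  big <- random_table(n = 10000, d = 1)
  expect_lt(class_feature_correlation(big, 1), 0.05)        # independent
})

test_that("merit matches Eq-style closed forms and the oracle", {
  ft <- tiny_table()
  # k = 1: merit is exactly rcf
  m1 <- merit(ft, "f_cont")
  expect_equal(m1$merit, m1$mean_class_corr)
  expect_equal(m1$k, 1)
  expect_equal(m1$mean_inter_corr, 0)

  # duplicated feature: k=2, rff=1 -> merit = 2*rcf / sqrt(4) = rcf
  dup <- feature_table(cbind(a = c(0, 1, 0, 1, 1, 0), b = c(0, 1, 0, 1, 1, 0)),
                       labels = tiny_table()$labels)
  m2 <- merit(dup, c("a", "b"))
  expect_equal(m2$mean_inter_corr, 1)
  expect_equal(m2$merit, m2$mean_class_corr)

  expect_error(merit(ft, character(0)), "empty subset")
  expect_error(merit(ft, c("f_sep", "f_sep")), "duplicate")
  expect_error(merit(ft, "ghost"), "unknown column")

  # dual-implementation oracle over every subset of an 8-column table
  tbl <- random_table(n = 40, d = 8, effect = 1, n_signal = 3, seed = 19)
  y <- as.numeric(tbl$labels == "active")
  for (mask in 1:255) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:7)) != 0L)
    expect_equal(merit(tbl, cols)$merit, merit_oracle(tbl$values, y, cols),
                 tolerance = 1e-12)
  }
})

test_that("merit decomposition satisfies the defining identity", {
  tbl <- random_table(n = 50, d = 6, effect = 0.8, n_signal = 2, seed = 3)
  for (cols in list(1, c(2, 5), c(1, 3, 4, 6))) {
    s <- merit(tbl, cols)
    expect_equal(s$merit,
                 s$k * s$mean_class_corr /
                   sqrt(s$k + s$k * (s$k - 1) * s$mean_inter_corr))
  }
})

test_that("exhaustive search finds planted structure and breaks ties", {
  # one informative column among noise
  hits <- 0
  for (s in 1:20) {
    ds <- generate_training_dataset(synthetic_spec(
      n_active = 120, n_inactive = 80, n_informative = 1, n_redundant = 0,
      n_zero_variance = 0, n_noise = 7, frac_binary = 0, effect_size = 1.5,
      seed = s))
    hits <- hits + ("inf_001" %in% exhaustive_search(ds$table)$columns)
  }
  expect_gte(hits, 19)

  # two perfectly redundant informative columns: the duplicated pair has
  # the same merit as either singleton, so the smaller-k tie-break keeps
  # exactly one (the first in column order)
  set.seed(4)
  x <- rnorm(60); y <- rep(c(1, 0), 30)
  tbl <- feature_table(cbind(a = x + y, b = x + y),
                       labels = ifelse(y == 1, "active", "inactive"))
  expect_equal(exhaustive_search(tbl)$columns, "a")

  # d = 1 and the guard
  one <- random_table(n = 20, d = 1)
  expect_equal(exhaustive_search(one)$columns, "v01")
  expect_error(exhaustive_search(random_table(n = 10, d = 16)), "max_dim")
})

test_that("best-first search dominates singletons and tracks the oracle", {
  agree <- 0
  for (s in 1:20) {
    tbl <- random_table(n = 60, d = 10, effect = 1, n_signal = 3, seed = 100 + s)
    bf <- best_first_search(tbl)
    ex <- exhaustive_search(tbl)
    singles <- vapply(seq_len(10), function(j) merit(tbl, j)$merit, numeric(1))
    expect_gte(bf$score$merit, max(singles))
    expect_gte(ex$score$merit, bf$score$merit)        # oracle dominance
    agree <- agree + (abs(bf$score$merit - ex$score$merit) < 1e-12)
  }
  expect_gte(agree / 20, 0.9)
})

test_that("more best-first patience never hurts", {
  for (s in 1:5) {
    tbl <- random_table(n = 50, d = 9, effect = 0.8, n_signal = 3, seed = 200 + s)
    m1 <- best_first_search(tbl, bf_config(patience = 1))$score$merit
    m5 <- best_first_search(tbl, bf_config(patience = 5))$score$merit
    expect_gte(m5, m1)
  }
})

test_that("genetic search is seed-deterministic and returns fresh scores", {
  tbl <- random_table(n = 60, d = 10, effect = 1, n_signal = 3, seed = 8)
  g1 <- genetic_search(tbl, gs_config(seed = 7))
  g2 <- genetic_search(tbl, gs_config(seed = 7))
  expect_identical(g1$columns, g2$columns)
  expect_equal(g1$score$merit, merit(tbl, g1$columns)$merit)  # no stale score
})

test_that("gpso degenerate weights behave as forced inheritance", {
  tbl <- random_table(n = 50, d = 8, effect = 1, n_signal = 2, seed = 12)
  # w = (1,0,0): positions never move; result = best initial particle
  frozen <- gpso_search(tbl, gpso_config(w1 = 1, w2 = 0, w3 = 0, seed = 3,
                                         iterations = 15))
  init <- gpso_search(tbl, gpso_config(w1 = 1, w2 = 0, w3 = 0, seed = 3,
                                       iterations = 0))
  expect_identical(frozen$columns, init$columns)

  # invalid weights refused
  expect_error(gpso_config(w1 = 0.5, w2 = 0.5, w3 = 0.5), "sum to 1")

  g <- gpso_search(tbl, gpso_config(seed = 5))
  expect_equal(g$score$merit, merit(tbl, g$columns)$merit)
  expect_identical(g$columns, gpso_search(tbl, gpso_config(seed = 5))$columns)
})

test_that("ssfs honors its search space and stays compact", {
  tbl <- random_table(n = 60, d = 10, effect = 1.2, n_signal = 2, seed = 31)
  # top_k = 1 forces the top-ranked singleton
  top1 <- ssfs_search(tbl, ssfs_config(top_k = 1))
  rcf <- vapply(1:10, function(j) class_feature_correlation(tbl, j), numeric(1))
  expect_equal(top1$columns, col_ids(tbl)[which.max(rcf)])

  expect_warning(ssfs_search(tbl, ssfs_config(top_k = 50)), "clamped")

  s <- ssfs_search(tbl, ssfs_config(top_k = 8, seed = 2))
  expect_equal(s$score$merit, merit(tbl, s$columns)$merit)

  # SSFS at most as large as BF in the majority of random instances
  smaller <- 0
  for (i in 1:20) {
    t2 <- random_table(n = 60, d = 12, effect = 0.9, n_signal = 3,
                       seed = 300 + i)
    n_ssfs <- length(ssfs_search(t2, ssfs_config(top_k = 12, seed = 1))$columns)
    n_bf <- length(best_first_search(t2)$columns)
    smaller <- smaller + (n_ssfs <= n_bf)
  }
  expect_gt(smaller / 20, 0.5)
})

test_that("duplicating a singleton is merit-neutral (k = 1 -> 2)", {
  # duplicating the only member gives rff = 1 and merit 2r/sqrt(4) = r:
  # exactly the singleton merit, so the smaller-k tie-break discards the
  # duplicate. (For k >= 2 a duplicate CAN raise merit by inflating k
  # while diluting the rff mean — a documented quirk of the heuristic.)
  tbl <- random_table(n = 50, d = 6, effect = 1, n_signal = 2, seed = 17)
  vals <- cbind(tbl$values, dup = tbl$values[, 1])
  aug <- feature_table(vals, labels = tbl$labels)
  expect_equal(merit(aug, c(1, 7))$merit, merit(aug, 1)$merit)
})

test_that("reduction_rate arithmetic", {
  expect_equal(reduction_rate(1872, 37), 1835 / 1872)  # 98.02%
  expect_equal(round(100 * reduction_rate(1872, 37), 2), 98.02)
  expect_equal(reduction_rate(10, 10), 0)
  expect_equal(reduction_rate(10, 0), 1)
  expect_error(reduction_rate(5, 6), "n_selected")
})
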