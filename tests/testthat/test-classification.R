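sep_table <- function(n = 80, seed = 1) {
  # linearly separable: one continuous column fully decides the class
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  vals <- cbind(sig = y * 2 + runif(n), pad = rnorm(n))
  rownames(vals) <- sprintf("s%03d", 1:n)
  feature_table(vals, labels = ifelse(y == 1, "active", "inactive"))
}

test_that("65/35 stratified split arithmetic and determinism", {
  ds <- generate_training_dataset(synthetic_spec(
    n_informative = 3, n_redundant = 0, n_zero_variance = 0, n_noise = 3,
    seed = 5))
  sp <- split_train_test(ds$table, split_config(seed = 11))
  expect_equal(nrow(sp$train$values), 261L)   # floor(0.65 * 402)
  expect_equal(nrow(sp$test$values), 141L)

  # class proportions within one compound of the global proportion
  p_global <- mean(ds$table$labels == "active")
  for (part in sp) {
    n_part <- nrow(part$values)
    expect_lte(abs(sum(part$labels == "active") - p_global * n_part), 1)
  }

  sp2 <- split_train_test(ds$table, split_config(seed = 11))
  expect_identical(row_ids(sp$train), row_ids(sp2$train))
  expect_length(intersect(row_ids(sp$train), row_ids(sp$test)), 0)

  tiny <- ft_subset(ds$table, rows = c(1, 2, 267))  # one lone inactive
  expect_error(split_train_test(tiny, split_config()), "stratification")
})

test_that("decision tree fits separable data perfectly", {
  tbl <- sep_table()
  m <- train(tbl, model_spec("DT", max_depth = 4))
  p <- predict_proba(m, tbl)
  expect_equal(as.numeric(p > 0.5), as.numeric(tbl$labels == "active"))
})

test_that("1-tree forest without bootstrap equals a gain-ratio tree", {
  tbl <- random_table(n = 60, d = 5, effect = 1.2, n_signal = 2, seed = 9)
  rf1 <- train(tbl, model_spec("RF", max_depth = 4, num_trees = 1,
                               bootstrap = FALSE, mtry = 5))
  tree <- cfscreen:::grow_tree(tbl$values, as.numeric(tbl$labels == "active"),
                               criterion = "gain_ratio", max_depth = 4)
  p_rf <- predict_proba(rf1, tbl)
  p_tree <- cfscreen:::predict_tree(tree, tbl$values)
  expect_equal(p_rf > 0.5, p_tree > 0.5)
})

test_that("naive Bayes posterior matches the hand-computed 4-cell rule", {
  # single binary feature; counts: active (1:3, 0:1), inactive (1:1, 0:3)
  vals <- matrix(c(1, 1, 1, 0, 1, 0, 0, 0), ncol = 1,
                 dimnames = list(paste0("r", 1:8), "bit"))
  tbl <- feature_table(vals, labels = rep(c("active", "inactive"), each = 4))
  m <- train(tbl, model_spec("NB"))
  p <- predict_proba(m, tbl)
  # Laplace: P(1|act) = (3+1)/(4+2) = 2/3, P(1|inact) = (1+1)/(4+2) = 1/3
  # priors 1/2 -> P(act|x=1) = (2/3)/(2/3 + 1/3) = 2/3
  expect_equal(unname(p[1]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(p[8]), 1 / 3, tolerance = 1e-12)
})

test_that("probabilities are valid and batching-invariant", {
  tbl <- random_table(n = 50, d = 4, effect = 1, n_signal = 2, seed = 21)
  for (clf in c("DT", "RF", "NB")) {
    m <- train(tbl, model_spec(clf, max_depth = 3, num_trees = 10))
    p_batch <- predict_proba(m, tbl)
    expect_true(all(p_batch >= 0 & p_batch <= 1))
    p_rows <- vapply(seq_len(50), function(i) {
      predict_proba(m, ft_subset(tbl, rows = i))
    }, numeric(1))
    expect_equal(unname(p_batch), unname(p_rows))
  }
  m <- train(tbl, model_spec("RF", num_trees = 10))
  expect_error(predict_proba(m, ft_subset(tbl, cols = 1:2)), "schema error")
})

test_that("roc_auc matches the all-pairs concordance oracle", {
  y <- rep(c(1, 0), each = 5)
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), y), 1)   # perfect split
  expect_equal(roc_auc(rep(0.3, 10), y), 0.5)            # complete ties
  expect_error(roc_auc(runif(4), rep(1, 4)), "both classes")

  set.seed(14)
  for (rep in 1:5) {
    scores <- sample(seq(0, 1, 0.1), 40, replace = TRUE)  # induce ties
    yy <- rbinom(40, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_equal(roc_auc(scores, yy), auc_oracle(scores, yy))
  }

  # invariance under strictly monotone transform
  scores <- runif(30); yy <- rbinom(30, 1, 0.5)
  expect_equal(roc_auc(scores, yy), roc_auc(qlogis(scores * 0.8 + 0.1), yy))
})

test_that("mcc follows the printed formula and its conventions", {
  expect_equal(mcc(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1)
  expect_equal(mcc(list(tp = 25, tn = 25, fp = 25, fn = 25)), 0)
  expect_equal(mcc(list(tp = 3, tn = 4, fp = 1, fn = 2)),
               10 / sqrt(4 * 5 * 5 * 6))
  expect_equal(mcc(list(tp = 0, tn = 10, fp = 0, fn = 0)), 0)  # zero factor

  # label/prediction swap symmetry: MCC is unchanged
  cc <- confusion_counts(c(0.9, 0.2, 0.8, 0.4), c(1, 0, 0, 1))
  swapped <- list(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
  expect_equal(mcc(cc), mcc(swapped))
})

test_that("cross-validation pools out-of-fold predictions", {
  tbl <- sep_table(n = 40, seed = 2)
  cv <- cross_validate(tbl, model_spec("RF", max_depth = 3, num_trees = 15),
                       split_config(cv_folds = 5, seed = 3))
  expect_gte(cv$auc, 0.95)
  expect_length(cv$pooled_scores, 40)
  expect_false(anyNA(cv$pooled_scores))

  # leave-one-out boundary: k = n runs and pools n predictions
  ten <- ft_subset(tbl, rows = 1:10)
  loo <- cross_validate(ten, model_spec("NB"),
                        split_config(cv_folds = 10, seed = 1))
  expect_length(loo$pooled_scores, 10)
  expect_error(cross_validate(ten, model_spec("NB"),
                              split_config(cv_folds = 11)),
               "fold count")
})

test_that("hyperparameter grid search is dominant and tie-broken", {
  tbl <- sep_table(n = 60, seed = 4)
  # singleton grid: no choice
  one <- optimize_hyperparameters(tbl, "RF",
                                  grid = list(max_depth = 3, num_trees = 10),
                                  config = split_config(cv_folds = 4, seed = 2))
  expect_equal(one$max_depth, 3)
  expect_equal(one$num_trees, 10)

  win <- optimize_hyperparameters(
    tbl, "RF", grid = list(max_depth = c(2, 4), num_trees = c(5, 15)),
    config = split_config(cv_folds = 4, seed = 2))
  scores <- attr(win, "grid_scores")
  expect_equal(attr(win, "cv_auc"), max(scores$cv_auc))
  # tie-break toward the cheaper model among the top scorers
  top <- scores[scores$cv_auc == max(scores$cv_auc), ]
  expect_equal(win$num_trees, min(top$num_trees))

  expect_error(optimize_hyperparameters(tbl, "RF",
                                        grid = list(max_depth = integer(0),
                                                    num_trees = 5)),
               "empty grid")

  # default grid spans the observed tuned ranges (depth 2-10, trees 13-245)
  g <- default_grid("RF")
  expect_true(min(g$max_depth) <= 2 && max(g$max_depth) >= 10)
  expect_true(min(g$num_trees) <= 13 && max(g$num_trees) >= 245)
})

test_that("training and validation are pure functions of seed", {
  tbl <- random_table(n = 50, d = 5, effect = 1, n_signal = 2, seed = 6)
  s <- model_spec("RF", max_depth = 4, num_trees = 10, seed = 33)
  expect_identical(predict_proba(train(tbl, s), tbl),
                   predict_proba(train(tbl, s), tbl))
  c1 <- cross_validate(tbl, s, split_config(cv_folds = 5, seed = 8))
  c2 <- cross_validate(tbl, s, split_config(cv_folds = 5, seed = 8))
  expect_identical(c1$pooled_scores, c2$pooled_scores)
})
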