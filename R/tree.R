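# First-party CART-style binary trees. No tree/forest package ships with
# the target image, and the forest contract here (information-gain-ratio
# splits with per-node sqrt(d) feature sampling) is not what CRAN's
# forests implement anyway, so the grower is written once and shared by
# the single-tree and forest classifiers.

entropy2 <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

# Best split for one feature: returns c(score, threshold) or NULL.
# `criterion`: "gini" (impurity decrease) or "gain_ratio".
best_split_feature <- function(x, y, criterion) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(x)
  cut_at <- which(xs[-n] < xs[-1])     # split between distinct values
  if (!length(cut_at)) return(NULL)
  cum1 <- cumsum(ys)
  n_l <- cut_at
  n_r <- n - n_l
  p_l <- cum1[cut_at] / n_l
  p_r <- (cum1[n] - cum1[cut_at]) / n_r
  p <- cum1[n] / n
  if (criterion == "gini") {
    parent <- 2 * p * (1 - p)
    child <- (n_l * 2 * p_l * (1 - p_l) + n_r * 2 * p_r * (1 - p_r)) / n
    score <- parent - child
  } else {
    gain <- entropy2(p) - (n_l * entropy2(p_l) + n_r * entropy2(p_r)) / n
    split_info <- entropy2(n_l / n)
    score <- ifelse(split_info > 0, gain / split_info, 0)
  }
  i <- which.max(score)
  c(score[i], (xs[cut_at[i]] + xs[cut_at[i] + 1]) / 2)
}

grow_tree <- function(X, y, criterion = "gini", max_depth = 5,
                      min_split = 2, mtry = ncol(X), depth = 0) {
  n <- length(y)
  p1 <- mean(y)
  leaf <- list(leaf = TRUE, prob = p1, n = n)
  if (depth >= max_depth || n < min_split || p1 == 0 || p1 == 1) return(leaf)
  cand <- if (mtry < ncol(X)) sort(sample.int(ncol(X), mtry)) else seq_len(ncol(X))
  best <- NULL; best_j <- NA_integer_
  for (j in cand) {
    sp <- best_split_feature(X[, j], y, criterion)
    if (is.null(sp)) next
    if (is.null(best) || sp[1] > best[1]) { best <- sp; best_j <- j }
  }
  if (is.null(best) || best[1] <= 0) return(leaf)
  go_l <- X[, best_j] <= best[2]
  list(leaf = FALSE, col = best_j, thr = best[2],
       prob = p1, n = n,
       left = grow_tree(X[go_l, , drop = FALSE], y[go_l], criterion,
                        max_depth, min_split, mtry, depth + 1),
       right = grow_tree(X[!go_l, , drop = FALSE], y[!go_l], criterion,
                         max_depth, min_split, mtry, depth + 1))
}

# (misclassification count on training data, number of leaves)
tree_risk <- function(node) {
  if (node$leaf) {
    return(c(err = node$n * min(node$prob, 1 - node$prob), leaves = 1))
  }
  tree_risk(node$left) + tree_risk(node$right)
}

# Cost-complexity post-pruning with complexity parameter `cp`, on the
# training misclassification rate: a subtree whose error reduction per
# extra leaf is <= cp * n_total collapses to a leaf (weakest-link,
# applied bottom-up).
prune_tree <- function(node, cp, n_total) {
  if (node$leaf) return(node)
  node$left <- prune_tree(node$left, cp, n_total)
  node$right <- prune_tree(node$right, cp, n_total)
  r <- tree_risk(node)
  r_leaf <- node$n * min(node$prob, 1 - node$prob)
  if ((r_leaf - r["err"]) / (r["leaves"] - 1) <= cp * n_total) {
    return(list(leaf = TRUE, prob = node$prob, n = node$n))
  }
  node
}

# Vectorized prediction: P(active) per row.
predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(nd, idx) {
    if (!length(idx)) return()
    if (nd$leaf) { out[idx] <<- nd$prob; return() }
    go_l <- X[idx, nd$col] <= nd$thr
    recurse(nd$left, idx[go_l])
    recurse(nd$right, idx[!go_l])
  }
  recurse(node, seq_len(nrow(X)))
  out
}
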