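test_that("confusion counts tally per class and add over sample subsets", {
  y <- matrix(c(1, 0, 1, 0,
                0, 1, 1, 0), 4, 2)
  p <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 1), 4, 2)
  cc <- confusion_counts(y, p)
  # manual tally: class 1 TP{1}, FP{2}, FN{3}; class 2 TP{2,3}, FP{4}, FN{}
  expect_identical(cc$tp, c(1L, 2L))
  expect_identical(cc$fp, c(1L, 1L))
  expect_identical(cc$fn, c(1L, 0L))
  # perfect agreement and full disagreement
  cc_eq <- confusion_counts(y, y)
  expect_true(all(cc_eq$fp == 0L) && all(cc_eq$fn == 0L))
  cc_neq <- confusion_counts(y, 1 - y)
  expect_true(all(cc_neq$tp == 0L))
  # additivity over disjoint sample sets
  cc_a <- confusion_counts(y[1:2, , drop = FALSE], p[1:2, , drop = FALSE])
  cc_b <- confusion_counts(y[3:4, , drop = FALSE], p[3:4, , drop = FALSE])
  expect_identical(cc_a$tp + cc_b$tp, cc$tp)
  expect_identical(cc_a$fn + cc_b$fn, cc$fn)
  expect_error(confusion_counts(y, p[1:2, , drop = FALSE]), "shape")
})

test_that("macro F1 follows the defining formulas with 0/0 -> 0", {
  y <- matrix(c(1, 1, 0), 3, 1)
  p <- matrix(c(1, 0, 1), 3, 1)
  rep1 <- f1_macro(confusion_counts(y, p))   # TP=1, FP=1, FN=1
  expect_equal(rep1$per_class$precision, 0.5)
  expect_equal(rep1$per_class$recall, 0.5)
  expect_equal(rep1$per_class$f1, 0.5)
  # perfect predictions
  expect_equal(f1_macro(confusion_counts(y, y))$macro, 1)
  # macro is the plain mean including zero classes: F1 {1, 0} -> 0.5
  y2 <- cbind(y, 0); p2 <- cbind(y, 0)
  y2[1, 2] <- 1                              # class 2 has support, never hit
  expect_equal(f1_macro(confusion_counts(y2, p2))$macro, 0.5)
})

test_that("macro F1 agrees with a brute-force implementation on random matrices", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(3:20, 1); C <- sample(2:6, 1)
    y <- random_label_matrix(n, C)
    p <- random_label_matrix(n, C)
    expect_equal(f1_macro(confusion_counts(y, p))$macro,
                 brute_macro_f1(y, p), tolerance = 1e-12)
  }
})

test_that("thresholding uses a closed lower bound and the default grid has 17 values", {
  g <- threshold_grid()
  expect_length(g, 17)
  expect_equal(g[1], 0.1); expect_equal(g[17], 0.9)
  probs <- matrix(c(0.3, 0.29, 0.31), 3, 1)
  expect_identical(as.vector(apply_thresholds(probs, 0.3)), c(1L, 0L, 1L))
})

test_that("single-threshold search returns the grid argmax with low tie-break", {
  set.seed(22)
  # perfectly separated probabilities: every grid value scores 1, the
  # tie-break returns the lowest threshold
  y <- random_label_matrix(20, 3)
  res <- search_single_threshold(y + 0, y)
  expect_equal(res$threshold, 0.1)
  expect_equal(res$score, 1)
  # construct calibrated probabilities whose exhaustive-grid optimum is 0.3:
  # positives uniformly above 0.3, negatives below 0.3 with contamination
  # just above 0.25 so lower thresholds lose precision
  n <- 200
  y1 <- matrix(rbinom(n, 1, 0.5), n, 1)
  p1 <- matrix(ifelse(y1 == 1, runif(n, 0.3, 1), runif(n, 0.26, 0.299)), n, 1)
  res1 <- search_single_threshold(p1, y1)
  # exhaustive-grid oracle
  oracle <- sapply(threshold_grid(), function(t)
    brute_macro_f1(y1, apply_thresholds(p1, t)))
  expect_equal(res1$threshold, threshold_grid()[which.max(oracle)])
  expect_equal(res1$threshold, 0.3)
  expect_equal(res1$trace$score, oracle)
  # permutation invariance of the search
  perm <- sample(n)
  res_p <- search_single_threshold(p1[perm, , drop = FALSE],
                                   y1[perm, , drop = FALSE])
  expect_equal(res_p$threshold, res1$threshold)
  expect_equal(res_p$score, res1$score)
})

test_that("greedy per-class search recovers distinct optima and never degrades", {
  set.seed(23)
  # 2-class toy with known optima 0.6 (class 1) and 0.2 (class 2)
  n <- 300
  y <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.3))
  p <- cbind(ifelse(y[, 1] == 1, runif(n, 0.6, 1), runif(n, 0.5, 0.59)),
             ifelse(y[, 2] == 1, runif(n, 0.2, 1), runif(n, 0.05, 0.19)))
  res <- greedy_multi_threshold(p, y, init_threshold = 0.4)
  # oracle: exhaustive search over the 17 x 17 grid
  g <- threshold_grid()
  grid_scores <- outer(seq_along(g), seq_along(g), Vectorize(function(i, j)
    brute_macro_f1(y, apply_thresholds(p, c(g[i], g[j])))))
  best <- which(grid_scores == max(grid_scores), arr.ind = TRUE)[1, ]
  expect_equal(res$score, max(grid_scores))
  expect_equal(res$thresholds, c(0.6, 0.2))
  expect_equal(c(g[best[1]], g[best[2]]), c(0.6, 0.2))
  # perfectly separated probabilities at init: output keeps the init value
  # and the trace is constant
  ysep <- random_label_matrix(30, 4)
  res_sep <- greedy_multi_threshold(ysep + 0, ysep, init_threshold = 0.3,
                                    grid = 0.3)
  expect_equal(res_sep$thresholds, rep(0.3, 4))
  expect_true(all(res_sep$trace == 1))
  # random instances: trace non-decreasing, final >= init score
  for (rep in 1:25) {
    n <- sample(20:60, 1); C <- sample(2:5, 1)
    y <- random_label_matrix(n, C, p = 0.3)
    p <- matrix(runif(n * C), n, C)
    r <- greedy_multi_threshold(p, y, init_threshold = 0.5)
    expect_true(all(diff(r$trace) >= -1e-12))
    expect_gte(r$score, macro_f1_score(p, y, 0.5))
  }
})

test_that("zero-support classes keep their initial threshold", {
  set.seed(24)
  y <- cbind(rbinom(40, 1, 0.5), 0)
  p <- matrix(runif(80), 40, 2)
  res <- greedy_multi_threshold(p, y, init_threshold = 0.35)
  expect_identical(res$unoptimized, 2L)
  expect_equal(res$thresholds[2], 0.35)
})

test_that("ensemble averaging is the elementwise mean with id checks", {
  set.seed(25)
  p <- matrix(runif(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(ensemble_average(list(p)), p)
  expect_equal(ensemble_average(list(p, 1 - p)),
               matrix(0.5, 4, 3, dimnames = dimnames(p)))
  expect_equal(ensemble_average(list(p, p, p)), p)
  q <- p; rownames(q) <- paste0("t", 1:4)
  expect_error(ensemble_average(list(p, q)), "ids")
  expect_error(ensemble_average(list(p, p[1:2, ])), "shape")
})
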