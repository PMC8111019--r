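test_that("ROC handles perfect, uninformative and worked examples", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden_j, 1)
  flat <- roc_curve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$youden_j, 0)
  ex <- roc_curve(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
  expect_equal(ex$auc, 5 / 6)
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(roc_curve(c(0.1), c(1, 0)), "equal length")
})

test_that("trapezoidal AUC equals rank concordance on random instances", {
  set.seed(41)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 1 / sample(c(3, 7, 11), 1)), n,
                     replace = TRUE)  # coarse grid forces ties
    expect_equal(roc_curve(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)
    got <- roc_curve(scores, labels)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("the Youden threshold matches an exhaustive sweep", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    curve <- roc_curve(scores, labels)
    sweep <- oracle_youden(scores, labels)
    expect_equal(youden(curve), sweep$threshold)
    expect_equal(curve$youden_j, sweep$j, tolerance = 1e-12)
  }
})

test_that("confusion counts enumerate the four cells", {
  expect_equal(as.vector(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               c(2, 0, 0, 2))
  expect_equal(as.vector(confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1))),
               c(0, 2, 2, 0))
  # hand-counted 6-item case: TP=2, FN=1, FP=1, TN=2
  cm <- confusion_counts(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 1, 0, 0))
  expect_equal(cm["positive", "positive"], 2)
  expect_equal(cm["positive", "negative"], 1)
  expect_equal(cm["negative", "positive"], 1)
  expect_equal(cm["negative", "negative"], 2)
  expect_equal(sum(cm), 6)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("fold assignment balances sizes and classes", {
  f1 <- make_folds(sprintf("a%03d", 1:100), 10, seed = 5)
  expect_equal(as.vector(table(f1)), rep(10L, 10))
  f2 <- make_folds(sprintf("b%03d", 1:102), 10, seed = 5)
  expect_equal(sort(as.vector(table(f2)), decreasing = TRUE),
               c(11L, 11L, rep(10L, 8)))
  expect_identical(make_folds(sprintf("c%02d", 1:50), 5, seed = 2),
                   make_folds(sprintf("c%02d", 1:50), 5, seed = 2))
  # stratification: each fold receives a near-equal share of each class
  labs <- rep(c(1L, 0L), c(30, 70))
  fs <- make_folds(sprintf("d%03d", 1:100), 10, seed = 3, labels = labs)
  pos_per_fold <- vapply(1:10, function(f) sum(labs[fs == f]), integer(1))
  expect_true(all(pos_per_fold == 3L))
  expect_error(make_folds(c("x", "x", "y"), 2), "distinct")
  expect_error(make_folds(letters[1:3], 5), "fewer ids")
})

test_that("cross-validated AUC rises with class separation", {
  aucs <- vapply(c(0, 2, 4, 6), function(s) {
    fs <- generate_feature_clusters(feature_sim_spec(
      600, dim = 64, informative_dim = 16, separation = s,
      positive_fraction = 0.15, seed = 27))
    run_cv(fs, "raw", k = 15, n_folds = 5, seed = 27)$summary$mean_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.02))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[4], 0.9)
})

test_that("k = 1 voting produces only 0/1 likelihoods", {
  fs <- make_tiny_store(n = 80, d = 8, seed = 33, sep = 3)
  rep1 <- run_cv(fs, "raw", k = 1, n_folds = 4, seed = 33)
  # with {0,1} likelihoods the Youden threshold must sit inside (0, 1)
  expect_true(all(rep1$per_fold$threshold > 0 &
                    rep1$per_fold$threshold < 1))
  expect_equal(nrow(rep1$per_fold), 4)
})

test_that("a fold whose archive lacks a class is rejected", {
  x <- matrix(rnorm(24), 12, 2)
  st <- feature_store(x, sprintf("e%02d", 1:12),
                      c(1L, rep(0L, 11)))
  expect_error(run_cv(st, "raw", k = 3, n_folds = 3, seed = 1),
               "missing a class")
})

test_that("per-fold confusion matrices sum to the query count", {
  fs <- make_tiny_store(n = 90, d = 8, seed = 44, sep = 4)
  rep <- run_cv(fs, "raw", k = c(3, 9), n_folds = 3, seed = 44)
  for (kk in c("3", "9"))
    expect_equal(sum(rep$confusion[[kk]]), 90)
  expect_equal(nrow(rep$per_fold), 6)
  expect_true(all(rep$per_fold$auc >= 0 & rep$per_fold$auc <= 1))
})

test_that("signed-rank statistics match exhaustive enumeration", {
  # all-positive differences, n = 10: two-sided p = 2 / 2^10
  res <- wilcoxon_paired(2:11, (2:11) - 1)
  expect_equal(res$statistic, sum(1:10))
  expect_equal(res$p_value, 2 / 2^10)
  # toy differences with mixed signs vs. brute-force sign-flip oracle
  a <- c(1, -2, 3, -4, 5, 6)
  res6 <- wilcoxon_paired(a, rep(0, 6))
  or6 <- oracle_wilcoxon(a, rep(0, 6))
  expect_equal(res6$statistic, or6$statistic)
  expect_equal(res6$p_value, or6$p_value)
  # random small cases, including ties from a coarse grid
  set.seed(71)
  for (i in 1:25) {
    n <- sample(5:11, 1)
    x <- sample(seq(-3, 3, 0.5), n, replace = TRUE)
    y <- sample(seq(-3, 3, 0.5), n, replace = TRUE)
    if (all(x == y)) x[1] <- x[1] + 0.5
    got <- wilcoxon_paired(x, y)
    want <- oracle_wilcoxon(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("signed-rank test agrees with wilcox.test where comparable", {
  set.seed(81)
  # tie-free exact regime
  for (i in 1:10) {
    x <- rnorm(12)
    y <- rnorm(12)
    got <- wilcoxon_paired(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large-n normal approximation
  x <- rnorm(40)
  y <- rnorm(40, 0.3)
  got <- wilcoxon_paired(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_paired(1:6, 1:6), "zero")
  expect_error(wilcoxon_paired(1:3, 2:4), "at least 5")
})
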