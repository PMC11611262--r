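test_that("F-score follows the two-class formula", {
  withr::with_seed(1, {
    X <- matrix(rnorm(50), 10, 5)
    y <- rep(c(0, 1), 5)
  })
  r <- fscore_importance(X, y)
  # direct formula evaluation
  for (j in 1:5) {
    xp <- X[y == 1, j]; xn <- X[y == 0, j]
    expect_equal(r$scores[j],
                 ((mean(xp) - mean(X[, j]))^2 + (mean(xn) - mean(X[, j]))^2) /
                   (var(xp) + var(xn)))
  }
  # constant feature scores 0; separating feature ranks first
  X2 <- cbind(rep(1, 10), c(rep(0, 5), rep(1, 5)), rep(2, 10))
  r2 <- fscore_importance(X2, c(rep(0, 5), rep(1, 5)))
  expect_identical(r2$scores[1], 0)
  expect_identical(r2$order[1], 2L)
  expect_error(fscore_importance(X, rep(1, 10)), "two classes")
})

test_that("tree importances are seeded and favor planted features", {
  g <- generate_feature_matrix(planted_matrix_spec(
    n_samples = 120, n_features = 30, n_informative = 3, effect_size = 1.5,
    seed = 2))
  for (fn in list(gbt_importance, rf_importance)) {
    ranks_of_planted <- sapply(1:5, function(s) {
      r <- fn(g$X, g$y, seed = s)
      mean(match(g$informative, r$order))
    })
    # informative features rank well above the random-average position (15.5)
    expect_lt(mean(ranks_of_planted), 10)
    expect_identical(fn(g$X, g$y, seed = 1)$scores,
                     fn(g$X, g$y, seed = 1)$scores)
  }
  expect_true(all(gbt_importance(matrix(1, 40, 4), rep(0:1, 20))$scores == 0))
})

test_that("MRMD combines relevance and distance as specified", {
  withr::with_seed(3, {
    X <- matrix(rnorm(60), 10, 6)
    X[, 4] <- X[, 3]              # duplicated pair
    y <- rep(c(0, 1), 5)
  })
  r <- mrmd_importance(X, y)
  # brute-force two-loop oracle
  Z <- scale(X)
  for (j in 1:6) {
    rel <- abs(cor(X[, j], y))
    dsum <- 0
    for (k in 1:6) if (k != j) dsum <- dsum + sqrt(sum((Z[, j] - Z[, k])^2))
    expect_equal(r$scores[j], rel + dsum / 5, tolerance = 1e-12)
  }
  # duplicated feature has a smaller distance term than a unique feature
  dist_term <- function(j) {
    mean(sapply(setdiff(1:6, j), function(k) sqrt(sum((Z[, j] - Z[, k])^2))))
  }
  expect_lt(dist_term(3), dist_term(1))
  # ranking invariant to column order
  perm <- c(5, 3, 1, 6, 2, 4)
  r2 <- mrmd_importance(X[, perm], y)
  expect_equal(r2$scores, r$scores[perm])
})

test_that("all four importance methods agree on a perfectly separating feature", {
  y <- rep(c(0, 1), each = 20)
  X <- cbind(rep(1, 40), y * 2 - 1, rep(0, 40), rep(3, 40))
  for (r in list(fscore_importance(X, y), gbt_importance(X, y, 1),
                 rf_importance(X, y, 1), mrmd_importance(X, y))) {
    expect_identical(r$order[1], 2L)
  }
})

test_that("prefilter_top keeps the n best columns in original order", {
  frags <- random_fragment(40, seed = 4)
  block <- encode_eaac(frags)
  y <- rep(0:1, 20)
  rk <- fscore_importance(block$values, y)
  top <- prefilter_top(block, rk, 250)
  expect_identical(ncol(top$values), 250L)
  # matches a brute-force sort on scores
  expected <- sort(order(-rk$scores, seq_along(rk$scores))[1:250])
  expect_identical(top$feature_names, block$feature_names[expected])
  # kept features preserve original relative order
  expect_identical(top$feature_names,
                   block$feature_names[block$feature_names %in% top$feature_names])
  # n = width is the identity; smaller blocks warn and keep all
  expect_identical(prefilter_top(block, rk, ncol(block$values)), block)
  small <- encode_aac(frags)
  expect_warning(kept <- prefilter_top(small, fscore_importance(small$values, y), 250),
                 "keeping all")
  expect_identical(kept, small)
  # idempotence: filtering an already-filtered block is the identity
  rk2 <- importance_ranking(rk$method, rk$scores[expected])
  expect_identical(prefilter_top(top, rk2, 250), top)
})

test_that("SFS walks the ranking and selects the AUC-maximizing prefix", {
  # feature 1 separates perfectly; the rest are noise
  g <- generate_feature_matrix(planted_matrix_spec(
    n_samples = 60, n_features = 6, n_informative = 0, effect_size = 0,
    seed = 5))
  X <- cbind(g$y * 4 + rnorm(60, sd = 0.1), g$X[, -1])
  rk <- fscore_importance(X, g$y)
  expect_identical(rk$order[1], 1L)
  res <- sfs(X, g$y, rk, cv_folds = 5, seed = 1)
  expect_identical(nrow(res$curve), 6L)
  expect_equal(res$curve$auc[1], 1)
  expect_identical(res$best_subset, 1L)
  expect_equal(res$best_auc, max(res$curve$auc))
  # failing evaluator aborts with the step index
  expect_error(sfs(X, g$y, rk, evaluator = function(Xs, y) stop("nope")),
               "step 1")
})

test_that("SFS recovers planted features ahead of noise", {
  g <- generate_feature_matrix(planted_matrix_spec(
    n_samples = 100, n_features = 50, n_informative = 5, effect_size = 1.5,
    seed = 6))
  rk <- gbt_importance(g$X, g$y, seed = 1)
  res <- sfs(g$X, g$y, rk, max_features = 15, cv_folds = 3, seed = 1)
  expect_lte(length(res$best_subset), 15L)
  expect_gte(sum(g$informative %in% res$best_subset), 3L)
  expect_gt(res$best_auc, 0.8)
})
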