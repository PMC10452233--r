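# LOOCV feature-selection classification: ranking correctness, leakage
# protection, determinism, chance-level behavior, grid summaries.

make_separable <- function(n = 20, F_ = 10, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("HC", "CS"), each = n / 2), levels = c("HC", "CS"))
  X <- matrix(rnorm(n * F_), n, F_)
  X[, 1] <- ifelse(y == "CS", 5, -5) + rnorm(n, sd = 0.1)
  list(X = X, y = y)
}

test_that("a label-aligned feature ranks first under every method", {
  d <- make_separable()
  for (m in c("Corr", "Fisher", "Relief", "LARS")) {
    rk <- fs_rank(d$X, d$y, m)
    expect_equal(rk[1], 1L)
    expect_setequal(rk, 1:10)
  }
})

test_that("Fisher ranking follows the population-variance score", {
  # class A {1,2}, class B {4,5}: score = 9 / 1 = 9; a weaker feature with
  # the same class means but inflated variance must rank below it
  X <- cbind(f_strong = c(1, 2, 4, 5),
             f_weak = c(-2, 5, 0.5, 8.5),
             f_null = c(1, 5, 2, 4))
  y <- factor(c("A", "A", "B", "B"))
  rk <- fs_rank(X, y, "Fisher")
  expect_equal(rk, c(1L, 2L, 3L))
})

test_that("zero-variance features rank last for every method", {
  d <- make_separable()
  X <- cbind(d$X, const = 7)
  for (m in c("Corr", "Fisher", "Relief", "LARS")) {
    rk <- fs_rank(X, d$y, m)
    expect_equal(rk[length(rk)], ncol(X))
  }
})

test_that("pure-noise features show no positional ranking bias", {
  set.seed(2)
  F_ <- 8
  first_pick <- matrix(0, 4, F_)
  rownames(first_pick) <- c("Corr", "Fisher", "Relief", "LARS")
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(16 * F_), 16, F_)
    y <- factor(rep(c("a", "b"), 8))
    for (m in rownames(first_pick)) {
      rk <- fs_rank(X, y, m)
      first_pick[m, rk[1]] <- first_pick[m, rk[1]] + 1
    }
  }
  # no feature position wins far more often than the uniform 1/F share
  expect_lt(max(first_pick) / n_rep, 3.5 / F_)
})

test_that("a perfectly separating feature gives LOOCV accuracy 1 at j = 1 everywhere", {
  d <- make_separable()
  for (fs in c("Corr", "Fisher", "Relief", "LARS")) {
    for (clf in c("LR", "Boost", "Tree", "RF")) {
      r <- run_loocv(d$X, d$y, fs, clf, feature_grid = 1, seed = 3)
      expect_equal(r$acc, 1, info = paste(fs, clf))
      expect_equal(r$K, 1L)
      expect_equal(r$sem, 0)
      expect_equal(r$optimal_features, 1L)
      expect_equal(unname(rowSums(r$confusion)),
                   unname(as.vector(table(d$y))))
    }
  }
})

test_that("rankings never depend on the held-out subject (no leakage)", {
  d <- make_separable(n = 12, F_ = 6, seed = 4)
  base <- run_loocv(d$X, d$y, "Corr", "LR", feature_grid = c(1, 3), seed = 5)
  X2 <- d$X
  X2[4, ] <- X2[4, ] * 1000 + 99          # corrupt one subject's features
  mut <- run_loocv(X2, d$y, "Corr", "LR", feature_grid = c(1, 3), seed = 5)
  expect_identical(base$fold_rankings[4, ], mut$fold_rankings[4, ])
})

test_that("fixed seeds make the whole CvResult reproducible", {
  set.seed(6)
  X <- matrix(rnorm(16 * 12), 16, 12)
  y <- factor(rep(c("HC", "SS"), each = 8))
  for (combo in list(c("Relief", "RF"), c("LARS", "Boost"))) {
    a <- run_loocv(X, y, combo[1], combo[2], feature_grid = c(1, 4), seed = 11)
    b <- run_loocv(X, y, combo[1], combo[2], feature_grid = c(1, 4), seed = 11)
    expect_identical(a$acc_matrix, b$acc_matrix)
    expect_identical(a$optimal_features, b$optimal_features)
    expect_identical(a$confusion, b$confusion)
  }
})

test_that("optimal K takes the smallest feature count among tied maxima", {
  d <- make_separable()
  r <- run_loocv(d$X, d$y, "Corr", "LR", feature_grid = c(1, 2, 5), seed = 7)
  expect_equal(r$ACC_CV[1], 1)
  expect_equal(r$K, 1L)                    # later columns also reach 1.0
})

test_that("SEM equals the binomial standard error of fold accuracies", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 1] <- ifelse(rep(c(TRUE, FALSE), each = 10), 1.5, -1.5) + rnorm(20)
  y <- factor(rep(c("HC", "CS"), each = 10))
  r <- run_loocv(X, y, "Corr", "Tree", feature_grid = c(1, 2), seed = 9)
  p <- r$acc
  expect_equal(r$sem, sqrt(p * (1 - p) / 20), tolerance = 1e-12)
})

test_that("label permutation keeps accuracy at chance level", {
  set.seed(10)
  X <- matrix(rnorm(16 * 20), 16, 20)
  y <- factor(rep(c("HC", "CS"), each = 8))
  accs <- replicate(30, {
    yp <- sample(y)
    run_loocv(X, yp, "Corr", "LR", feature_grid = c(1, 3, 6), seed = 12)$acc
  })
  qs <- quantile(accs, c(0.025, 0.975))
  expect_lte(qs[1], 0.5)
  expect_gte(qs[2], 0.5)
})

test_that("grid summary flags the best cell with a fixed tie-break", {
  d <- make_separable(n = 12, F_ = 5, seed = 13)
  res <- grid_classification(d$X, d$y, fs_methods = c("Corr", "Fisher"),
                             classifiers = c("LR", "Tree"),
                             feature_grid = 1, seed = 14)
  tab <- summarize_grid(res)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$best), 1)
  # all cells reach accuracy 1 here, so the first combination is flagged
  expect_true(tab$best[1])
  expect_equal(tab$acc[1], 1)
})
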