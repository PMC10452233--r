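# Group statistics: normality gating, Kruskal-Wallis with post hocs,
# edge-wise ANOVA with Bonferroni, lobe-level edge summaries.

test_that("normality gate is calibrated on normal and powered on skewed data", {
  set.seed(1)
  grp <- factor(rep(c("A", "B", "C"), each = 40))
  rej_norm <- mean(replicate(200, {
    v <- rnorm(120)
    min(normality_and_homogeneity(v, grp)$shapiro_min_p) < 0.05
  }))
  # three Shapiro tests per replicate: familywise rejection ~ 1 - 0.95^3
  expect_lt(abs(rej_norm - (1 - 0.95^3)), 0.08)

  rej_exp <- mean(replicate(100, {
    v <- rexp(120)
    min(normality_and_homogeneity(v, grp)$shapiro_min_p) < 0.05
  }))
  expect_gt(rej_exp, 0.8)

  const <- normality_and_homogeneity(rep(1, 120), grp)
  expect_false(const$parametric)
})

test_that("Levene p-values are roughly uniform under homogeneous groups", {
  set.seed(2)
  grp <- factor(rep(c("A", "B", "C"), each = 30))
  ps <- replicate(200, normality_and_homogeneity(rnorm(90), grp)$levene_p)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_gt(min(ps), 0)
})

test_that("Kruskal-Wallis H matches the rank formula and base R", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- factor(rep(c("A", "B", "C"), each = 3))
  r <- kruskal_wallis_with_posthoc(v, grp)
  expect_equal(r$H, 7.2, tolerance = 1e-12)
  expect_equal(r$H, unname(kruskal.test(v, grp)$statistic), tolerance = 1e-12)
  expect_equal(nrow(r$post_hoc), 3)
  expect_true(all(r$post_hoc$p_bonferroni >= r$post_hoc$p_raw))
  expect_true(all(r$post_hoc$p_bonferroni <= 1))

  r0 <- kruskal_wallis_with_posthoc(rep(2, 9), grp)
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)
})

test_that("Kruskal-Wallis detects a one-SD location shift at n = 40", {
  set.seed(3)
  grp <- factor(rep(c("A", "B", "C"), each = 40))
  rej <- mean(replicate(50, {
    v <- rnorm(120)
    v[grp == "B"] <- v[grp == "B"] + 1
    kruskal_wallis_with_posthoc(v, grp)$p < 0.05
  }))
  expect_gt(rej, 0.9)
})

test_that("edge-wise ANOVA agrees with aov per column", {
  set.seed(4)
  grp <- factor(rep(c("A", "B", "C"), each = 10))
  X <- matrix(rnorm(30 * 5), 30, 5)
  X[grp == "C", 2] <- X[grp == "C", 2] + 2
  res <- anova_edgewise(X, grp)
  for (j in 1:5) {
    a <- summary(aov(X[, j] ~ grp))[[1]]
    expect_equal(res$F[j], a$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_raw[j], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_true(all(res$p_corrected >= res$p_raw - 1e-15))
  expect_true(all(res$p_corrected <= 1))
})

test_that("edge-wise ANOVA handles degenerate and null edges", {
  grp <- factor(rep(c("A", "B"), each = 5))
  X <- cbind(rep(c(0, 1), each = 5),      # zero within-group variance
             rep(1, 10))                  # fully constant
  res <- anova_edgewise(X, grp)
  expect_true(res$degenerate[1])
  expect_true(res$significant[1])
  expect_equal(res$p_raw[2], 1)
  expect_false(res$significant[2])

  set.seed(5)
  grp3 <- factor(rep(c("A", "B", "C"), each = 20))
  pr <- anova_edgewise(matrix(rnorm(60 * 400), 60), grp3)$p_raw
  expect_lt(abs(mean(pr) - 0.5), 0.05)    # null p-values uniform on average
})

test_that("significance masks are invariant to column order", {
  set.seed(6)
  grp <- factor(rep(c("A", "B", "C"), each = 15))
  X <- matrix(rnorm(45 * 20), 45, 20)
  X[grp == "A", 7] <- X[grp == "A", 7] + 3
  perm <- sample(20)
  m1 <- anova_edgewise(X, grp)$significant
  m2 <- anova_edgewise(X[, perm], grp)$significant
  expect_identical(m1[perm], m2)
})

test_that("DK table maps 68 parcels onto the seven reporting regions", {
  tab <- dk_roi_table()
  expect_equal(nrow(tab), 68)
  expect_setequal(unique(tab$region),
                  c("frontal", "temporal", "parietal", "occipital",
                    "PCC", "ACC", "insula"))
  expect_equal(sum(tab$hemisphere == "lh"), 34)
  expect_equal(unname(table(tab$region)["insula"]), 2)
})

test_that("lobe-level summary counts significant edges conservatively", {
  n_edges <- 68 * 67 / 2
  empty <- roi_group_summary(rep(FALSE, n_edges))
  expect_true(all(empty == 0))

  tab <- dk_roi_table()
  idx <- upper_tri_index(68)
  frontal <- which(tab$region == "frontal")
  e <- which(idx[, 1] %in% frontal & idx[, 2] %in% frontal)[1]
  mask <- rep(FALSE, n_edges)
  mask[e] <- TRUE
  M <- roi_group_summary(mask)
  expect_equal(M["frontal", "frontal"], 1L)
  expect_equal(sum(M) - M["frontal", "frontal"], 0L)

  set.seed(7)
  mask2 <- runif(n_edges) < 0.02
  M2 <- roi_group_summary(mask2)
  expect_identical(M2, t(M2))
  expect_equal(sum(M2[upper.tri(M2)]) + sum(diag(M2)), sum(mask2))
  expect_error(roi_group_summary(rep(FALSE, 100)), "ROI count")
})
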