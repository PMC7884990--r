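test_that("exact rank-sum p matches enumeration for all small splits", {
  # worked examples
  expect_equal(ranksum_exact(c(1, 2), c(3, 4), "less")$p, 1 / 6)
  expect_equal(ranksum_exact(1, 2, "less")$p, 1 / 2)
  # identical samples: one-tailed p >= 0.5 either way (symmetry)
  expect_gte(ranksum_exact(c(1, 2, 3), c(1, 2, 3), "greater")$p, 0.5)
  expect_gte(ranksum_exact(c(1, 2, 3), c(1, 2, 3), "less")$p, 0.5)
  # exhaustive: random tied data, every split size, all alternatives
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:8, 1); nx <- sample(1:(n - 1), 1)
    v <- sample(1:4, n, replace = TRUE)
    x <- v[seq_len(nx)]; y <- v[(nx + 1):n]
    for (alt in c("less", "greater", "two.sided"))
      expect_equal(ranksum_exact(x, y, alt)$p, brute_ranksum_p(x, y, alt))
  }
  expect_error(ranksum_exact(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum agrees with the classical exact distribution", {
  set.seed(7)
  x <- rnorm(6); y <- rnorm(7)  # untied: wilcox.test is exact here
  expect_equal(ranksum_exact(x, y, "greater")$p,
               wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value)
  expect_equal(ranksum_exact(x, y, "two.sided")$p,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # beyond the cap the method descriptor flags the approximation
  big <- ranksum_exact(rnorm(20), rnorm(20), "greater")
  expect_match(big$method, "approximation")
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohen_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohen_d(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_equal(cohen_d(c(1, 3, 5), c(1, 3, 5)), 0)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(cohen_d(x + 7, y + 7), cohen_d(x, y))   # shift invariance
  expect_error(cohen_d(c(1, 1), c(1, 1)), "pooled SD")
  expect_error(cohen_d(1, c(1, 2)), "at least 2")
})

test_that("BCa intervals are seeded, degenerate-safe, and match boot", {
  x <- c(rnorm(25, 1), 4, 5)
  a <- bootstrap_ci_bca(x, median, n_resamples = 500, seed = 3)
  b <- bootstrap_ci_bca(x, median, n_resamples = 500, seed = 3)
  expect_identical(a, b)
  expect_lt(a[1], a[2])
  expect_warning(ci <- bootstrap_ci_bca(rep(2, 10), median, 200, seed = 1),
                 "degenerate")
  expect_equal(ci, c(2, 2))
  # independent implementation check on a smooth statistic
  set.seed(11)
  y <- rexp(40)
  mine <- bootstrap_ci_bca(y, mean, n_resamples = 4000, seed = 5)
  bt <- boot::boot(y, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(max(abs(mine - ref)), 0.06)
})

test_that("BH step-up matches the hand-worked examples and p.adjust", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.04), q = 0.05)
  expect_identical(sum(r1$reject), 3L)       # 0.04 <= 0.05 * 3/3
  r2 <- bh_fdr(c(0.03, 0.5, 0.9), q = 0.05)
  expect_identical(sum(r2$reject), 0L)       # 0.03 > 0.05 / 3
  empty <- bh_fdr(numeric(0))
  expect_length(empty$reject, 0)
  set.seed(4)
  p <- runif(50)^1.5
  expect_equal(bh_fdr(p)$adjusted, p.adjust(p, "BH"))
  # BH rejects at least as much as Bonferroni at the same level
  bonf <- p <= 0.05 / length(p)
  expect_true(all(bonf <= bh_fdr(p, 0.05)$reject))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman rho handles monotone and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$statistic, -1)
  set.seed(9)
  x <- sample(1:5, 30, replace = TRUE); y <- x + sample(0:2, 30, replace = TRUE)
  expect_equal(spearman_rho(x, y)$statistic, cor(x, y, method = "spearman"))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("the robust slope tracks bisquare M-estimation under outliers", {
  set.seed(12)
  x <- rnorm(50); y <- 1.5 * x + rnorm(50, sd = 0.4)
  y[1:3] <- 25                                  # gross outliers
  ours <- sparenet:::robust_slope(x, y)
  rlm_fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  expect_lt(abs(ours - unname(rlm_fit$coefficients[2])), 0.02)
  expect_lt(abs(ours - 1.5), 0.2)               # outliers down-weighted
  expect_gt(abs(unname(lm(y ~ x)$coefficients[2]) - 1.5), 0.5)
})

test_that("permutation slope test is seeded with the +1 convention", {
  set.seed(1)
  x <- rnorm(20); y <- 2 * x
  res <- permutation_slope_test(x, y, n_perm = 999, seed = 2)
  expect_equal(res$p, 1 / 1000)                 # minimum attainable p
  res2 <- permutation_slope_test(x, y, n_perm = 999, seed = 2)
  expect_identical(res$p, res2$p)
  set.seed(13)
  null_res <- permutation_slope_test(rnorm(15), rnorm(15), n_perm = 99,
                                     seed = 4)
  expect_gte(null_res$p, 1 / 100)
  expect_lte(null_res$p, 1)
})

test_that("paired t matches hand arithmetic and the textbook form", {
  res <- paired_t(c(2, 3, 4), c(1, 1, 1))      # differences 1, 2, 3
  expect_equal(res$statistic, 2 * sqrt(3))
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero variance")
  set.seed(15)
  a <- rnorm(12); b <- a + rnorm(12)
  tt <- t.test(a, b, paired = TRUE)
  mine <- paired_t(a, b)
  expect_equal(mine$statistic, unname(tt$statistic))
  expect_equal(mine$p, tt$p.value)
  expect_equal(mine$ci, as.numeric(tt$conf.int))
})
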