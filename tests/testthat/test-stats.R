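# Statistical battery: worked examples frozen by hand, cross-checks against
# base-R routines, brute-force ANOVA oracle, and calibration properties.

test_that("one_sample_t matches the hand-computed example and stats::t.test", {
  x <- c(1.1, 1.0, 1.05, 0.95, 1.2)
  res <- one_sample_t(x, mu0 = 1)
  expect_equal(res$statistic, 1.3950, tolerance = 1e-4)
  expect_equal(res$df, 4)
  ref <- t.test(x, mu = 1)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  # symmetric values around mu0 give t = 0
  expect_equal(one_sample_t(c(0.9, 1.1, 0.8, 1.2), 1)$statistic, 0)
  # antisymmetry under reflection about mu0
  y <- c(1.02, 0.97, 1.11, 1.05)
  expect_equal(one_sample_t(2 - y, 1)$statistic,
               -one_sample_t(y, 1)$statistic)
  expect_error(one_sample_t(rep(1, 5), 1), "zero variance")
  expect_error(one_sample_t(1.2, 1), "length")
})

test_that("paired_t matches the hand-computed example", {
  d <- c(0.1, -0.1, 0.2, 0.0)
  res <- paired_t(d, rep(0, 4))
  expect_equal(res$statistic, 0.7746, tolerance = 1e-4)
  expect_equal(res$df, 3)
  ref <- t.test(d + 5, rep(5, 4) + 0:3 / 10, paired = TRUE)
  res2 <- paired_t(d + 5, rep(5, 4) + 0:3 / 10)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_error(paired_t(d, d), "zero variance")
  expect_error(paired_t(d, d[1:3]), "equal length")
})

test_that("paired_t p-values are uniform under the null", {
  ps <- withr::with_seed(99, replicate(1000, {
    paired_t(rnorm(12), rnorm(12))$p_value
  }))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("pearson_r matches hand computation and cor.test", {
  expect_equal(pearson_r(1:5, 1:5 * 2)$statistic, 1)
  expect_equal(pearson_r(1:5, -(1:5))$statistic, -1)
  res <- pearson_r(c(1, 2, 3), c(2, 4, 7))
  expect_equal(res$statistic, 0.9934, tolerance = 1e-4)
  expect_equal(res$df, 1)
  x <- c(0.3, 1.2, 0.8, 2.2, 1.7, 0.1)
  y <- c(1.1, 0.4, 0.9, 2.0, 1.2, 0.3)
  ref <- cor.test(x, y)
  res2 <- pearson_r(x, y)
  expect_equal(res2$statistic, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_r(rep(1, 4), 1:4), "zero variance")
})

test_that("rm_anova_gg reproduces the one-way toy table", {
  y <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 5, 4))
  res <- rm_anova_gg(y)
  expect_equal(res$F, 7.0, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 4)
  # hand-computed sums of squares behind that F
  expect_equal(res$F, (14 / 3 / 2) / (4 / 3 / 4), tolerance = 1e-12)
  # epsilon against the independent eigenvalue oracle
  expect_equal(res$epsilon, eps_eigen_oneway(y), tolerance = 1e-10)
  # rank-deficient (3-subject) covariance sits at the lower bound 1/(k-1)
  expect_equal(res$epsilon, 0.5, tolerance = 1e-10)
})

test_that("two-level within factors have epsilon exactly 1", {
  y <- withr::with_seed(5, matrix(rnorm(20), 10, 2))
  expect_equal(rm_anova_gg(y)$epsilon, 1)
  y3 <- withr::with_seed(6, array(rnorm(10 * 2 * 3), c(10, 2, 3)))
  res <- rm_anova_gg(y3)
  expect_equal(res$epsilon[res$effect == "A"], 1)
})

test_that("rm_anova_gg agrees with the brute-force oracle on random tables", {
  withr::with_seed(123, {
    for (rep in 1:5) {
      y <- array(rnorm(5 * 3 * 3, mean = rep(1:3, each = 5)), c(5, 3, 3))
      res <- rm_anova_gg(y)
      bf <- bf_rm_anova(y)
      expect_equal(res$F, unname(bf), tolerance = 1e-8)
      expect_true(all(res$p_gg >= 0 & res$p_gg <= 1))
      # epsilon bounds: 1/(k-1) for the 3-level mains, 1/4 for interaction
      expect_true(res$epsilon[1] >= 0.5 - 1e-12 && res$epsilon[1] <= 1 + 1e-12)
      expect_true(res$epsilon[3] >= 0.25 - 1e-12 && res$epsilon[3] <= 1 + 1e-12)
    }
  })
})

test_that("epsilon bounds hold over random one-way layouts", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      k <- sample(3:6, 1)
      y <- matrix(rnorm(8 * k), 8, k) %*%
        matrix(rnorm(k * k, sd = 0.5), k, k)
      eps <- rm_anova_gg(y)$epsilon
      expect_gte(eps, 1 / (k - 1) - 1e-10)
      expect_lte(eps, 1 + 1e-10)
    }
  })
})

test_that("compound-symmetric data give epsilon near 1", {
  y <- withr::with_seed(7, {
    subj <- rnorm(200, sd = 1)             # exchangeable covariance
    sweep(matrix(rnorm(200 * 3), 200, 3), 1, subj, "+")
  })
  expect_gt(rm_anova_gg(y)$epsilon, 0.95)
})

test_that("rm_anova_gg rejects bad layouts", {
  expect_error(rm_anova_gg(matrix(1:4, 2, 2)), "3 subjects")
  y <- matrix(rnorm(12), 4, 3); y[2, 2] <- NA
  expect_error(rm_anova_gg(y), "missing")
})

test_that("gaussian_kde implements the fixed-bandwidth kernel formula", {
  # single point: peak = 1 / (sigma sqrt(2 pi)), on a grid containing it
  k <- gaussian_kde(0.5, bandwidth = 0.04,
                    grid = seq(0.3, 0.7, length.out = 401))
  expect_equal(max(k$density), 1 / (0.04 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(k$grid[which.max(k$density)], 0.5)
  # normalisation by trapezoid over the default (+/- 8 sigma) grid
  x <- withr::with_seed(8, rnorm(40, 1, 0.1))
  k <- gaussian_kde(x, bandwidth = 0.04)
  integral <- sum(diff(k$grid) * (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # two far-apart points: two symmetric equal-height modes at the data
  g <- seq(-0.5, 10.5, by = 0.01)
  k2 <- gaussian_kde(c(0, 10), bandwidth = 0.04, grid = g)
  left <- k2$density[g <= 5]
  right <- k2$density[g > 5]
  expect_equal(g[g <= 5][which.max(left)], 0)
  expect_equal(g[g > 5][which.max(right)], 10)
  expect_equal(max(left), max(right))
  expect_equal(max(left), 0.5 / (0.04 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(k2$density, rev(k2$density), tolerance = 1e-10)
  expect_error(gaussian_kde(x, bandwidth = 0), "bandwidth")
})

test_that("gaussian_kde is shift/scale equivariant", {
  x <- withr::with_seed(9, rnorm(25, 1, 0.05))
  g <- seq(0.8, 1.2, length.out = 101)
  a <- 3.5; b <- -2
  k1 <- gaussian_kde(x, 0.04, grid = g)
  k2 <- gaussian_kde(a * x + b, a * 0.04, grid = a * g + b)
  expect_equal(k2$density, k1$density / a, tolerance = 1e-12)
})
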