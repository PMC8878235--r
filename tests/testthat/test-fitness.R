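test_that("fuzzy entropy: degenerate, uniform, and hand-summed cases", {
  expect_equal(fuzzy_entropy(c(1, 0, 0, 0)), 0)
  for (m in c(2, 5, 16)) {
    expect_equal(fuzzy_entropy(rep(1 / m, m)), log(m), tolerance = 1e-12)
  }
  expect_equal(fuzzy_entropy(c(0.5, 0.25, 0.25)),
               0.5 * log(2) + 2 * 0.25 * log(4), tolerance = 1e-12)
  expect_error(fuzzy_entropy(c(-0.1, 1.1)))
  expect_warning(h <- fuzzy_entropy(c(2, 2)), "renormalizing")
  expect_equal(h, log(2))
})

test_that("skewness: symmetry, antisymmetry, arithmetic oracle", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  y <- c(0, 0, 0, 1)
  # term-by-term from the stated formula
  s <- stats::sd(y)
  expect_equal(sample_skewness(y), mean((y - mean(y))^3) / s^3)
  set.seed(1)
  z <- rnorm(50)
  expect_equal(sample_skewness(-z), -sample_skewness(z))
  d <- sample_skewness(rep(2, 5))
  expect_equal(as.numeric(d), 0)
  expect_true(is_degenerate(d))
})

test_that("kurtosis: hand value, scale invariance, normal limit", {
  y <- c(-1, 1, -1, 1)
  # deviations all 1: m4 = 1, s^2 = 4/3, so kurtosis = 9/16
  expect_equal(sample_kurtosis(y), 9 / 16)
  set.seed(2)
  z <- rnorm(100)
  expect_equal(sample_kurtosis(3.7 * z), sample_kurtosis(z),
               tolerance = 1e-12)
  expect_equal(sample_kurtosis(z + 10), sample_kurtosis(z),
               tolerance = 1e-9)
  set.seed(3)
  big <- rnorm(1e5)
  expect_lt(abs(sample_kurtosis(big) - 3), 0.1)
})

test_that("variance closed forms and shift invariance", {
  expect_equal(sample_variance(c(5, 5, 5)), 0)
  expect_equal(sample_variance(c(0, 2)), 2)
  set.seed(4)
  z <- rnorm(30)
  expect_equal(sample_variance(z + 7), sample_variance(z), tolerance = 1e-12)
  expect_error(sample_variance(1))
})

test_that("joint correlation: diagonal, anti-diagonal, brute force", {
  d <- diag(4) / 4
  expect_equal(joint_correlation(d), 1, tolerance = 1e-12)
  anti <- d[, 4:1]
  expect_equal(joint_correlation(anti), -1, tolerance = 1e-12)
  set.seed(5)
  for (L in c(4, 9, 16)) {
    p <- random_glcm_matrix(L)
    expect_equal(joint_correlation(p), bf_joint_correlation(p),
                 tolerance = 1e-12)
  }
  deg <- matrix(0, 3, 3); deg[2, 2] <- 1
  expect_true(is_degenerate(joint_correlation(deg)))
})

test_that("aggregate fitness honours weights and prefers the truth", {
  fv <- fitness_vector(1.3, 2.9, -0.2, 0.4, 0.8)
  expect_equal(aggregate_fitness(fv, c(1, 0, 0, 0, 0)), 1.3)
  expect_equal(aggregate_fitness(fv, c(0, 0, 0, 0, 2)), 1.6)
  expect_error(aggregate_fitness(fv, rep(0, 5)))
  expect_error(aggregate_fitness(fv, c(-1, 0, 0, 0, 1)))

  bl <- generate_labelled_points(3, 25, separation = 10, seed = 8)
  truth_blocks <- lapply(1:3, function(b) which(bl$labels == b))
  f_truth <- partition_fitness(bl$points, truth_blocks)
  set.seed(9)
  rand_blocks <- split(seq_len(75), sample(rep(1:3, 25)))
  f_rand <- partition_fitness(bl$points, lapply(rand_blocks, as.integer))
  expect_lt(f_truth, f_rand)
})

test_that("normality test matches an independent reference implementation", {
  # expected values frozen from scipy.stats.normaltest (D'Agostino-Pearson)
  x1 <- c(0.12, 0.47, -1.3, 2.1, 0.05, -0.77, 1.62, -0.33, 0.9, -1.05,
          0.28, -0.6, 1.1, -2.4, 0.73, 0.31, -0.15, 0.55, -0.9, 1.8)
  r1 <- test_normality(x1)
  expect_equal(r1$statistic, 0.35059945796152825, tolerance = 1e-10)
  expect_equal(r1$p_value, 0.8392054488755539, tolerance = 1e-10)
  expect_true(r1$is_normal)

  x2 <- c(0.5, 1.2, 2.9, 0.3, 0.8, 4.5, 0.1, 1.7, 0.9, 2.2,
          6.8, 0.4, 1.1, 3.3, 0.2, 1.9, 0.6, 2.7, 0.7, 5.1)
  r2 <- test_normality(x2)
  expect_equal(r2$statistic, 8.22195158812363, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.016391771726330665, tolerance = 1e-10)
  expect_false(r2$is_normal)

  expect_error(test_normality(rnorm(7)), "at least 8")
})

test_that("normality test is calibrated under the null and powerful", {
  null_pass <- 0
  alt_reject <- 0
  for (i in 1:100) {
    set.seed(1000 + i)
    if (test_normality(rnorm(500))$is_normal) null_pass <- null_pass + 1
    if (!test_normality(rexp(500))$is_normal) alt_reject <- alt_reject + 1
  }
  expect_gte(null_pass, 90)
  expect_gte(alt_reject, 95)
})

test_that("p-values stay in [0, 1] across sample shapes", {
  set.seed(6)
  for (i in 1:50) {
    x <- switch(1 + i %% 3, rnorm(40), rexp(40), runif(40))
    p <- test_normality(x)$p_value
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("merge rule: identical, shifted-normal, and skewed clusters", {
  set.seed(7)
  a <- rnorm(300)
  d1 <- should_merge(a, a)
  expect_true(d1$merge)
  expect_equal(d1$reason, "equal_stats")

  set.seed(70)
  b <- rnorm(300, mean = 4)  # same shape, different location
  d2 <- should_merge(a, b)
  expect_true(d2$merge)
  expect_true(d2$reason %in% c("equal_stats", "both_normal"))

  set.seed(71)
  ln <- rlnorm(300)
  d3 <- should_merge(a, ln)
  expect_false(d3$merge)
  expect_equal(d3$reason, "rejected")
})

test_that("merge rule is symmetric and rejects undersized clusters", {
  set.seed(8)
  a <- rnorm(100); b <- rlnorm(100)
  d_ab <- should_merge(a, b); d_ba <- should_merge(b, a)
  expect_equal(d_ab$merge, d_ba$merge)
  expect_equal(d_ab$reason, d_ba$reason)
  expect_equal(sort(d_ab$p_values), sort(d_ba$p_values))

  tiny <- should_merge(rnorm(5), rnorm(100))
  expect_false(tiny$merge)
  expect_equal(tiny$detail, "undersized")
})
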