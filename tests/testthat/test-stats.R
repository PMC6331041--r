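test_that("permutation test handles degenerate equal samples", {
  res <- permutationTestMedianDiff(rep(5, 4), rep(5, 4), n_perm = 200, seed = 1)
  expect_equal(res$observed_stat, 0)
  expect_equal(res$p_value, 1)
})

test_that("exact mode equals exhaustive label enumeration", {
  a <- c(1, 2)
  b <- c(10, 11)
  res <- permutationTestMedianDiff(a, b, exact = TRUE)
  expect_equal(res$observed_stat, 9)
  expect_equal(res$n_permutations, 6L)
  # independent oracle: every binary labeling with two 'a' labels
  pooled <- c(a, b)
  labelings <- expand.grid(rep(list(c(TRUE, FALSE)), 4))
  labelings <- labelings[rowSums(labelings) == 2, ]
  stats <- apply(labelings, 1, function(lab) {
    abs(median(pooled[as.logical(lab)]) - median(pooled[!as.logical(lab)]))
  })
  expect_equal(res$p_value, mean(stats >= 9))
  expect_equal(res$p_value, 1 / 3)
})

test_that("exact mode matches the enumeration oracle on random small samples", {
  set.seed(51)
  for (rep in 1:10) {
    na <- sample(2:4, 1)
    nb <- sample(2:4, 1)
    a <- round(rnorm(na), 1)  # rounding induces occasional ties
    b <- round(rnorm(nb, 1), 1)
    res <- permutationTestMedianDiff(a, b, exact = TRUE)
    pooled <- c(a, b)
    n <- na + nb
    labelings <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    labelings <- labelings[rowSums(labelings) == na, ]
    stats <- apply(labelings, 1, function(lab) {
      abs(median(pooled[as.logical(lab)]) - median(pooled[!as.logical(lab)]))
    })
    expect_equal(res$p_value, mean(stats >= res$observed_stat))
  }
})

test_that("random permutation p-values are reproducible and bounded below", {
  a <- rnorm(30)
  b <- rnorm(30, 2)
  r1 <- permutationTestMedianDiff(a, b, n_perm = 500, seed = 99)
  r2 <- permutationTestMedianDiff(a, b, n_perm = 500, seed = 99)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 501)
  expect_error(permutationTestMedianDiff(a, b, n_perm = 0), "n_perm")
  expect_error(permutationTestMedianDiff(numeric(0), b), "non-empty")
})

test_that("correlation tests match hand values and the closed-form oracle", {
  x <- 1:10
  res <- correlationTest(x, 2 * x + 3)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)

  res <- correlationTest(x, -x, method = "pearson")
  expect_equal(res$r, -1)
  expect_equal(correlationTest(x, -x, method = "spearman")$r, -1)

  # ranks equal the values here; hand rank computation: sum(d^2) = 4,
  # rho = 1 - 6 * 4 / (5 * 24) = 0.8
  res <- correlationTest(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                         method = "spearman")
  expect_equal(res$r, 0.8)

  set.seed(52)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  res <- correlationTest(x, y)
  # textbook closed form
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  # cor.test as an independent implementation
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(res$n, 40)

  expect_error(correlationTest(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(correlationTest(c(1, NA), c(2, 3)), "complete cases")
})

test_that("spearman uses mid-ranks under ties", {
  x <- c(1, 1, 2, 3)
  y <- c(2, 1, 3, 4)
  res <- correlationTest(x, y, method = "spearman")
  expect_equal(res$r, cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("Poisson regression recovers saturated-mean and planted slopes", {
  y <- rep(3L, 20)
  x <- rnorm(20)
  fit <- fitPoissonRegression(y, x)
  expect_equal(fit$beta1, 0, tolerance = 1e-6)
  expect_equal(fit$beta0, log(3), tolerance = 1e-6)
  expect_true(fit$converged)

  expect_error(fitPoissonRegression(c(1.5, 2, 3), 1:3), "non-negative integers")
  expect_error(fitPoissonRegression(c(-1L, 2L, 3L), 1:3), "non-negative")

  set.seed(53)
  x <- rexp(3000)
  y <- rpois(3000, exp(0.5 - 1.0 * x))
  fit <- fitPoissonRegression(y, x)
  expect_lt(abs(fit$beta1 + 1.0), 0.15)
  expect_lt(fit$wald_p, 1e-10)
})

test_that("the Poisson fit satisfies the score equations", {
  set.seed(54)
  x <- rnorm(500)
  y <- rpois(500, exp(0.3 + 0.4 * x))
  fit <- fitPoissonRegression(y, x)
  mu <- exp(fit$beta0 + fit$beta1 * x)
  expect_lt(abs(sum(y - mu)), 1e-6)
  expect_lt(abs(sum(x * (y - mu))), 1e-6)
})

test_that("tissue enrichment reduces to the null on proportional input", {
  genome <- rep(c("anther", "leaf", "pistil"), c(20, 60, 20))
  top <- rep(c("anther", "leaf", "pistil"), c(2, 6, 2))
  enr <- tissueEnrichment(top, genome)
  expect_equal(enr$statistic, 0)
  expect_true(all(enr$table$chi_component == 0))
  expect_true(all(enr$table$binom_p_raw == 1))
  expect_equal(sum(enr$table$observed), length(top))
  expect_equal(sum(enr$table$expected), length(top))
})

test_that("chi components and binomial p-values match hand computation", {
  # n_top = 20 at genome frequency 0.2 -> E = 4; O = 10 -> (10-4)/2 = 3
  genome <- rep(c("anther", "other"), c(200, 800))
  top <- rep(c("anther", "other"), c(10, 10))
  enr <- tissueEnrichment(top, genome)
  row <- enr$table[enr$table$tissue == "anther", ]
  expect_equal(row$expected, 4)
  expect_equal(row$chi_component, 3.0)
  expect_equal(row$binom_p_adj, min(1, 2 * row$binom_p_raw))

  # exact two-sided binomial by direct minimum-likelihood summation
  genome <- rep(c("anther", "other"), c(100, 900))
  top <- rep(c("anther", "other"), c(8, 12))
  enr <- tissueEnrichment(top, genome)
  probs <- dbinom(0:20, 20, 0.1)
  p_oracle <- sum(probs[probs <= dbinom(8, 20, 0.1) * (1 + 1e-7)])
  expect_equal(enr$table$binom_p_raw[enr$table$tissue == "anther"], p_oracle,
               tolerance = 1e-12)

  expect_error(tissueEnrichment(c("anther", "root"), genome),
               "absent from the vocabulary")
})

test_that("the Bonferroni factor is the number of tissue classes", {
  tiss <- paste0("t", 1:9)
  genome <- rep(tiss, each = 50)
  top <- rep("t1", 10)
  enr <- tissueEnrichment(top, genome, tissues = tiss)
  expect_equal(enr$df, 8)
  expect_equal(enr$table$binom_p_adj, pmin(1, 9 * enr$table$binom_p_raw))
})
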