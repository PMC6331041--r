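## median without dispatch/NA handling, for the hot permutation loop;
## agrees with stats::median on numeric input
.fastMedian <- function(x) {
  n <- length(x)
  h <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort(x, partial = h)[h]
  } else {
    s <- sort(x, partial = c(h, h + 1L))
    (s[h] + s[h + 1L]) / 2
  }
}

#' Two-sample permutation test on the difference between medians
#'
#' Pools the two samples, reshuffles group labels and recomputes the absolute
#' difference between group medians. The p-value uses the add-one estimator
#' p = (1 + b) / (1 + B), where b counts permuted statistics at least as
#' large as the observed one, so p is never zero and never below
#' 1 / (n_perm + 1). With `exact = TRUE` every distinct label assignment is
#' enumerated instead and p is the exact tail fraction (including the
#' identity assignment).
#'
#' @param a,b numeric samples, both non-empty.
#' @param n_perm number of random permutations; default 1000.
#' @param seed integer seed making the random test reproducible.
#' @param exact enumerate all choose(n, length(a)) assignments (only feasible
#'   for small samples; capped at 500000 assignments).
#' @return list with `observed_stat`, `p_value`, `n_permutations`, `seed`,
#'   `exact`.
#' @export
permutationTestMedianDiff <- function(a, b, n_perm = 1000, seed = NULL,
                                      exact = FALSE) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (!exact && n_perm < 1) stop("n_perm must be >= 1")
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  observed <- abs(median(a) - median(b))
  if (exact) {
    total <- choose(n, na)
    if (total > 5e5) stop("too many assignments for exhaustive enumeration")
    idx <- combn(n, na)
    stats <- apply(idx, 2L, function(i) {
      abs(median(pooled[i]) - median(pooled[-i]))
    })
    return(list(
      observed_stat = observed,
      p_value = mean(stats >= observed),
      n_permutations = as.integer(total),
      seed = seed,
      exact = TRUE
    ))
  }
  stats <- withSeed(seed, vapply(seq_len(n_perm), function(k) {
    i <- sample.int(n, na)
    abs(.fastMedian(pooled[i]) - .fastMedian(pooled[-i]))
  }, numeric(1L)))
  list(
    observed_stat = observed,
    p_value = (1 + sum(stats >= observed)) / (1 + n_perm),
    n_permutations = as.integer(n_perm),
    seed = seed,
    exact = FALSE
  )
}

#' Correlation test with t-based p-value
#'
#' Pearson's r, or Spearman's rho computed as Pearson's r on mid-ranks.
#' Significance uses the one-sample t statistic
#' t = r * sqrt((n - 2) / (1 - r^2)) against the t distribution with n - 2
#' degrees of freedom (two-sided). Rows with missing values in either vector
#' are dropped first (complete cases).
#'
#' @param x,y numeric vectors of equal length; at least 3 complete cases.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `method`, `r`, `t_stat`, `p_value`, `n`.
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  cc <- complete.cases(x, y)
  x <- x[cc]
  y <- y[cc]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete cases")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(method = method, r = r, t_stat = t_stat, p_value = p, n = n)
}

#' Poisson regression of counts on a predictor
#'
#' Fits counts ~ exp(beta0 + beta1 * x) by maximum likelihood (the
#' iteratively reweighted least squares of [stats::glm()] with a log link;
#' convergence tolerance 1e-8, at most 100 iterations). Reports Wald
#' significance for beta1 and a chi-squared goodness-of-fit test on the
#' residual deviance at n - 2 degrees of freedom.
#'
#' @param y non-negative integer counts.
#' @param x numeric predictor, same length, finite.
#' @return list with `beta0`, `beta1`, `se0`, `se1`, `wald_p`,
#'   `residual_deviance`, `gof_p`, `n_iterations`, `converged`, `n`.
#' @export
fitPoissonRegression <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (anyNA(y) || any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("predictor must be finite")
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  fit <- glm(y ~ x, family = poisson(),
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    warning("Poisson IRLS did not converge within 100 iterations")
  }
  cf <- summary(fit)$coefficients
  z1 <- cf["x", "z value"]
  list(
    beta0 = unname(cf["(Intercept)", "Estimate"]),
    beta1 = unname(cf["x", "Estimate"]),
    se0 = unname(cf["(Intercept)", "Std. Error"]),
    se1 = unname(cf["x", "Std. Error"]),
    wald_p = unname(2 * pnorm(-abs(z1))),
    residual_deviance = unname(fit$deviance),
    gof_p = unname(pchisq(fit$deviance, df = n - 2, lower.tail = FALSE)),
    n_iterations = fit$iter,
    converged = fit$converged,
    n = n
  )
}

#' Primary-tissue enrichment of a top-scoring gene set
#'
#' Compares the primary-tissue composition of a top-fraction gene set against
#' genome-wide expectations. An overall chi-squared goodness-of-fit statistic
#' (T - 1 degrees of freedom) is followed by a per-tissue battery: the
#' signed chi component (O - E) / sqrt(E) for a hanging chi-gram, and a
#' two-sided exact binomial test of O_i successes in n_top trials at the
#' genome frequency of the tissue, Bonferroni-adjusted for the T comparisons.
#'
#' @param top_tissues primary-tissue labels of the top-fraction genes.
#' @param genome_tissues primary-tissue labels of all genes.
#' @param tissues optional canonical tissue vocabulary (default: tissues seen
#'   in `genome_tissues`, in first-appearance order). A top-set tissue absent
#'   from the vocabulary is an error.
#' @return list with `statistic`, `df`, `p_value` (overall test) and `table`
#'   (data.frame: tissue, observed, expected, chi_component, binom_p_raw,
#'   binom_p_adj).
#' @examples
#' tissueEnrichment(rep(c("anther", "leaf"), c(10, 10)),
#'                  rep(c("anther", "leaf"), c(20, 80)))
#' @export
tissueEnrichment <- function(top_tissues, genome_tissues, tissues = NULL) {
  if (!length(top_tissues) || !length(genome_tissues)) {
    stop("label collections must be non-empty")
  }
  if (is.null(tissues)) tissues <- unique(genome_tissues)
  bad <- setdiff(unique(top_tissues), tissues)
  if (length(bad)) {
    stop(sprintf("tissue '%s' in the top set is absent from the vocabulary",
                 bad[1L]))
  }
  n_top <- length(top_tissues)
  obs <- as.integer(table(factor(top_tissues, levels = tissues)))
  gen <- as.integer(table(factor(genome_tissues, levels = tissues)))
  freq <- gen / sum(gen)
  expected <- n_top * freq
  nz <- expected > 0
  statistic <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  df <- length(tissues) - 1L
  chi_component <- ifelse(nz, (obs - expected) / sqrt(pmax(expected, 1e-300)), 0)
  binom_p <- vapply(seq_along(tissues), function(i) {
    binom.test(obs[i], n_top, p = freq[i])$p.value
  }, numeric(1L))
  list(
    statistic = statistic,
    df = df,
    p_value = pchisq(statistic, df = df, lower.tail = FALSE),
    table = data.frame(
      tissue = tissues,
      observed = obs,
      expected = expected,
      chi_component = chi_component,
      binom_p_raw = binom_p,
      binom_p_adj = pmin(1, length(tissues) * binom_p)
    )
  )
}
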