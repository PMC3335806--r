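# Self-contained statistical primitives shared by all pipeline stages.
# Each has an independent oracle in the test suite (combinatorial summation,
# permutation, or the corresponding base-R routine).

#' Upper-tail cumulative hypergeometric probability
#'
#' `P(X >= k)` where `X` counts successes when drawing `n` items without
#' replacement from a population of `N` containing `K` successes.  Computed
#' by log-gamma arithmetic and log-space summation, so it is accurate far
#' into the tail.
#'
#' @param k Observed success count (lower bound of the tail).
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @return A probability in `[0, 1]`.
#' @examples
#' hypergeom_tail(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N) {
    abort("inconsistent hypergeometric counts: need 0 <= K, n <= N")
  }
  if (k > min(K, n)) abort("`k` exceeds min(K, n): impossible count")
  if (k <= max(0, n + K - N)) return(1)
  i <- seq(k, min(K, n))
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(log_sum_exp(lp)))
}

hypergeom_pmf_log <- function(i, K, n, N) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

#' Fisher's exact test for a 2x2 table
#'
#' One-sided ("greater", enrichment of the top-left cell) p-values are the
#' cumulative hypergeometric tail on the table's margins; two-sided p-values
#' sum all tables with the same margins whose probability does not exceed the
#' observed table's (with a small relative tolerance, as is conventional).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A `cistromer_test` with the odds-ratio-free statistic (observed
#'   top-left count) and p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must be a 2x2 matrix of non-negative integers")
  }
  a <- tab[1, 1]
  K <- sum(tab[1, ]); n <- sum(tab[, 1]); N <- sum(tab)
  if (N == 0) {
    return(new_cistromer_test(a, 1, "Fisher exact test (2x2)", 0L, 0L))
  }
  if (alternative == "greater") {
    p <- hypergeom_tail(a, K, n, N)
  } else {
    lo <- max(0, n + K - N); hi <- min(K, n)
    support <- seq(lo, hi)
    lp <- hypergeom_pmf_log(support, K, n, N)
    obs <- lp[support == a]
    p <- min(1, exp(log_sum_exp(lp[lp <= obs + 1e-7])))
  }
  new_cistromer_test(a, p, sprintf("Fisher exact test (2x2, %s)", alternative),
                     as.integer(K), as.integer(N - K))
}

# Kolmogorov distribution survival function Q(lambda) = P(K > lambda),
# with the small-sample lambda correction of Stephens.
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- seq_len(100)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

ks_statistic_two_sample <- function(a, b) {
  all_v <- sort(unique(c(a, b)))
  ca <- stats::ecdf(a)(all_v)
  cb <- stats::ecdf(b)(all_v)
  max(abs(ca - cb))
}

# Exact P(D >= d) for the two-sample KS statistic without ties, by counting
# monotone lattice paths that stay strictly inside the band |i/m - j/n| < d.
ks_exact_p <- function(d, m, n) {
  u <- matrix(0, m + 1, n + 1)
  u[1, 1] <- 1
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 && j == 0) next
      if (abs(i / m - j / n) >= d - 1e-9) { u[i + 1, j + 1] <- 0; next }
      up <- if (i > 0) u[i, j + 1] else 0
      left <- if (j > 0) u[i + 1, j] else 0
      u[i + 1, j + 1] <- up + left
    }
  }
  1 - u[m + 1, n + 1] / choose(m + n, m)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum gap between the two empirical CDFs.  For tie-free
#' samples with `n_a * n_b <= 10000` the p-value is exact (lattice-path
#' counting); otherwise the asymptotic Kolmogorov distribution is used with
#' effective `n = n_a n_b / (n_a + n_b)` and the standard small-sample
#' lambda correction.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `cistromer_test` with fields `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 values per sample")
  m <- length(a); n <- length(b)
  D <- ks_statistic_two_sample(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && m * n <= 10000) {
    p <- ks_exact_p(D, m, n)
    method <- "Two-sample Kolmogorov-Smirnov test (exact)"
  } else {
    ne <- m * n / (m + n)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    p <- kolmogorov_sf(lambda)
    method <- "Two-sample Kolmogorov-Smirnov test (asymptotic)"
  }
  new_cistromer_test(D, p, method, m, n)
}

#' One-sample Kolmogorov-Smirnov test against a fitted normal
#'
#' Tests the sample against `Normal(mean(a), sd(a))`.  The asymptotic
#' Kolmogorov p-value is used without a Lilliefors correction for the
#' estimated parameters, which makes the test lenient towards normality;
#' treat borderline acceptances as qualitative.
#'
#' @param a Numeric vector, length >= 8, with positive standard deviation.
#' @return A `cistromer_test` with `statistic` (D) and `p.value`.
#' @export
ks_one_sample_normal <- function(a) {
  a <- a[!is.na(a)]
  n <- length(a)
  if (n < 8) abort("need >= 8 values for the one-sample KS test")
  s <- sd(a)
  if (s == 0) abort("zero standard deviation: distribution is degenerate")
  z <- sort((a - mean(a)) / s)
  cdf <- pnorm(z)
  i <- seq_len(n)
  D <- max(pmax(i / n - cdf, cdf - (i - 1) / n))
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  new_cistromer_test(D, kolmogorov_sf(lambda),
                     "One-sample Kolmogorov-Smirnov test vs fitted normal", n)
}

#' Kruskal-Wallis rank test
#'
#' H with the standard tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom.  When every value is identical H is 0 and p is 1.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values each).
#' @return A `cistromer_test` with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 values each")
  }
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  t_counts <- table(x)
  correction <- 1 - sum(t_counts^3 - t_counts) / (N^3 - N)
  if (correction <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / correction
    p <- pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  new_cistromer_test(H, p, "Kruskal-Wallis rank sum test", N,
                     as.integer(length(groups)))
}

#' Welch's unpaired two-sample t-test
#'
#' Two-sided p-value with Welch-Satterthwaite degrees of freedom.  If both
#' groups have zero variance: p = 1 when the means agree, 0 otherwise.
#'
#' @param a,b Numeric vectors of length >= 2 (>= 3 recommended).
#' @return A `cistromer_test` with `statistic` (t), `p.value` and `df`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 values per group")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_cistromer_test(if (eq) 0 else Inf, if (eq) 1 else 0,
                              "Welch two-sample t-test", na, nb, df = NA_real_))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df)
  new_cistromer_test(t_stat, p, "Welch two-sample t-test", na, nb, df = df)
}

#' Pearson R-squared and ordinary least squares
#'
#' Textbook closed forms.  `ols_fit()` regresses `y` on `x`; a constant `x`
#' yields `NA` slope/intercept as a degenerate-input sentinel.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return `pearson_r2()`: a single number in `[0, 1]`.  `ols_fit()`: a
#'   one-row tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  (sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

#' @rdname pearson_r2
#' @export
ols_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 paired values")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    return(tibble(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, n = length(x)))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ssr <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  tibble(slope = slope, intercept = intercept, r_squared = r2, n = length(x))
}
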