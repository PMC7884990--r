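stat_result <- function(statistic, p = NA_real_, method = "", ...) {
  structure(c(list(statistic = statistic, p = p, method = method), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Exact Wilcoxon rank-sum test
#'
#' One- or two-tailed rank-sum test. For combined sample sizes up to
#' `exact_cap` the p-value is exact: the full null distribution of the rank
#' sum of `x` is computed over all `choose(n, nx)` equally likely rank
#' assignments (ties handled with mid-ranks) by dynamic programming over
#' subset sums, which is equivalent to exhaustive enumeration. Beyond the
#' cap, a normal approximation with tie correction and continuity correction
#' is used and flagged in the method descriptor.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"greater"` means `x` tends larger than `y`;
#'   `"less"` the reverse; `"two.sided"` doubles the smaller tail.
#' @param exact_cap largest combined n for the exact method (default 25).
#' @return `stat_result` with `statistic` (rank sum of `x`), `p`, `method`.
#' @export
ranksum_exact <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          exact_cap = 25) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  if (n <= exact_cap) {
    r2 <- as.integer(round(2 * r))          # mid-ranks doubled -> integers
    w2 <- as.integer(round(2 * w_obs))
    S <- sum(r2)
    # f[k+1, s+1] = number of size-k subsets of processed ranks with sum s
    f <- matrix(0, nx + 1, S + 1)
    f[1, 1] <- 1
    for (rr in r2) {
      kmax <- min(nx, n)                    # rows to update, top-down
      for (k in kmax:1) {
        src <- f[k, 1:(S - rr + 1)]
        if (any(src > 0))
          f[k + 1, (rr + 1):(S + 1)] <- f[k + 1, (rr + 1):(S + 1)] + src
      }
    }
    dist <- f[nx + 1, ]
    total <- sum(dist)                      # = choose(n, nx)
    sums <- 0:S
    p_le <- sum(dist[sums <= w2]) / total
    p_ge <- sum(dist[sums >= w2]) / total
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    stat_result(w_obs, p, "exact rank-sum (full enumeration by subset-sum DP)")
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- 0.5
    p_ge <- stats::pnorm((w_obs - cc - mu) / sqrt(sig2), lower.tail = FALSE)
    p_le <- stats::pnorm((w_obs + cc - mu) / sqrt(sig2))
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    stat_result(w_obs, p, "rank-sum (normal approximation, tie-corrected)")
  }
}

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y))` divided by the pooled SD with `n1 + n2 - 2`
#' denominator.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return numeric effect size.
#' @export
cohen_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("zero pooled SD: effect size undefined", call. = FALSE)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Percentile bootstrap with bias correction (from the fraction of resample
#' statistics below the observed value, counting ties as half) and
#' acceleration (from the skewness of leave-one-out jackknife values).
#'
#' @param x numeric sample of size >= 2.
#' @param statistic function of a numeric vector returning a scalar.
#' @param n_resamples bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for reproducibility.
#' @return numeric `c(lower, upper)`. A degenerate resample distribution
#'   collapses to `[obs, obs]` with a warning.
#' @export
bootstrap_ci_bca <- function(x, statistic = stats::median,
                             n_resamples = 10000, level = 0.95, seed = NULL) {
  if (length(x) < 2) stop("sample must have at least 2 observations", call. = FALSE)
  obs <- statistic(x)
  thetas <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_resamples, replace = TRUE),
                  nrow = length(x))
    apply(idx, 2, function(i) statistic(x[i]))
  })
  if (max(thetas) - min(thetas) < .Machine$double.eps * max(1, abs(obs))) {
    warning("degenerate bootstrap distribution; returning [obs, obs]")
    return(c(obs, obs))
  }
  B <- length(thetas)
  prop <- (sum(thetas < obs) + 0.5 * sum(thetas == obs)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_along(x), function(i) statistic(x[-i]), numeric(1))
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  zq <- stats::qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  unname(stats::quantile(thetas, adj, type = 6))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(m)`, reject the
#' k smallest where `k = max{ i : p(i) <= q * i / m }`. Adjusted p-values are
#' the monotone cumulative minimum of `p(i) * m / i`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q target FDR level (default 0.05).
#' @return list with logical `reject` and numeric `adjusted`, both in the
#'   input order; empty input gives empty output.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(list(reject = logical(0), adjusted = numeric(0)))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  crit <- q * seq_len(m) / m
  k <- max(c(0L, which(ranked <= crit)))
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  adj_sorted <- rev(cummin(rev(pmin(1, ranked * m / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(reject = reject, adjusted = adjusted)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranked values, with the t-approximation
#' p-value (two-sided); noted as an approximation in the method descriptor.
#'
#' @param x,y equal-length numeric vectors, length >= 3, non-constant.
#' @return `stat_result` with `statistic` (rho) and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  stat_result(rho, p, "Spearman rank correlation (t approximation)")
}

# Iteratively reweighted least-squares slope with Tukey bisquare weights,
# initialized at OLS; scale fixed per iteration at 1.4826 * MAD of residuals.
robust_slope <- function(x, y, max_iter = 50, tol = 1e-8) {
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- fit$coefficients
  for (it in seq_len(max_iter)) {
    r <- y - b[1] - b[2] * x
    s <- stats::mad(r, center = 0)
    if (!is.finite(s) || s == 0) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 3) break
    fit_w <- stats::lm.wfit(cbind(1, x), y, w)
    if (max(abs(fit_w$coefficients - b)) < tol * max(1, abs(b[2]))) {
      b <- fit_w$coefficients; break
    }
    b <- fit_w$coefficients
  }
  unname(b[2])
}

#' Permutation test of a robust regression slope
#'
#' The observed slope comes from bisquare IRLS robust regression of `y` on
#' `x`; `y` is permuted `n_perm` times and the p-value is
#' `(1 + #{|slope_perm| >= |slope_obs|}) / (n_perm + 1)` (the +1 convention
#' avoids p = 0).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return `stat_result` with `statistic` (the robust slope) and `p`.
#' @export
permutation_slope_test <- function(x, y, n_perm = 1000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  slope_obs <- robust_slope(x, y)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(robust_slope(x, sample(y))) >= abs(slope_obs)
    }, logical(1)))
  })
  stat_result(slope_obs, (1 + exceed) / (n_perm + 1),
              sprintf("permutation test of bisquare robust slope (%d permutations)",
                      n_perm))
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = pre - post`, with two-sided p and a t-based confidence interval for
#' the mean difference.
#'
#' @param pre,post equal-length numeric vectors, length >= 2, with
#'   non-constant differences.
#' @param level confidence level for the mean-difference CI.
#' @return `stat_result` with `statistic` (t), `p`, `mean_diff`, `ci`.
#' @export
paired_t <- function(pre, post, level = 0.95) {
  if (length(pre) != length(post) || length(pre) < 2)
    stop("pre and post must have equal length >= 2", call. = FALSE)
  d <- pre - post
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences", call. = FALSE)
  n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  tval <- mean(d) / se
  p <- 2 * stats::pt(-abs(tval), n - 1)
  ci <- mean(d) + c(-1, 1) * stats::qt((1 + level) / 2, n - 1) * se
  stat_result(tval, p, "paired t-test", mean_diff = mean(d), ci = ci)
}
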