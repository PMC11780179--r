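# Group-comparison statistics used on the image-based measurements:
# one-way ANOVA with Tukey HSD for the lung metrics, Welch and Brown-Forsythe
# ANOVA with Dunnett's T3 for body weights, all at alpha = 0.05.
#
# F-distribution and studentized-range tail probabilities come from base R
# (stats::pf, stats::ptukey); the studentized maximum modulus needed by
# Dunnett's T3 has no base implementation and is evaluated by fixed-seed
# Monte Carlo. Permutation and Monte-Carlo oracles used by the test suite are
# exported so validation is reproducible.

as_group_list <- function(data) {
  if (is.data.frame(data)) data <- split(data[[2]], data[[1]])
  stopifnot(is.list(data), length(data) >= 2L)
  data <- lapply(data, function(x) as.numeric(x[is.finite(x)]))
  if (is.null(names(data)) || any(names(data) == ""))
    names(data) <- paste0("group", seq_along(data))
  if (any(vapply(data, length, 1L) < 2L))
    stop("every group needs n >= 2")
  data
}

group_stats <- function(groups) {
  list(n = vapply(groups, length, 1.0),
       mean = vapply(groups, mean, 1.0),
       var = vapply(groups, stats::var, 1.0))
}

comparison_result <- function(statistic, df1, df2, p_value, method,
                              pairwise = NULL, alpha = 0.05) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p_value, method = method, pairwise = pairwise,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: F = %.4g on (%.4g, %.4g) df, p = %.4g\n",
              x$method, x$statistic, x$df1, x$df2, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MSB / MSW` on `(k - 1, N - k)`
#' degrees of freedom. Degenerate inputs are handled explicitly: all values
#' identical gives `F = 0, p = 1`; zero within-group variance with unequal
#' means gives `p = 0` with a warning.
#'
#' @param data a named list of numeric vectors (one per group, each n >= 2),
#'   or a two-column data frame (group, value).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A `comparison_result` with the omnibus F, df and p value.
#' @export
one_way_anova <- function(data, alpha = 0.05) {
  g <- as_group_list(data)
  s <- group_stats(g)
  k <- length(g); N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - grand)^2)
  ssw <- sum((s$n - 1) * s$var)
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(comparison_result(0, df1, df2, 1, "one-way ANOVA",
                                           alpha = alpha))
    warning("zero within-group variance with unequal means")
    return(comparison_result(Inf, df1, df2, 0, "one-way ANOVA", alpha = alpha))
  }
  f <- (ssb / df1) / (ssw / df2)
  comparison_result(f, df1, df2, stats::pf(f, df1, df2, lower.tail = FALSE),
                    "one-way ANOVA", alpha = alpha)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p values for all group pairs, using the pooled
#' within-group mean square; unequal group sizes use the Tukey-Kramer
#' standard error `sqrt(MSW/2 * (1/n_i + 1/n_j))`.
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (difference of means), `q` (studentized-range statistic), `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(data, alpha = 0.05) {
  g <- as_group_list(data)
  s <- group_stats(g)
  k <- length(g); N <- sum(s$n)
  msw <- sum((s$n - 1) * s$var) / (N - k)
  pairs <- utils::combn(k, 2)
  res <- vapply(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    est <- unname(s$mean[j] - s$mean[i])
    se <- sqrt(msw / 2 * (1 / s$n[i] + 1 / s$n[j]))
    q <- unname(if (se > 0) abs(est) / se else if (est == 0) 0 else Inf)
    p <- unname(if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
    c(est, q, p)
  }, numeric(3))
  tibble::tibble(
    group1 = names(g)[pairs[1, ]], group2 = names(g)[pairs[2, ]],
    estimate = res[1, ], q = res[2, ], p_adj = pmin(1, res[3, ]),
    significant = res[3, ] < alpha)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F with Satterthwaite-type denominator degrees of freedom; does not
#' assume equal group variances. Any group with zero variance is an error
#' (its weight is undefined).
#'
#' @inheritParams one_way_anova
#' @return A `comparison_result`.
#' @export
welch_anova <- function(data, alpha = 0.05) {
  g <- as_group_list(data)
  s <- group_stats(g)
  if (any(s$var == 0)) stop("zero group variance: Welch weights undefined")
  k <- length(g)
  w <- s$n / s$var
  W <- sum(w)
  mw <- sum(w * s$mean) / W
  a <- sum((1 - w / W)^2 / (s$n - 1))
  num <- sum(w * (s$mean - mw)^2) / (k - 1)
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * a
  f <- num / den
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * a)
  comparison_result(f, df1, df2, stats::pf(f, df1, df2, lower.tail = FALSE),
                    "Welch ANOVA", alpha = alpha)
}

#' Brown-Forsythe one-way ANOVA (test of means)
#'
#' The Brown-Forsythe F* statistic: between-group sum of squares over
#' `sum((1 - n_i/N) * s_i^2)`, with Satterthwaite denominator degrees of
#' freedom. Robust to unequal variances.
#'
#' @inheritParams one_way_anova
#' @return A `comparison_result`.
#' @export
brown_forsythe <- function(data, alpha = 0.05) {
  g <- as_group_list(data)
  s <- group_stats(g)
  if (any(s$var == 0)) stop("zero group variance: weights undefined")
  k <- length(g); N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - grand)^2)
  ci <- (1 - s$n / N) * s$var
  f <- ssb / sum(ci)
  df1 <- k - 1
  df2 <- sum(ci)^2 / sum(ci^2 / (s$n - 1))
  comparison_result(f, df1, df2, stats::pf(f, df1, df2, lower.tail = FALSE),
                    "Brown-Forsythe ANOVA", alpha = alpha)
}

#' Dunnett's T3 pairwise comparisons
#'
#' Pairwise Welch-type t statistics with Satterthwaite degrees of freedom,
#' adjusted against the studentized maximum modulus (SMM) distribution with
#' `m = k(k-1)/2` comparisons. The SMM tail probability is evaluated by
#' fixed-seed Monte Carlo (`max |Z_1..Z_m| / sqrt(chi^2_nu / nu)` with
#' independent draws), with `n_mc` draws per comparison.
#'
#' @inheritParams one_way_anova
#' @param n_mc Monte-Carlo draws for the SMM tail (default 1e6).
#' @param mc_seed RNG seed for the Monte-Carlo evaluation (default
#'   20240915; fixed so results are reproducible).
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`,
#'   `t` (Welch statistic), `df`, `p_adj`, `significant`.
#' @export
dunnett_t3 <- function(data, alpha = 0.05, n_mc = 1e6, mc_seed = 20240915L) {
  g <- as_group_list(data)
  s <- group_stats(g)
  if (any(s$var == 0)) stop("zero group variance: T3 undefined")
  k <- length(g)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  stat <- vapply(seq_len(m), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    vi <- s$var[i] / s$n[i]; vj <- s$var[j] / s$n[j]
    est <- unname(s$mean[j] - s$mean[i])
    tt <- est / sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (s$n[i] - 1) + vj^2 / (s$n[j] - 1))
    c(est, unname(tt), unname(df))
  }, numeric(3))
  p_adj <- vapply(seq_len(m), function(c_idx) {
    smm_tail(abs(stat[2, c_idx]), m, stat[3, c_idx], n_mc, mc_seed)
  }, 1.0)
  tibble::tibble(
    group1 = names(g)[pairs[1, ]], group2 = names(g)[pairs[2, ]],
    estimate = stat[1, ], t = stat[2, ], df = stat[3, ],
    p_adj = pmin(1, p_adj), significant = p_adj < alpha)
}

# P(max_j |Z_j| / sqrt(chi2_nu/nu) > q), Monte Carlo with fixed seed
smm_tail <- function(q, m, nu, n_mc, seed) {
  withr::with_seed(seed, {
    z <- matrix(abs(stats::rnorm(n_mc * m)), nrow = n_mc)
    mx <- if (m == 1L) z[, 1] else do.call(pmax, asplit(z, 2))
    s <- sqrt(stats::rchisq(n_mc, df = nu) / nu)
    mean(mx / s > q)
  })
}

#' Label-permutation p value for an omnibus statistic
#'
#' Independent oracle used for validation: the statistic (default the ANOVA
#' F) is recomputed under `n_perm` random permutations of the group labels;
#' the p value is `(1 + #{stat_perm >= stat_obs}) / (n_perm + 1)`.
#'
#' @inheritParams one_way_anova
#' @param statistic function mapping a named group list to a scalar; default
#'   computes the classical F.
#' @param n_perm number of permutations (>= 1000).
#' @param seed RNG seed.
#' @return Permutation p value.
#' @export
permutation_oracle <- function(data, statistic = NULL, n_perm = 1e4,
                               seed = 1L) {
  if (n_perm < 1e3) stop("n_perm must be >= 1000")
  g <- as_group_list(data)
  if (is.null(statistic))
    statistic <- function(gl) one_way_anova(gl)$statistic
  values <- unlist(g, use.names = FALSE)
  sizes <- vapply(g, length, 1L)
  idx <- rep(seq_along(g), sizes)
  obs <- statistic(g)
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      statistic(split(values[sample.int(length(values))], idx))
    }, 1.0)
  })
  (1 + sum(perm_stats >= obs)) / (n_perm + 1)
}
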