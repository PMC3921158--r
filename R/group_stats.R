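#' Natural log transform for positive measures
#'
#' Connectivity and graph measures are log-transformed before group testing
#' (they are positively skewed). Non-positive values are a hard error: a
#' PLI of exactly zero must be handled upstream.
#'
#' @param values numeric vector of strictly positive values.
#' @return `log(values)`.
#' @export
log_transform <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("log transform requires strictly positive finite values")
  log(values)
}

#' Two-tailed independent-samples t-test (pooled variance)
#'
#' Student's t with pooled variance, df = n1 + n2 - 2, two-tailed p, and
#' partial eta squared t^2 / (t^2 + df) as effect size.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return List of class `"stat_result"`: `t`, `df`, `p`, `eta_p2`.
#' @export
independent_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  t <- unname(ht$statistic)
  df <- unname(ht$parameter)
  structure(list(t = t, df = df, p = ht$p.value,
                 eta_p2 = t^2 / (t^2 + df)),
            class = "stat_result")
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List of class `"correlation_result"`: `r`, `n`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), n = length(x), p = ht$p.value),
            class = "correlation_result")
}

#' Power of a two-sample two-tailed t-test
#'
#' Exact power under the noncentral t distribution with noncentrality
#' d * sqrt(n / 2) and 2n - 2 degrees of freedom.
#'
#' @param n per-group sample size (>= 2).
#' @param d standardized mean difference (Cohen's d).
#' @param alpha two-tailed significance level.
#' @return Power in (0, 1).
#' @export
t_test_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Required per-group sample size
#'
#' Smallest integer per-group n such that a two-sided two-sample t-test at
#' level `alpha` reaches at least the target power for effect size `d`,
#' from the noncentral-t power curve. The conventional large effect
#' (d = 0.8) at alpha .05 and power .80 gives n = 26.
#'
#' @param effect_size_d standardized mean difference, > 0.
#' @param alpha test level in (0, 1).
#' @param power target power in (0, 1).
#' @return Integer per-group sample size (minimum 2).
#' @export
required_n <- function(effect_size_d = 0.8, alpha = 0.05, power = 0.80) {
  if (effect_size_d <= 0) stop("effect size must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("target power must be in (0, 1)")
  n <- 2
  while (t_test_power(n, effect_size_d, alpha) < power) {
    n <- n + 1
    if (n > 1e7) stop("required sample size exceeds search bound")
  }
  n
}
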