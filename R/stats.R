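#' Exact Mann-Whitney U test by full enumeration
#'
#' Two-sided Mann-Whitney test whose null distribution is obtained by
#' enumerating all `choose(n1+n2, n1)` assignments of the pooled observed
#' values to the two groups. Ties are handled naturally: U is computed from
#' mid-ranks and the enumeration runs over the observed (possibly tied)
#' rank multiset, so the exact p-value remains valid with ties — the case
#' base R's exact `wilcox.test` refuses. The two-sided p-value counts
#' assignments whose U is at least as far from its null mean `n1*n2/2` as
#' the observed U (the null distribution is symmetric because swapping group
#' labels maps U to `n1*n2 - U`).
#'
#' Beyond `n1 + n2 > exact_limit` (default 25) the enumeration is replaced
#' by the normal approximation with tie-corrected variance, flagged in the
#' method label.
#'
#' @param x,y numeric vectors of measurements for the two groups.
#' @param exact_limit largest pooled size for which full enumeration is
#'   attempted.
#' @return an object of class `htest` with the U statistic (for the first
#'   sample), the two-sided p-value, and `n1`, `n2` in `parameter`.
#' @examples
#' # complete separation at n = 4 vs 5: the smallest achievable two-sided level
#' mw_exact_test(c(10, 11, 12, 13), c(1, 2, 3, 4, 5))$p.value  # 2/126
#' @export
mw_exact_test <- function(x, y, exact_limit = 25) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))  # mid-ranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    # U for an assignment depends only on its rank sum
    rank_sums <- combn(r, n1, FUN = sum)
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "Exact Mann-Whitney U test (full enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u_obs),
                 parameter = c(n1 = n1, n2 = n2),
                 p.value = p,
                 method = method,
                 alternative = "two.sided",
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y)))),
            class = "htest")
}

#' Welch two-sample t test
#'
#' Unpaired t test without assuming equal variances (Welch-Satterthwaite
#' degrees of freedom), as used for the larger weight-suckle-weight samples.
#' Thin wrapper over [stats::t.test()]. Degenerate near-constant data, which
#' `t.test` rejects, are handled directly: two constant samples with equal
#' means give t = 0, p = 1; otherwise the Welch statistic is computed from
#' the defining formulas (an exactly zero standard error with distinct means
#' yields the smallest representable positive p).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return an object of class `htest`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  tryCatch(stats::t.test(x, y, var.equal = FALSE),
           error = function(e) welch_degenerate(x, y))
}

# manual Welch computation for samples t.test considers essentially constant
welch_degenerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x) / n1
  v2 <- stats::var(y) / n2
  se <- sqrt(v1 + v2)
  delta <- mean(x) - mean(y)
  if (se == 0) {
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- n1 + n2 - 2
    p <- if (delta == 0) 1 else .Machine$double.xmin
  } else {
    tstat <- delta / se
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- max(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin)
  }
  structure(list(statistic = c(t = tstat),
                 parameter = c(df = df),
                 p.value = p,
                 method = "Welch Two Sample t-test (degenerate: near-constant samples)",
                 alternative = "two.sided",
                 estimate = c(`mean of x` = mean(x), `mean of y` = mean(y)),
                 data.name = "x and y"),
            class = "htest")
}

#' Median, quartiles and range of a sample
#'
#' Small-sample summary used for kinetic endpoints: median, lower and upper
#' quartiles by linear interpolation on the sorted values
#' ([stats::quantile()] type 7), and the min/max for "[min; max]"-style
#' reporting.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `median`, `q1`, `q3`, `min`, `max`.
#' @export
median_quartiles <- function(values) {
  if (length(values) == 0 || any(!is.finite(values)))
    stop("values must be non-empty and finite")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3],
    min = min(values), max = max(values))
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`: negative for a reduction (a
#' value of -34 is reported as a "34% reduction"), positive for an excess.
#'
#' @param reference the baseline value, non-zero.
#' @param value the value compared against it.
#' @return percent change.
#' @examples
#' percent_change(3.30, 2.18)  # about -34: the diet effect on milk flow
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (value - reference) / reference
}
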