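## Self-contained nonparametric statistics with exact small-sample behavior.
## These are deliberately not wrappers around stats::wilcox.test /
## stats::p.adjust / stats::chisq.test: the test suite uses those (and direct
## enumeration) as independent oracles.

new_stat_result <- function(statistic_name, statistic, p_value, method,
                            n = NULL, df = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(statistic_name = statistic_name, statistic = statistic,
         p_value = p_value, method = method, n = n, df = df),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.6g, p = %.6g (%s", x$statistic_name, x$statistic,
              x$p_value, x$method))
  if (!is.null(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(")\n")
  invisible(x)
}

midranks <- function(v) rank(v, ties.method = "average")

#' Mann-Whitney U test
#'
#' Two-sample rank test comparing experimental groups. The U statistic is
#' computed with midranks for ties. For small samples
#' (`n_x + n_y <= exact_limit`, no ties) the two-sided p-value is exact, by
#' enumeration of all group labelings; otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_limit maximum combined sample size for exact enumeration
#'   (default 20).
#' @return a `stat_result` with the U statistic (for `x`) and two-sided p.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- midranks(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))

  if (!ties && nx + ny <= exact_limit) {
    ## exact: U-distribution over all C(nx+ny, nx) labelings
    rk <- seq_len(nx + ny)
    combs <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(rk[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    return(new_stat_result("U", u, min(1, p), "exact enumeration",
                           n = c(nx, ny)))
  }

  ## normal approximation with tie and continuity corrections
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(new_stat_result("U", u, 1, "degenerate (all tied)",
                                          n = c(nx, ny)))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(-z))
  new_stat_result("U", u, p, "normal approximation (tie/continuity corrected)",
                  n = c(nx, ny))
}

#' Wilcoxon signed-rank test against zero
#'
#' One-sample signed-rank test of the symmetry hypothesis (median 0), used to
#' compare left/right log2 expression ratios with a symmetric null. Exact
#' zeros are dropped before ranking. For `n <= exact_limit` the two-sided
#' p-value is exact by enumeration of all 2^n sign assignments (valid under
#' ties in |d| because the realized midranks are enumerated); otherwise a
#' normal approximation with tie correction is used.
#'
#' @param d numeric vector of differences (e.g., log2 ratios).
#' @param exact_limit maximum n for exact enumeration (default 15).
#' @return a `stat_result` with the W+ statistic and two-sided p.
#' @export
wilcoxon_signed_rank_vs_zero <- function(d, exact_limit = 15) {
  d <- as.numeric(d)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(new_stat_result("W+", 0, 1, "degenerate (all zeros)", n = 0))
  r <- midranks(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4

  if (n <= exact_limit) {
    ## exact: all 2^n sign patterns on the realized ranks
    w_all <- 0
    for (i in seq_len(n)) {
      w_all <- c(w_all, w_all + r[i])
    }
    p <- mean(abs(w_all - mu) >= abs(w - mu) - 1e-12)
    return(new_stat_result("W+", w, min(1, p), "exact enumeration", n = n))
  }

  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(-z))
  new_stat_result("W+", w, p, "normal approximation (tie/continuity corrected)",
                  n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: adjusted p_(i) =
#' min_{j >= i} ( m * p_(j) / j ), capped at 1, returned in the original
#' order. NAs propagate (they do not count toward m).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson goodness-of-fit of observed counts against expected proportions,
#' optionally with Yates' continuity correction (2 cells only; the per-cell
#' correction |O - E| - 0.5 is floored at 0 to avoid over-correction).
#'
#' @param observed nonnegative integer counts.
#' @param expected_props proportions summing to 1; every expected count must
#'   be positive.
#' @param yates apply Yates' continuity correction (only valid for 2 cells).
#' @return a `stat_result` with the chi-squared statistic, df and p.
#' @export
chi_squared_gof <- function(observed, expected_props, yates = FALSE) {
  if (length(observed) != length(expected_props))
    stop("observed and expected_props must have equal length", call. = FALSE)
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be nonnegative integers", call. = FALSE)
  if (abs(sum(expected_props) - 1) > 1e-8)
    stop("expected_props must sum to 1", call. = FALSE)
  n <- sum(observed)
  expected <- n * expected_props
  if (any(expected <= 0))
    stop("all expected counts must be positive", call. = FALSE)
  k <- length(observed)
  if (yates && k != 2L)
    stop("Yates' correction is only defined for 2 cells", call. = FALSE)
  corr <- if (yates) 0.5 else 0
  dev <- pmax(abs(observed - expected) - corr, 0)
  statistic <- sum(dev^2 / expected)
  df <- k - 1L
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  new_stat_result("X-squared", statistic, p,
                  if (yates) "chi-squared GOF, Yates corrected"
                  else "chi-squared GOF",
                  n = n, df = df)
}
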