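#' Simple linear regression with R-squared
#'
#' Ordinary least squares of `y` on `x`, with the coefficient of
#' determination computed as the squared Pearson correlation. Implemented
#' self-contained (closed-form normal equations) so the phantom-based
#' validation pipeline has no external statistical dependency.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must not be
#'   constant.
#' @return an `ns_regression` list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("`x` is constant: slope undefined", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 0 else sxy^2 / (sxx * syy)
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r_squared = r2, n = n),
            class = "ns_regression")
}

#' @export
print.ns_regression <- function(x, ...) {
  cat(sprintf("<regression> y = %.4g x + %.4g, R^2 = %.4f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. `U` is reported for group
#' `a`: the number of (a, b) pairs with a > b, counting ties as 1/2. The
#' two-sided p-value doubles the smaller tail probability, capped at 1.
#'
#' With `method = "auto"`, the exact null distribution is used when the
#' combined sample size is at most 16 and there are no ties; otherwise the
#' normal approximation with mid-rank tie correction and continuity
#' correction is used. `method = "exact"` may be requested explicitly for
#' any tie-free samples — the null distribution is computed by the rank-sum
#' counting recurrence, which stays cheap far beyond n = 16.
#'
#' @param a,b numeric vectors, both nonempty.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return an `ns_mwu` list: `u_statistic`, `p_two_sided`, `method`
#'   (`"exact"` or `"normal-approximation"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty", call. = FALSE)
  if (!all(is.finite(c(a, b)))) stop("inputs must be finite", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- switch(method,
    auto = !ties && n1 + n2 <= 16L,
    exact = TRUE,
    normal = FALSE)
  if (use_exact && ties) {
    stop("exact method requires tie-free data; use method = \"normal\"",
         call. = FALSE)
  }
  if (use_exact) {
    counts <- rank_sum_counts(n1, n2)  # counts[k+1] = #subsets with U = k
    total <- sum(counts)
    lo <- sum(counts[seq_len(round(u) + 1)]) / total          # P(U <= u)
    hi <- sum(counts[(round(u) + 1):length(counts)]) / total  # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    meth <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(pooled)
    tiecor <- sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1))
    sig2 <- n1 * n2 / 12 * (n1 + n2 + 1 - tiecor)
    if (sig2 <= 0) {  # all observations identical
      p <- 1
    } else {
      z <- max(abs(u - mu) - 0.5, 0) / sqrt(sig2)  # continuity-corrected
      p <- min(1, 2 * stats::pnorm(-z))
    }
    meth <- "normal-approximation"
  }
  structure(list(u_statistic = u, p_two_sided = p, method = meth,
                 n1 = n1, n2 = n2),
            class = "ns_mwu")
}

#' @export
print.ns_mwu <- function(x, ...) {
  cat(sprintf("<mann-whitney> U = %g (n1 = %d, n2 = %d), two-sided p = %.4g (%s)\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; used by the phantom monotonicity
#' checks.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ---- internal ----------------------------------------------------------

# number of n1-subsets of ranks 1..n1+n2 achieving each U value 0..n1*n2:
# the standard Mann-Whitney counting recurrence (equivalently, partitions
# into at most n1 parts each at most n2)
rank_sum_counts <- function(n1, n2) {
  umax <- n1 * n2
  f <- matrix(0, nrow = n1 + 1L, ncol = umax + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n1 + n2)) {
    for (j in rev(seq_len(min(i, n1)))) {
      # adding rank i as the j-th chosen element raises U by i - j
      shift <- i - j
      if (shift <= umax) {
        src <- seq_len(umax + 1L - shift)
        f[j + 1L, src + shift] <- f[j + 1L, src + shift] + f[j, src]
      }
    }
  }
  f[n1 + 1L, ]
}
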