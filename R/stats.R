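#' Welch two-sample t-test
#'
#' Location test without the equal-variance assumption:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with unbiased group
#' variances, degrees of freedom by the Welch--Satterthwaite
#' approximation, and a two-sided p-value from Student's t. When both
#' groups have zero variance and equal means the convention `t = 0,
#' p = 1` applies; zero variance with unequal means gives `p = 0`.
#'
#' @param x,y numeric vectors, each of length at least 2, finite.
#' @return list with `t_stat`, `df_welch`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stopf("each group needs at least 2 values (got %d and %d)",
          length(x), length(y))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  d <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (d == 0) return(list(t_stat = 0, df_welch = nx + ny - 2, p_value = 1))
    return(list(t_stat = sign(d) * Inf, df_welch = nx + ny - 2, p_value = 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t, df_welch = df, p_value = 2 * pt(-abs(t), df))
}

# Row-wise Welch t over a matrix: columns idx_a vs idx_b.
# Returns t, df, p vectors; zero-variance rows follow welch_t_test's
# conventions.
welch_t_rows <- function(mat, idx_a, idx_b) {
  a <- mat[, idx_a, drop = FALSE]
  b <- mat[, idx_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  d <- ma - mb
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), 0)
  p[se2 == 0 & d == 0] <- 1
  list(t_stat = t, df_welch = df, p_value = p,
       mean_a = ma, mean_b = mb)
}

#' Holm step-down p-value adjustment
#'
#' Family-wise-error-controlling step-down adjustment: with the m
#' p-values sorted ascending, `adj(i) = min(1, max_{j <= i} (m - j + 1) *
#' p(j))`, mapped back to the input order. Ties are broken stably.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact null pmf of the Mann-Whitney U statistic for group sizes (m, n):
# distribution of the rank sum of m items drawn from ranks 1..(m+n),
# shifted by m(m+1)/2. Computed by subset-sum dynamic programming.
mwu_exact_pmf <- function(m, n) {
  N <- m + n
  maxs <- sum((N - m + 1):N)
  # g[k+1, s+1] = number of k-subsets of {1..v} with rank sum s
  g <- matrix(0, nrow = m + 1, ncol = maxs + 1)
  g[1, 1] <- 1
  for (v in seq_len(N)) {
    for (k in rev(seq_len(min(m, v)))) {
      src <- seq_len(maxs + 1 - v)
      g[k + 1, src + v] <- g[k + 1, src + v] + g[k, src]
    }
  }
  mins <- m * (m + 1) / 2
  counts <- g[m + 1, (mins + 1):(maxs + 1)]
  counts / choose(N, m)  # pmf over U = 0 .. m*n
}

#' Mann-Whitney U test
#'
#' `U_a` counts pairs with `a_i > b_j`, ties contributing 1/2 (computed
#' via the rank-sum identity). The exact two-sided p-value is used for
#' tie-free samples with `n_a * n_b <= 400` (or when `method = "exact"`);
#' otherwise a normal approximation with tie-corrected variance and a 0.5
#' continuity correction. Two-sided p is `min(1, 2 * one-sided)`.
#'
#' @param a,b numeric vectors, non-empty.
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @return list with `u_statistic` (for group `a`), `p_value` and the
#'   `method` used.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b))) stopf("non-finite values")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- method == "exact" ||
    (method == "auto" && !ties && na * nb <= 400)
  if (use_exact && ties) {
    stopf("exact method is only available for tie-free samples")
  }
  if (use_exact) {
    pmf <- mwu_exact_pmf(na, nb)
    pl <- sum(pmf[seq_len(u + 1)])          # P(U <= u)
    pg <- sum(pmf[(u + 1):(na * nb + 1)])   # P(U >= u)
    p <- min(1, 2 * min(pl, pg))
    return(list(u_statistic = u, p_value = p, method = "exact"))
  }
  mu <- na * nb / 2
  tab <- table(r)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sig2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sig2 == 0) {
    return(list(u_statistic = u, p_value = 1, method = "normal"))
  }
  dev <- u - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sig2)
  if (dev == 0) z <- 0
  p <- min(1, 2 * pnorm(-abs(z)))
  list(u_statistic = u, p_value = p, method = "normal")
}
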