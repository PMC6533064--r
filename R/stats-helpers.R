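# Vectorized column-wise t statistics for the mass-univariate layers.
# Degenerate zero-variance columns (reachable on synthetic data): a zero
# mean difference yields t = 0, p = 1; a nonzero difference with zero
# variance is treated as infinitely reliable (p -> 0, noise-free limit).

zero_se_p <- function(p, m, se_zero) {
  p[se_zero & m == 0] <- 1
  p[se_zero & m != 0] <- .Machine$double.xmin
  p
}

col_onesample_t <- function(A, mu = 0, alternative = "two.sided") {
  n <- nrow(A)
  m <- colMeans(A) - mu
  s <- sqrt(pmax(colMeans(A^2) - colMeans(A)^2, 0) * n / (n - 1))
  se <- s / sqrt(n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  p <- zero_se_p(p, m, se == 0)
  list(estimate = m, t = t, df = rep(df, length(t)), p = p)
}

col_welch_t <- function(A, B, alternative = "two.sided") {
  n1 <- nrow(A); n2 <- nrow(B)
  m <- colMeans(A) - colMeans(B)
  v1 <- pmax(colMeans(A^2) - colMeans(A)^2, 0) * n1 / (n1 - 1)
  v2 <- pmax(colMeans(B^2) - colMeans(B)^2, 0) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, m / sqrt(se2), ifelse(m == 0, 0, sign(m) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  p <- zero_se_p(p, m, se2 == 0)
  list(estimate = m, t = t, df = df, p = p)
}

col_paired_t <- function(A, B, alternative = "two.sided") {
  if (nrow(A) != nrow(B)) abort("paired comparison needs equal trial counts")
  col_onesample_t(A - B, 0, alternative)
}

# Moore-Penrose pseudo-inverse via SVD (for rectangular unmixing matrices).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
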