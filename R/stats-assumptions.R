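# Distributional assumption checks and sphericity machinery for the
# repeated-measures ANOVA.

#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper around Royston's algorithm
#' ([stats::shapiro.test()]): errors on degenerate input instead of
#' returning an undefined statistic.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("Shapiro-Wilk requires at least 3 observations")
  if (n > 5000) stop("Shapiro-Wilk is defined for n <= 5000")
  if (stats::sd(values) == 0)
    stop("Shapiro-Wilk is degenerate for a constant sample")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Levene's test for homogeneity of variance (classic, mean-centred)
#'
#' One-way ANOVA on the absolute deviations from each group's mean.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor).
#' @return list with `F`, `df1`, `df2` and `p`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("Levene's test needs at least two groups")
  z <- abs(values - stats::ave(values, groups))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (zg - mean(z))^2)
  ssw <- sum((z - zg[groups])^2)
  if (ssb <= .Machine$double.eps * sum(z^2))
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Greenhouse-Geisser epsilon from a repeated-measures covariance
#'
#' `eps = (sum lambda)^2 / ((k-1) * sum lambda^2)` where `lambda` are the
#' eigenvalues of the double-centred covariance matrix of the `k`
#' repeated measures. Equals 1 under compound symmetry (sphericity) and
#' reaches its lower bound `1/(k-1)` under maximal violation.
#'
#' @param cell_covariance `k x k` covariance matrix of the repeated
#'   measures.
#' @param k number of repeated-measure levels (defaults to
#'   `nrow(cell_covariance)`).
#' @return the epsilon estimate, clipped to `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(cell_covariance, k = nrow(cell_covariance)) {
  S <- as.matrix(cell_covariance)
  stopifnot(nrow(S) == k, ncol(S) == k)
  if (k < 2) stop("epsilon needs at least 2 levels")
  J <- diag(k) - matrix(1 / k, k, k)
  Sc <- J %*% S %*% J
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  if (sum(lam^2) == 0) return(1)
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(1, max(1 / (k - 1), eps))
}

# epsilon for an arbitrary within effect, from subject scores on an
# orthonormal contrast basis (d columns)
gg_epsilon_scores <- function(scores) {
  d <- ncol(scores)
  if (d < 2) return(1)
  M <- stats::cov(scores)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  if (sum(lam^2) == 0) return(1)
  min(1, max(1 / d, sum(lam)^2 / (d * sum(lam^2))))
}

#' Mauchly's test of sphericity
#'
#' Tests sphericity of `k` repeated measures from the sample covariance
#' of `n` subjects, via the chi-square approximation to `-rho (n-1)
#' log W`. With `k = 2` sphericity holds automatically (`W = 1, p = 1`).
#'
#' @param cell_covariance `k x k` sample covariance of the repeated
#'   measures (or, via `scores`, an `n x d` orthonormal-contrast score
#'   matrix).
#' @param n number of subjects the covariance was estimated from.
#' @param k number of repeated-measure levels.
#' @return list with `W`, `chisq`, `df` and `p`.
#' @export
mauchly <- function(cell_covariance, n, k = nrow(cell_covariance)) {
  S <- as.matrix(cell_covariance)
  C <- orthonormal_contrasts(k)
  M <- t(C) %*% S %*% C
  mauchly_from_M(M, n)
}

mauchly_from_M <- function(M, n) {
  d <- nrow(M)
  if (d < 2) return(list(W = 1, chisq = 0, df = 0, p = 1))
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam <= 0))
    return(list(W = 0, chisq = Inf, df = d * (d + 1) / 2 - 1, p = 0))
  W <- prod(lam) / (mean(lam))^d
  df <- d * (d + 1) / 2 - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chisq <- -(n - 1) * rho * log(W)
  list(W = W, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

# orthonormal basis of the k-1 dimensional contrast space (Helmert-based)
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}
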