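## Nonparametric tests with exact small-sample behaviour. The exact branches
## enumerate every assignment of the pooled sample, which is what makes their
## p-values checkable against brute force to machine precision.

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. For pooled sample sizes
#' `n + m <= exactMax` the p-value is computed by exhaustive enumeration of
#' all `choose(n + m, n)` group assignments of the pooled midranks;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Two-sided p-values are the doubled smaller tail,
#' capped at 1.
#'
#' @param x,y non-empty numeric samples.
#' @param twoSided two-sided (default) or one-sided (smaller tail).
#' @param exactMax largest pooled size for the exact branch.
#' @return A [TestResult-class] with `statistic` = U of `x`.
#' @examples
#' pValue(mannWhitneyU(c(1, 2), c(3, 4)))   # exact: 1/3
#' @export
mannWhitneyU <- function(x, y, twoSided = TRUE, exactMax = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (N <= exactMax) {
    idx <- utils::combn(N, n)
    Ustar <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    pLo <- mean(Ustar <= U + eps)
    pHi <- mean(Ustar >= U - eps)
    p1 <- min(pLo, pHi)
    p <- if (twoSided) min(1, 2 * p1) else p1
    return(new("TestResult", statistic = U, pValue = p,
               method = "Mann-Whitney U (exact enumeration)",
               n = c(n, m), exact = TRUE))
  }

  mu <- n * m / 2
  tab <- table(r)
  tieAdj <- sum(tab^3 - tab)
  sigma2 <- n * m / 12 * ((N + 1) - tieAdj / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- U - mu
    cc <- sign(z) * 0.5
    z <- (z - cc) / sqrt(sigma2)
    p <- if (twoSided) min(1, 2 * stats::pnorm(-abs(z)))
         else stats::pnorm(z)
  }
  new("TestResult", statistic = U, pValue = p,
      method = "Mann-Whitney U (normal approximation)",
      n = c(n, m), exact = FALSE)
}

#' @noRd
ksStatistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(q) mean(x <= q), 0)
  Fy <- vapply(v, function(q) mean(y <= q), 0)
  max(abs(Fx - Fy))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`. For pooled sizes `n + m <= exactMax` the
#' p-value `P(D* >= D)` is computed by exhaustive enumeration of all splits
#' of the pooled sample (valid with ties); otherwise the asymptotic
#' Kolmogorov distribution is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exactMax largest pooled size for the exact branch.
#' @return A [TestResult-class] with `statistic` = D.
#' @export
ksTwoSample <- function(x, y, exactMax = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  D <- ksStatistic(x, y)

  if (N <= exactMax) {
    pool <- c(x, y)
    idx <- utils::combn(N, n)
    Dstar <- apply(idx, 2L, function(i) ksStatistic(pool[i], pool[-i]))
    p <- mean(Dstar >= D - 1e-12)
    return(new("TestResult", statistic = D, pValue = p,
               method = "two-sample Kolmogorov-Smirnov (exact enumeration)",
               n = c(n, m), exact = TRUE))
  }

  ne <- n * m / N
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(1, max(0, p))
  new("TestResult", statistic = D, pValue = p,
      method = "two-sample Kolmogorov-Smirnov (asymptotic)",
      n = c(n, m), exact = FALSE)
}

#' Friedman rank test for paired conditions
#'
#' Friedman chi-square computed from within-subject ranks with the standard
#' tie correction, compared against the chi-square distribution with
#' `k - 1` degrees of freedom. Used to compare paired per-cell activity
#' across the control/drug/wash conditions.
#'
#' @param blocks numeric matrix, subjects (cells) x conditions, no missing
#'   cells.
#' @return A [TestResult-class] with the chi-square statistic.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 3, 5))
#' testStatistic(friedmanTest(m))   # maximal statistic 6 for k = 3, n = 3
#' @export
friedmanTest <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (anyNA(blocks)) stop("blocks must have no missing cells")
  nSub <- nrow(blocks); k <- ncol(blocks)
  if (nSub < 2L || k < 2L)
    stop("need at least 2 subjects and 2 conditions")
  R <- t(apply(blocks, 1L, rank))
  Rj <- colSums(R)
  num <- 12 * sum((Rj - nSub * (k + 1) / 2)^2)
  ties <- apply(blocks, 1L, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  den <- nSub * k * (k + 1) - sum(ties) / (k - 1)
  if (num == 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- num / den
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  new("TestResult", statistic = stat, pValue = p,
      method = "Friedman rank test", n = c(nSub, k), exact = FALSE)
}
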