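# Paired test machinery shared by the proteome and clinical modules.

#' Two-sided paired Wilcoxon signed-rank p-value
#'
#' Zero differences are dropped before ranking (the standard signed-rank
#' convention). With no ties among the remaining absolute differences and
#' n <= \code{exactLimit}, the p-value is exact (signed-rank distribution,
#' equivalent to enumerating all 2^n sign assignments); otherwise the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. An all-zero (or empty) difference vector is not
#' testable: the function returns p = 1 with \code{untestable = TRUE} so
#' that zero-noise null fixtures run end-to-end instead of erroring.
#'
#' @param d numeric vector of paired differences (NAs dropped).
#' @param exactLimit largest zero-free, tie-free n for which the exact
#'   distribution is used (default 25).
#' @return list(p, statistic, n, exact, untestable).
#' @examples
#' wilcoxonSignedRank(c(1.2, 0.8, 2.1, 0.3, 1.7, 0.9, 1.1, 0.5))$p  # 2/256
#' @export
wilcoxonSignedRank <- function(d, exactLimit = 25L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = NA_real_, n = 0L, exact = FALSE,
                untestable = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= exactLimit) {
    # exact two-sided: double the smaller tail of the signed-rank law
    p <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
    return(list(p = p, statistic = W, n = n, exact = TRUE, untestable = FALSE))
  }
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  if (sigma2 <= 0)
    return(list(p = 1, statistic = W, n = n, exact = FALSE, untestable = TRUE))
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(p = p, statistic = W, n = n, exact = FALSE, untestable = FALSE)
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion pi0 on a lambda grid
#' (default 0.05, 0.10, ..., 0.95) as
#' \code{mean(p > lambda) / (1 - lambda)}, smooths the estimates with a
#' cubic smoothing spline (df = 3) and evaluates the fit at the largest
#' lambda; the estimate is clamped to \code{[1/m, 1]} so no q-value can be
#' exactly zero. q-values are \code{pi0 * m * p / rank} monotonised from
#' the largest p downwards and capped at 1, i.e. with pi0 = 1 they equal
#' Benjamini-Hochberg adjusted p-values exactly.
#'
#' @param p vector of p-values in [0, 1] (NAs allowed, returned as NA).
#' @param lambda grid for pi0 estimation.
#' @param pi0 optional fixed pi0 overriding estimation (e.g. 1 for plain BH).
#' @return list(q = q-values in input order, pi0 = estimate used).
#' @examples
#' ps <- c(0.001, 0.02, 0.5, 0.8)
#' storeyQvalues(ps, pi0 = 1)$q    # identical to p.adjust(ps, "BH")
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  if (m == 0L) return(list(q = p, pi0 = NA_real_))
  if (is.null(pi0)) {
    lambda <- sort(lambda)
    pi0l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    pi0 <- if (length(lambda) >= 4L) {
      fit <- smooth.spline(lambda, pi0l, df = 3)
      predict(fit, x = max(lambda))$y
    } else pi0l[length(pi0l)]
    pi0 <- min(max(pi0, 1 / m), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  q <- pmin(q, 1)
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  list(q = out, pi0 = pi0)
}

#' Two-sided paired t-test p-value
#'
#' Classical paired t statistic on n - 1 degrees of freedom, as used for
#' small-n immunofluorescence intensity comparisons (n = 3 or 4 biopsies).
#' Differences with zero variance are not testable and are returned
#' flagged rather than as p = 0.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return list(p, t, df, meanDiff, untestable).
#' @examples
#' pairedTTest(c(2, 4, 6), c(1, 2, 3))  # t = 2*sqrt(3) on 2 df
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  keep <- complete.cases(a, b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  if (sd(d) == 0)
    return(list(p = NA_real_, t = NA_real_, df = n - 1L,
                meanDiff = mean(d), untestable = TRUE))
  ht <- t.test(a[keep], b[keep], paired = TRUE)
  list(p = ht$p.value, t = unname(ht$statistic), df = n - 1L,
       meanDiff = mean(d), untestable = FALSE)
}
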