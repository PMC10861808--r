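#' Paired Wilcoxon signed-rank test
#'
#' Classic drop-zeros Wilcoxon: zero differences are removed, absolute
#' differences are ranked with average ranks for ties, and the statistic is
#' the sum of ranks of positive differences. The null distribution is exact
#' (via [stats::psignrank()]) when n <= 25 and there are no ties among the
#' absolute differences; otherwise the normal approximation with tie
#' correction is used, without continuity correction. Two-sided p.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact null is used (default
#'   25).
#' @return List with `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n` (pairs after zero removal), `method` ("exact" or
#'   "normal").
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 5)
    stop("fewer than 5 nonzero differences (n = ", n,
         "): the signed-rank test is underpowered; refusing to mislead")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_max) {
    mu <- n * (n + 1) / 4
    p <- if (V > mu) 2 * (1 - stats::psignrank(V - 1, n))
         else 2 * stats::psignrank(V, n)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = V, p_value = min(1, p), n = n, method = method)
}

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of the (average-tie) rank vectors. The
#' p-value uses the exact permutation null for n <= `exact_max` (default
#' 8), otherwise the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom.
#' Two-sided.
#'
#' @param u,d Numeric vectors of equal length (>= 3, both with nonzero
#'   variance).
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(u, d, exact_max = 8) {
  if (length(u) != length(d)) stop("u and d must have equal length")
  n <- length(u)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::var(u) == 0 || stats::var(d) == 0)
    stop("zero variance in one coordinate: Spearman rho is undefined")
  ru <- rank(u); rd <- rank(d)
  rho <- stats::cor(ru, rd)
  if (n <= exact_max) {
    perms <- permutations(n)
    ruc <- ru - mean(ru)
    obs <- abs(sum(ruc * (rd - mean(rd))))
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      s <- abs(sum(ruc * (rd[perms[i, ]] - mean(rd))))
      if (s >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact-permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Ordinary least-squares linear trend
#'
#' Slope and intercept of `u` regressed on `d` (the summary line drawn
#' through an uncertainty-versus-distance cloud).
#'
#' @param u Response values.
#' @param d Predictor values; at least 2 distinct values required.
#' @return List with `slope` and `intercept`.
#' @export
linear_trend <- function(u, d) {
  if (length(u) != length(d)) stop("u and d must have equal length")
  if (length(unique(d)) < 2)
    stop("need at least 2 distinct predictor values for a linear trend")
  slope <- stats::cov(u, d) / stats::var(d)
  list(slope = slope, intercept = mean(u) - slope * mean(d))
}
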