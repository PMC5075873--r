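#' Wilcoxon rank-sum test
#'
#' The statistic is `W = sum of the pooled mid-ranks of group-1`, where
#' group-1 is the smaller group (groups are swapped if needed so that
#' `n1 <= n2`).  For `n1 + n2 <= exact_limit` the p-value is exact, computed
#' by enumerating all `choose(n1+n2, n1)` group-1 rank assignments;
#' otherwise a normal approximation with mid-rank tie correction is used
#' (no continuity correction).  Two-sided p-values sum both tails at or
#' beyond the observed statistic's distance from the null mean.
#'
#' @param group1,group2 numeric samples.
#' @param exact_limit largest pooled size for exhaustive enumeration.
#' @return a `rank_sum_report`: list with `W`, `n1`, `n2`, `p`, `method`
#'   (`"exact"` or `"normal"`) and `swapped` (whether the inputs were
#'   reordered to make group-1 the smaller group).
#' @export
wilcoxon_rank_sum <- function(group1, group2, exact_limit = 12) {
  swapped <- length(group1) > length(group2)
  if (swapped) { tmp <- group1; group1 <- group2; group2 <- tmp }
  n1 <- length(group1); n2 <- length(group2); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(group1, group2))  # mid-ranks for ties
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (N <= exact_limit) {
    combs <- utils::combn(N, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    dev <- abs(W - mu)
    p <- mean(abs(sums - mu) >= dev - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) { p <- 1 } else {
      z <- (W - mu) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(W = W, n1 = n1, n2 = n2, p = p, method = method,
                 swapped = swapped),
            class = "rank_sum_report")
}

#' @export
print.rank_sum_report <- function(x, ...) {
  cat("Wilcoxon rank sum: W = ", x$W, " (n1 = ", x$n1, ", n2 = ", x$n2,
      "), p = ", format(x$p, digits = 4), " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Two-sample test for equality of proportions
#'
#' Pooled-estimate z statistic without continuity correction:
#' `z = (k1/m - k2/n) / sqrt(phat (1 - phat) (1/m + 1/n))` with
#' `phat = (k1 + k2)/(m + n)`.  One-sided p is the upper tail of `z`
#' (alternative: proportion 1 greater); two-sided doubles the smaller tail.
#'
#' @param k1,m successes and size of sample 1.
#' @param k2,n successes and size of sample 2.
#' @param sided `"one"` or `"two"`.
#' @return a `proportion_report`: list with `z`, `p_hat`, `m`, `n`, `p`,
#'   `sided`.
#' @export
two_sample_proportion <- function(k1, m, k2, n, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (k1 < 0 || k1 > m || k2 < 0 || k2 > n) stop("successes must lie in [0, size]")
  p_hat <- (k1 + k2) / (m + n)
  if (p_hat <= 0 || p_hat >= 1)
    stop("pooled proportion is ", p_hat, "; z statistic undefined")
  z <- (k1 / m - k2 / n) / sqrt(p_hat * (1 - p_hat) * (1 / m + 1 / n))
  p <- if (sided == "one") stats::pnorm(z, lower.tail = FALSE)
       else min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(z = z, p_hat = p_hat, m = m, n = n, p = p, sided = sided),
            class = "proportion_report")
}

#' @export
print.proportion_report <- function(x, ...) {
  cat("Two-sample proportion test: z = ", format(x$z, digits = 4),
      " (pooled p-hat = ", format(x$p_hat, digits = 4), ", m = ", x$m,
      ", n = ", x$n, "), ", x$sided, "-sided p = ", format(x$p, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Binomial point probability
#'
#' `C(n, k) q^k (1 - q)^(n - k)`: the probability of exactly `k` successes
#' in `n` independent trials with success probability `q` (e.g. the chance
#' that 5 of 8 cases fall in one of four equally likely quadrants,
#' `binomial_point(8, 5, 1/4) = 0.0231`).
#'
#' @param n trials.
#' @param k successes (`0 <= k <= n`).
#' @param q success probability in `[0, 1]`.
#' @return the point probability.
#' @export
binomial_point <- function(n, k, q) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  # explicit product form; 0^0 = 1 covers the degenerate q in {0, 1} cases
  choose(n, k) * q^k * (1 - q)^(n - k)
}
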