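#' Log-space hypergeometric tail probabilities
#'
#' The statistic behind every overlap-map cell: for a universe of `n`
#' features, a prefix of `i` features from one list and `j` from the other,
#' the overlap count follows a hypergeometric distribution. Tails are
#' returned as natural logarithms so that P-values far below the smallest
#' representable double (for transcript-scale lists, e\eqn{^{-10000}} and
#' below) remain finite and comparable.
#'
#' `log_hyper_upper()` is \eqn{\ln P(X \ge c)}, `log_hyper_lower()` is
#' \eqn{\ln P(X \le c)}. Counts below the support lower bound
#' \eqn{\max(0, i + j - n)} are clamped to it, so `log_hyper_upper(0, ...)`
#' is exactly 0.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param c Overlap count(s), `0 <= c <= min(i, j)`.
#' @param i,j Prefix lengths, `1 <= i, j <= n`.
#' @param n Size of the common label universe.
#' @return Numeric vector of natural-log probabilities (all `<= 0`).
#' @examples
#' log_hyper_upper(5, 5, 5, 10)   # ln(1/252)
#' log_hyper_lower(0, 2, 2, 4)    # ln(1/6)
#' @export
log_hyper_upper <- function(c, i, j, n) {
  check_hyper_args(c, i, j, n)
  lo <- pmax(0, i + j - n)
  c <- pmax(c, lo)
  # P(X >= c) = upper tail at c - 1; exact in log space via phyper
  stats::phyper(c - 1, i, n - i, j, lower.tail = FALSE, log.p = TRUE)
}

#' @rdname log_hyper_upper
#' @export
log_hyper_lower <- function(c, i, j, n) {
  check_hyper_args(c, i, j, n)
  # below the support floor the event {X <= c} is empty: log P = -Inf
  stats::phyper(c, i, n - i, j, lower.tail = TRUE, log.p = TRUE)
}

check_hyper_args <- function(c, i, j, n) {
  if (anyNA(c) || anyNA(i) || anyNA(j) || anyNA(n)) {
    stop("hypergeometric arguments must not contain NA", call. = FALSE)
  }
  if (any(n < 1) || any(i < 1) || any(j < 1) || any(i > n) || any(j > n)) {
    stop("need 1 <= i, j <= n", call. = FALSE)
  }
  if (any(c < 0) || any(c > pmin(i, j))) {
    stop("need 0 <= c <= min(i, j)", call. = FALSE)
  }
  invisible(NULL)
}

#' Signed log P-value of a prefix-overlap count
#'
#' One-sided: the enrichment tail \eqn{P(X \ge c)}, always carrying sign +1.
#' Two-sided: \eqn{2 \min(P(X \ge c), P(X \le c))}, capped at 1; the sign is
#' -1 when the lower tail attains the minimum (the overlap is *depleted*,
#' i.e. the two prefixes are anticorrelated) and +1 otherwise, ties going to
#' +1. The log P-value is always on the natural-log scale, so the
#' conventional display threshold \eqn{-\ln(0.05) \approx 3} applies.
#'
#' @inheritParams log_hyper_upper
#' @param mode `"two_sided"` (default) or `"one_sided"`.
#' @return A list with numeric vectors `log_p` (`<= 0`) and `sign`
#'   (`+1`/`-1`).
#' @examples
#' signed_log_pvalue(2, 2, 2, 4)                 # ln(1/3), sign +1
#' signed_log_pvalue(0, 2, 2, 4)                 # ln(1/3), sign -1
#' signed_log_pvalue(0, 5, 5, 10, mode = "one_sided")  # 0, sign +1
#' @export
signed_log_pvalue <- function(c, i, j, n, mode = c("two_sided", "one_sided")) {
  mode <- match.arg(mode)
  c <- pmax(c, pmax(0, i + j - n)) # clamp to the support floor
  up <- log_hyper_upper(c, i, j, n)
  if (mode == "one_sided") {
    return(list(log_p = up, sign = rep(1, length(up))))
  }
  lo <- log_hyper_lower(c, i, j, n)
  log_p <- pmin(log(2) + pmin(up, lo), 0)
  sign <- ifelse(lo < up, -1, 1)
  list(log_p = log_p, sign = sign)
}
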