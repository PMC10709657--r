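# Independent oracles, deliberately naive: plain-arithmetic hypergeometric
# enumeration, set-based intersection counts, and exhaustive min-P searches.
# They share no code path with the package internals they check.

# Exact hypergeometric PMF by direct binomial products (exact in doubles for
# n <= 40 since all choose() values are < 2^53).
oracle_hyper_pmf <- function(i, j, n) {
  k <- 0:min(i, j)
  p <- choose(i, k) * choose(n - i, j - k) / choose(n, j)
  names(p) <- k
  p
}

oracle_log_upper <- function(c, i, j, n) {
  p <- oracle_hyper_pmf(i, j, n)
  log(sum(p[as.integer(names(p)) >= c]))
}

oracle_log_lower <- function(c, i, j, n) {
  p <- oracle_hyper_pmf(i, j, n)
  log(sum(p[as.integer(names(p)) <= c]))
}

# Log-space enumeration via lchoose + log-sum-exp: usable at any n, still an
# independent route (never calls phyper/dhyper).
oracle_log_upper_big <- function(c, i, j, n) {
  lo <- max(0, i + j - n)
  hi <- min(i, j)
  c <- max(c, lo)
  k <- c:hi
  terms <- lchoose(i, k) + lchoose(n - i, j - k) - lchoose(n, j)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

oracle_log_lower_big <- function(c, i, j, n) {
  lo <- max(0, i + j - n)
  hi <- min(i, j)
  c <- min(max(c, lo), hi)
  k <- lo:c
  terms <- lchoose(i, k) + lchoose(n - i, j - k) - lchoose(n, j)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# Naive prefix-intersection count from plain set operations.
oracle_overlap <- function(a_order, b_order, i, j) {
  length(intersect(a_order[seq_len(i)], b_order[seq_len(j)]))
}

# Exhaustive minimal-P search over a whole quadrant by brute force; mirrors
# the quadrant conventions but uses naive counts and direct phyper calls.
oracle_quadrant_min <- function(a, b, quadrant, mode = "two_sided") {
  quad <- quadrant_spec(quadrant)
  bounds <- quadrant_bounds(a, b, quadrant)
  ao <- oriented_labels(a, quad$orient_a)
  bo <- oriented_labels(b, quad$orient_b)
  n <- a$n
  # c(i, j) via cumulative membership: rank of each a-label in b's order
  pos_in_b <- match(ao, bo)
  best <- NULL
  for (i in seq_len(bounds[["max_i"]])) {
    inb <- sort(pos_in_b[seq_len(i)])
    js <- seq_len(bounds[["max_j"]])
    cnt <- findInterval(js, inb)
    slp <- signed_log_pvalue(cnt, i, js, n, mode = mode)
    ok <- slp$sign > 0
    if (!any(ok)) next
    lp <- slp$log_p[ok]
    k <- which(ok)[which.min(lp)]
    cand <- list(i = i, j = js[k], overlap = cnt[k], log_p = slp$log_p[k])
    if (is.null(best) || cand$log_p < best$log_p) best <- cand
  }
  best
}

# Small scenario helpers shared across test files.
tiny_lists <- function(n = 20, seed = 1) {
  sc <- make_scenario("random", n = n, seed = seed)
  list(a = sc$a, b = sc$b)
}
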