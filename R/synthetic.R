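#' Generate a synthetic signature pair
#'
#' Scenario generator used throughout the test-bench: each scenario yields
#' two ranked lists over the same label universe, with values mapped from
#' ranks onto a symmetric range so zero crossings are well defined.
#'
#' * `identical` — the two lists are the same: a full-length correlated
#'   diagonal.
#' * `reversed` — the second list's values are negated: a full-length
#'   anticorrelated (du/ud) diagonal.
#' * `four_block` — four consecutive rank blocks of n/4 features,
#'   concordant / concordant / discordant / discordant, with the zero
#'   crossing at a configurable fraction of the lists (default
#'   `zero_fraction = 0.4`), so all four quadrants carry a diagonal
#'   signal and the split lines sit off-centre.
#' * `random` — two independent rank shuffles: no signal.
#' * `planted` — the accuracy benchmark: `n_overlap` labels placed
#'   uniformly at random within the top `n_top` down-regulated positions
#'   of both lists, all remaining labels ranked at random. The default
#'   parameters (`n = 19962`, 200 planted among the top 300) are the
#'   benchmark conditions; a wider preset (e.g. 1500-2500 among the top
#'   3500-4500) can be requested through the same parameters.
#'
#' @param kind Scenario kind (see above).
#' @param n Universe size (`>= 10`).
#' @param n_overlap,n_top Planted-scenario parameters
#'   (`n_overlap <= n_top <= n`).
#' @param zero_fraction Position of the zero crossing as a fraction of the
#'   list (four-block scenario).
#' @param seed Integer seed; the same seed reproduces the same lists.
#' @return A list of class `overlap_scenario`: ranked lists `a` and `b`,
#'   the `planted` label set (planted scenario only, otherwise `NULL`),
#'   and `params`.
#' @export
make_scenario <- function(kind = c("identical", "reversed", "four_block",
                                   "random", "planted"),
                          n = 1000, n_overlap = 200, n_top = 300,
                          zero_fraction = 0.4, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 10)
  if (kind == "planted") {
    stopifnot(n_overlap >= 1, n_overlap <= n_top, n_top <= n)
  }
  labels <- sprintf("g%0*d", nchar(n), seq_len(n))
  # rank r of n maps to ((r - zero_pos) - 0.5) / n: strictly increasing,
  # symmetric for zero_pos = n/2, zero crossing after floor(frac * n)
  rank_values <- function(frac) {
    (seq_len(n) - floor(frac * n) - 0.5) / n
  }
  build <- function(order_labels, values) new_ranked_list(order_labels, values)
  gen <- function() {
    switch(kind,
      identical = {
        perm <- sample(labels)
        v <- rank_values(0.5)
        list(a = build(perm, v), b = build(perm, v), planted = NULL)
      },
      reversed = {
        perm <- sample(labels)
        v <- rank_values(0.5)
        # negating symmetric values exactly reverses the ranking
        list(a = build(perm, v), b = build(rev(perm), v), planted = NULL)
      },
      four_block = {
        perm <- sample(labels)
        v <- rank_values(zero_fraction)
        q <- n %/% 4L
        dd <- perm[seq_len(q)]
        du <- perm[q + seq_len(q)]
        ud <- perm[2L * q + seq_len(q)]
        uu <- perm[(3L * q + 1L):n]
        # each class is interleaved toward the extremities it belongs to,
        # so every quadrant sees a diagonal enrichment from its own corner:
        # dd genes head both down ends, uu genes both up ends, du genes the
        # down end of a and the up end of b, ud genes the converse
        ilv <- function(x, y) { # alternate x1 y1 x2 y2 ..., then leftovers
          k <- min(length(x), length(y))
          c(rbind(x[seq_len(k)], y[seq_len(k)]),
            x[-seq_len(k)], y[-seq_len(k)])
        }
        perm_a <- c(ilv(dd, du), rev(ilv(uu, ud)))
        perm_b <- c(ilv(dd, ud), rev(ilv(uu, du)))
        list(a = build(perm_a, v), b = build(perm_b, v), planted = NULL)
      },
      random = {
        v <- rank_values(0.5)
        list(a = build(sample(labels), v), b = build(sample(labels), v),
             planted = NULL)
      },
      planted = {
        v <- rank_values(0.5)
        planted <- sample(labels, n_overlap)
        rest <- setdiff(labels, planted)
        place <- function() {
          ord <- character(n)
          top_pos <- sample(n_top, n_overlap)
          ord[top_pos] <- sample(planted)
          ord[setdiff(seq_len(n), top_pos)] <- sample(rest)
          ord
        }
        list(a = build(place(), v), b = build(place(), v),
             planted = sort(planted))
      }
    )
  }
  out <- with_seed_if(seed, gen())
  structure(
    c(out, list(params = list(kind = kind, n = n,
                              n_overlap = if (kind == "planted") n_overlap,
                              n_top = if (kind == "planted") n_top,
                              zero_fraction = if (kind == "four_block")
                                zero_fraction,
                              seed = seed))),
    class = "overlap_scenario"
  )
}

#' @export
print.overlap_scenario <- function(x, ...) {
  cat("<overlap_scenario> kind = ", x$params$kind, ", n = ", x$params$n,
      if (!is.null(x$planted)) paste0(", |planted| = ", length(x$planted)),
      "\n", sep = "")
  invisible(x)
}

#' Detection-accuracy metrics against a planted set
#'
#' @param detected Labels returned by the overlap analysis.
#' @param planted Labels constructed to overlap.
#' @param n Universe size.
#' @return A one-row tibble: `tpr` (planted features recovered), `tnr`
#'   (non-planted features correctly excluded), `accuracy`
#'   (`(TP + TN)/n`), and the raw counts.
#' @export
accuracy_metrics <- function(detected, planted, n) {
  tp <- length(intersect(detected, planted))
  fp <- length(setdiff(detected, planted))
  fn <- length(planted) - tp
  tn <- n - length(planted) - fp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    tpr = tp / length(planted),
    tnr = tn / (n - length(planted)),
    accuracy = (tp + tn) / n
  )
}

#' Accuracy benchmark on planted-overlap scenarios
#'
#' Generates independent planted scenarios (seeded reproducibly from
#' `seed`, so different search algorithms can be scored on the same
#' scenarios by passing the same `seed`), runs the down-down quadrant
#' search — the planted overlaps are down-regulated in both lists — and
#' scores the detected enrichment set against the planted set.
#'
#' @param replicates Number of scenarios (`>= 1`).
#' @param algorithm `"ea"` or `"grid"`.
#' @inheritParams rrho
#' @inheritParams make_scenario
#' @param seed Master seed for scenario generation and the search.
#' @return A tibble with one row per replicate: scenario seed, best
#'   coordinate, overlap, `log_p`, and `tpr`/`tnr`/`accuracy`.
#' @export
benchmark_accuracy <- function(replicates = 20,
                               algorithm = c("ea", "grid"),
                               n = 19962, n_overlap = 200, n_top = 300,
                               step = NULL, ea = ea_params(),
                               mode = c("two_sided", "one_sided"),
                               seed = 1) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  stopifnot(replicates >= 1)
  scen_seeds <- derive_seeds(seed, replicates)
  search_seeds <- derive_seeds(seed + 1L, replicates)
  purrr::map_dfr(seq_len(replicates), function(r) {
    sc <- make_scenario("planted", n = n, n_overlap = n_overlap,
                        n_top = n_top, seed = scen_seeds[r])
    fit <- rrho(sc$a, sc$b, algorithm = algorithm, mode = mode, step = step,
                ea = ea, quadrants = "dd", adjust = "none", map = FALSE,
                seed = search_seeds[r])
    q <- fit$quadrants$dd
    metrics <- accuracy_metrics(q$enriched, sc$planted, n)
    dplyr::bind_cols(
      tibble::tibble(replicate = r, scenario_seed = scen_seeds[r],
                     algorithm = algorithm, i = q$i, j = q$j,
                     overlap = q$overlap, log_p = q$log_p),
      metrics
    )
  })
}

#' Type-I-error harness on random list pairs
#'
#' Generates independent random signature pairs, runs the full pipeline
#' with the permutation-adjusted minimal P-value on each (plain-permutation
#' null: random lists carry no expression matrices), and counts the pairs
#' in which any quadrant reports an adjusted P below 0.05. Under a sound
#' adjustment this fraction stays at or below the nominal 5%. The returned
#' binomial tail is the exact one-sided probability of observing at most
#' the seen count if the true rate were 5%.
#'
#' @param n_pairs Number of random pairs (`>= 50`).
#' @param n List length per pair.
#' @param permutations Permutations per pair.
#' @inheritParams rrho
#' @param seed Master seed.
#' @return A one-row tibble: `n_pairs`, `n_significant`, `fraction`,
#'   `percent`, and `binom_p = binom_lower_tail(n_significant, n_pairs,
#'   0.05)`.
#' @export
type1_harness <- function(n_pairs = 200, n = 1000, permutations = 100,
                          algorithm = c("grid", "ea"), step = NULL,
                          ea = ea_params(),
                          mode = c("two_sided", "one_sided"), seed = 1) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  stopifnot(n_pairs >= 50)
  pair_seeds <- derive_seeds(seed, 2L * n_pairs)
  hits <- vapply(seq_len(n_pairs), function(k) {
    sc <- make_scenario("random", n = n, seed = pair_seeds[k])
    fit <- rrho(sc$a, sc$b, algorithm = algorithm, step = step, ea = ea,
                mode = mode, adjust = "permutation",
                permutations = permutations, map = FALSE,
                seed = pair_seeds[n_pairs + k])
    any(vapply(fit$quadrants,
               function(q) isTRUE(q$p_adjusted < 0.05), logical(1)))
  }, logical(1))
  k <- sum(hits)
  tibble::tibble(
    n_pairs = n_pairs, n = n, permutations = permutations,
    n_significant = k, fraction = k / n_pairs,
    percent = 100 * k / n_pairs,
    binom_p = binom_lower_tail(k, n_pairs, 0.05)
  )
}

#' Exact one-sided lower binomial tail
#'
#' `P(X <= k)` for `X ~ Binomial(n, rate)`; used to quantify how far below
#' the nominal rate an observed type-I count lies.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param rate Nominal success rate.
#' @return The exact tail probability.
#' @export
binom_lower_tail <- function(k, n, rate = 0.05) {
  stats::pbinom(k, n, rate)
}
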