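#' Partition features into HPP predictor and predicted sets
#'
#' The hybrid prediction-permutation (HPP) null preserves inter-feature
#' correlation without re-running the differential analysis: features that
#' cannot be predicted from one another are permuted freely (the
#' *predictor* set), and every remaining feature (the *predicted* set) is
#' reconstructed from its best predictor via a fitted linear relation.
#'
#' For each feature y, simple regressions
#' \eqn{\log Expr_y = \beta_1 \log Expr_x + \beta_0} are fitted against
#' candidate predictors x (vectorised through the correlation structure,
#' exactly equivalent to per-pair ordinary least squares). Among models
#' with \eqn{\beta_1} significant at `alpha_sig` (t test), the minimal
#' mean-squared-error model is kept — which for simple OLS is the model
#' with the largest |r|, so the fold-change and P-value flavours select
#' the same predictor and differ only in the stored model (slope
#' \eqn{\beta_1} vs |r|). A feature is a *predictor* if it best-predicts
#' another feature and is not itself predicted; chains of predictions are
#' allowed, cycles are broken by moving the lexicographically smallest
#' label of the cycle into the predictor set. Features with no significant
#' predictor, and constant-expression features, join the predictor set.
#'
#' @param expr Feature-by-sample log-expression matrix with feature labels
#'   as rownames and at least 3 samples.
#' @param flavour `"fold_change"` (slope model) or `"pvalue"`
#'   (correlation-mixture model).
#' @param alpha_sig Significance level for the slope t test.
#' @param max_candidates Candidate predictors considered per feature: the
#'   `max_candidates` most correlated features (all pairs when the matrix
#'   is small enough).
#' @return An `hpp_assignment`: `predictor_set` (character),
#'   `predicted` (tibble `feature`, `predictor`, `beta1`, `r`, `depth`,
#'   topologically sorted), `flavour`.
#' @export
select_predictors <- function(expr, flavour = c("fold_change", "pvalue"),
                              alpha_sig = 0.05, max_candidates = 200) {
  flavour <- match.arg(flavour)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) {
    stop("need at least 3 samples to fit expression regressions, got ",
         ncol(expr), call. = FALSE)
  }
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr))) {
    stop("expression matrix needs unique feature rownames", call. = FALSE)
  }
  labels <- rownames(expr)
  m <- ncol(expr)
  sds <- apply(expr, 1, stats::sd)
  variable <- sds > 0
  edges <- NULL
  if (sum(variable) >= 2) {
    vlab <- labels[variable]
    C <- stats::cor(t(expr[variable, , drop = FALSE]))
    diag(C) <- NA_real_
    absr <- abs(C)
    # two-sided t test on the slope == t test on r
    tt <- absr * sqrt((m - 2) / pmax(1 - absr^2, 0))
    pv <- 2 * stats::pt(tt, df = m - 2, lower.tail = FALSE)
    sig <- !is.na(pv) & pv < alpha_sig
    pick <- lapply(seq_along(vlab), function(y) {
      cand <- which(sig[y, ])
      if (!length(cand)) return(NULL)
      if (length(cand) > max_candidates) {
        cand <- cand[order(-absr[y, cand])][seq_len(max_candidates)]
      }
      # best = max |r| (= minimal MSE); ties to the smaller label
      best <- cand[order(-absr[y, cand], vlab[cand])][1]
      data.frame(feature = vlab[y], predictor = vlab[best],
                 beta1 = C[y, best] * sds[vlab[y]] / sds[vlab[best]],
                 r = C[y, best], stringsAsFactors = FALSE)
    })
    edges <- dplyr::bind_rows(pick)
  }
  if (is.null(edges) || nrow(edges) == 0) {
    return(structure(list(predictor_set = sort(labels),
                          predicted = empty_predicted(),
                          flavour = flavour, alpha_sig = alpha_sig),
                     class = "hpp_assignment"))
  }
  pred_of <- stats::setNames(edges$predictor, edges$feature)
  # break cycles in the best-predictor functional graph: within each cycle
  # the smallest label joins the predictor set (loses its edge)
  colour <- stats::setNames(integer(length(labels)), labels) # 0 new 1 path 2 done
  for (start in names(pred_of)) {
    if (colour[start] != 0L) next
    path <- character(0)
    v <- start
    while (!is.na(pred_of[v]) && colour[v] == 0L) {
      colour[v] <- 1L
      path <- c(path, v)
      v <- pred_of[[v]]
      if (colour[v] == 1L) { # cycle closed at v
        cyc <- path[seq.int(match(v, path), length(path))]
        drop <- sort(cyc)[1]
        pred_of <- pred_of[names(pred_of) != drop]
        break
      }
    }
    colour[path] <- 2L
  }
  predicted_names <- names(pred_of)
  predictor_set <- sort(setdiff(labels, predicted_names))
  # topological depth: distance to the predictor set along chains
  depth <- stats::setNames(rep(NA_integer_, length(predicted_names)),
                           predicted_names)
  for (f in predicted_names) {
    d <- 1L
    v <- pred_of[[f]]
    while (v %in% predicted_names) {
      d <- d + 1L
      v <- pred_of[[v]]
      if (d > length(labels)) stop("cycle in predictor graph", call. = FALSE)
    }
    depth[f] <- d
  }
  predicted <- edges[match(predicted_names, edges$feature), ]
  predicted$depth <- unname(depth[predicted$feature])
  predicted <- tibble::as_tibble(predicted[order(predicted$depth,
                                                 predicted$feature), ])
  structure(list(predictor_set = predictor_set, predicted = predicted,
                 flavour = flavour, alpha_sig = alpha_sig),
            class = "hpp_assignment")
}

empty_predicted <- function() {
  tibble::tibble(feature = character(0), predictor = character(0),
                 beta1 = numeric(0), r = numeric(0), depth = integer(0))
}

#' @export
print.hpp_assignment <- function(x, ...) {
  cat("<hpp_assignment> ", length(x$predictor_set), " predictor / ",
      nrow(x$predicted), " predicted features (", x$flavour, ")\n", sep = "")
  invisible(x)
}

#' Draw one hybrid prediction-permutation of a value list
#'
#' Predictor-set values are permuted among the predictor features; each
#' predicted feature is then reconstructed in chain order from its (now
#' permuted) predictor: fold-change flavour
#' \eqn{v_y = \beta_1 v_x}; P-value flavour
#' \eqn{v_y = |r| v_x + (1 - |r|) \hat v} with \eqn{\hat v} a bootstrap
#' draw (with replacement) from the original value list. With no predicted
#' features the HPP draw is exactly a plain permutation of the list.
#'
#' @param assignment An `hpp_assignment`, or `NULL` for a plain
#'   permutation.
#' @param values Named numeric vector of per-feature statistics covering
#'   the assignment's universe.
#' @return Named numeric vector, same names and order as `values`.
#' @export
hpp_permute <- function(assignment, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (is.null(assignment) || nrow(assignment$predicted) == 0) {
    return(stats::setNames(sample(unname(values)), names(values)))
  }
  stopifnot(inherits(assignment, "hpp_assignment"))
  universe <- c(assignment$predictor_set, assignment$predicted$feature)
  if (!setequal(universe, names(values))) {
    stop("assignment universe does not match the value list", call. = FALSE)
  }
  out <- values
  ps <- assignment$predictor_set
  out[ps] <- sample(unname(values[ps]))
  pr <- assignment$predicted
  boot <- sample(unname(values), nrow(pr), replace = TRUE)
  for (d in sort(unique(pr$depth))) { # parents always at smaller depth
    rows <- pr$depth == d
    if (assignment$flavour == "fold_change") {
      out[pr$feature[rows]] <- pr$beta1[rows] * out[pr$predictor[rows]]
    } else {
      ar <- abs(pr$r[rows])
      out[pr$feature[rows]] <- ar * out[pr$predictor[rows]] +
        (1 - ar) * boot[rows]
    }
  }
  out
}

#' Null distribution of the per-quadrant minimal log P
#'
#' Repeats the HPP permutation on both lists `R` times; after each draw the
#' lists are re-ranked and the configured minimal-P search is re-run in
#' every requested quadrant. All quadrants share the same `R` permutations.
#' Without assignments (no expression matrices) the null degenerates to a
#' plain label permutation.
#'
#' @inheritParams rrho
#' @param assignment_a,assignment_b Optional `hpp_assignment` objects for
#'   the two lists.
#' @param R Number of permutations (`>= 20`).
#' @return A tibble with columns `rep`, `quadrant`, `log_p` and
#'   `p = exp(log_p)`; a permutation in which a quadrant has no
#'   enrichment-direction coordinate contributes `log_p = 0`.
#' @export
null_min_logp <- function(a, b, quadrants = QUADRANTS,
                          algorithm = c("ea", "grid"),
                          mode = c("two_sided", "one_sided"),
                          step = NULL, ea = ea_params(),
                          assignment_a = NULL, assignment_b = NULL,
                          flavour = c("fold_change", "pvalue"),
                          R = 100, seed = NULL) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  quadrants <- match.arg(quadrants, QUADRANTS, several.ok = TRUE)
  stopifnot(R >= 20)
  stopifnot(inherits(a, "ranked_list"), inherits(b, "ranked_list"))
  va0 <- stats::setNames(a$values, a$labels)
  vb0 <- stats::setNames(b$values, b$labels)
  nq <- length(quadrants)
  run <- function() {
    lp <- matrix(0, nrow = R, ncol = nq, dimnames = list(NULL, quadrants))
    for (r in seq_len(R)) {
      va <- hpp_permute(assignment_a, va0)
      vb <- hpp_permute(assignment_b, vb0)
      pa <- reranked(names(va), unname(va))
      pb <- reranked(names(vb), unname(vb))
      for (qn in quadrants) {
        bounds <- quadrant_bounds(pa, pb, qn)
        lp[r, qn] <- if (bounds[["max_i"]] < 1L || bounds[["max_j"]] < 1L) {
          0
        } else if (algorithm == "grid") {
          grid_search(pa, pb, qn, step = step, mode = mode)$log_p
        } else {
          ea_search(pa, pb, qn, params = ea, mode = mode)$log_p
        }
      }
    }
    lp
  }
  lp <- with_seed_if(seed, run())
  tibble::tibble(
    rep = rep(seq_len(R), times = nq),
    quadrant = rep(quadrants, each = R),
    log_p = as.vector(lp),
    p = exp(as.vector(lp))
  )
}

#' Method-of-moments beta fit with a Kolmogorov-Smirnov check
#'
#' Fits a Beta distribution to a sample of null minimal P-values by the
#' method of moments: with sample mean m and variance v,
#' \eqn{k = m(1 - m)/v - 1}, \eqn{\alpha = mk}, \eqn{\beta = (1 - m)k}.
#' The fit is accepted when the moments are usable (`v > 0`, `k > 0`), the
#' KS goodness-of-fit P-value is at least 0.05, and no more than 10% of
#' the sample had to be clamped away from 0/1 (values are clamped to
#' `[1e-300, 1 - 1e-12]` before fitting).
#'
#' @param sample Numeric vector of P-values in (0, 1], length `>= 20`.
#' @return A `beta_fit` list: `alpha`, `beta`, `ks_p`, `accepted`,
#'   `clamp_frac`, and the clamped `sample`.
#' @examples
#' fit_beta_mom(stats::runif(1000))  # alpha and beta near 1
#' @export
fit_beta_mom <- function(sample) {
  stopifnot(is.numeric(sample), length(sample) >= 20)
  clamped <- pmin(pmax(sample, 1e-300), 1 - 1e-12)
  clamp_frac <- mean(clamped != sample)
  m <- mean(clamped)
  v <- stats::var(clamped)
  if (!is.finite(v) || v <= 0) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, ks_p = NA_real_,
                          accepted = FALSE, clamp_frac = clamp_frac,
                          sample = clamped), class = "beta_fit"))
  }
  k <- m * (1 - m) / v - 1
  alpha <- m * k
  beta <- (1 - m) * k
  ks_p <- if (k > 0) {
    suppressWarnings(stats::ks.test(clamped, stats::pbeta, alpha,
                                    beta)$p.value)
  } else NA_real_
  accepted <- isTRUE(k > 0 && is.finite(ks_p) && ks_p >= 0.05 &&
                       clamp_frac <= 0.1)
  structure(list(alpha = alpha, beta = beta, ks_p = ks_p,
                 accepted = accepted, clamp_frac = clamp_frac,
                 sample = clamped), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("<beta_fit> alpha = ", signif(x$alpha, 4), ", beta = ",
      signif(x$beta, 4), ", KS p = ", signif(x$ks_p, 3),
      if (x$accepted) " (accepted)\n" else " (rejected)\n", sep = "")
  invisible(x)
}

#' Adjust a minimal P-value against its permutation null
#'
#' The significance threshold t is the 5% quantile of the null: the fitted
#' beta quantile when the fit is accepted, the empirical 5th percentile of
#' the sample otherwise. The adjusted P-value is
#' \eqn{\min(1, 0.05\, p / t)}, computed in log space so minimal P-values
#' far below double underflow survive: at `min_p = t` the adjusted value
#' is exactly 0.05, and under a uniform null (t = 0.05) the adjustment is
#' the identity.
#'
#' @param min_p The observed minimal P-value (in (0, 1]), or its natural
#'   log when `log = TRUE`.
#' @param fit A `beta_fit` from [fit_beta_mom()].
#' @param sample The null sample (used for the empirical fallback);
#'   defaults to the sample stored in `fit`.
#' @param log If `TRUE`, `min_p` is a log P-value and the log adjusted
#'   P-value is returned.
#' @return The adjusted P-value (or its natural log), never above 1
#'   (log 0).
#' @export
adjust_pvalue <- function(min_p, fit, sample = fit$sample, log = FALSE) {
  stopifnot(inherits(fit, "beta_fit"))
  t <- if (fit$accepted) {
    stats::qbeta(0.05, fit$alpha, fit$beta)
  } else {
    # the ECDF inverse proper (type 1): the ceiling(0.05 R)-th smallest
    # null value, which by exchangeability keeps the exceedance rate at or
    # below the nominal level, unlike an interpolated quantile
    stats::quantile(sample, 0.05, names = FALSE, type = 1)
  }
  log_min_p <- if (log) min_p else base::log(min_p)
  stopifnot(all(log_min_p <= 0))
  if (!is.finite(t) || t <= 0) {
    warning("degenerate null sample (5% threshold is 0); ",
            "reporting adjusted P = 1")
    return(if (log) 0 else 1)
  }
  out <- pmin(base::log(0.05) + log_min_p - base::log(t), 0)
  if (log) out else exp(out)
}
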