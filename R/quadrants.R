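QUADRANTS <- c("dd", "uu", "du", "ud")

#' Quadrant conventions
#'
#' Each quadrant pairs one extremity of each list: `dd` = down-regulated in
#' both signatures, `uu` = up in both, `du` = down in a / up in b, `ud` =
#' up in a / down in b. Within a quadrant, coordinates are 1-based prefix
#' lengths counted from each list's own extremity; a genuine signal of the
#' quadrant's direction appears as an *enrichment* of the two oriented
#' prefixes. The expected reported sign is +1 for the correlated quadrants
#' (`dd`, `uu`) and -1 for the anticorrelated ones (`du`, `ud`), matching
#' the global-map convention where anticorrelation shows up as depletion.
#'
#' @param name One of `"dd"`, `"uu"`, `"du"`, `"ud"`.
#' @return A list with `name`, `orient_a`, `orient_b` and `expected_sign`.
#' @export
quadrant_spec <- function(name) {
  name <- match.arg(name, QUADRANTS)
  switch(name,
    dd = list(name = "dd", orient_a = "down", orient_b = "down",
              expected_sign = 1),
    uu = list(name = "uu", orient_a = "up", orient_b = "up",
              expected_sign = 1),
    du = list(name = "du", orient_a = "down", orient_b = "up",
              expected_sign = -1),
    ud = list(name = "ud", orient_a = "up", orient_b = "down",
              expected_sign = -1)
  )
}

#' Quadrant coordinate bounds
#'
#' The zero crossing of each list splits it into a down-regulated head
#' (`split_index` features) and an up-regulated tail. A quadrant's prefix
#' lengths range over the matching halves; a list with no feature on one
#' side yields a zero-extent (empty) quadrant, which is reported, not an
#' error.
#'
#' @param a,b Aligned `ranked_list` objects.
#' @param quadrant Quadrant name.
#' @return Named integer vector `c(max_i, max_j)`.
#' @export
quadrant_bounds <- function(a, b, quadrant) {
  quad <- quadrant_spec(quadrant)
  ext <- function(x, orientation) {
    if (orientation == "down") x$split_index else x$n - x$split_index
  }
  c(max_i = as.integer(ext(a, quad$orient_a)),
    max_j = as.integer(ext(b, quad$orient_b)))
}

#' Enriched label set at a best coordinate
#'
#' The feature set delimited by the minimal-P coordinate: the intersection
#' of the two oriented prefixes, i.e. the features lying between the best
#' coordinate and the quadrant's outer corner (where the two extremities
#' meet). For `dd`/`uu` these are the features most down-/up-regulated in
#' both lists; for `du`/`ud` the features regulated in opposite directions.
#' Its size always equals the overlap count at the best coordinate.
#'
#' @param a,b Aligned `ranked_list` objects.
#' @param quadrant Quadrant name.
#' @param i,j Best-coordinate prefix lengths (quadrant-relative, 1-based).
#' @return Character vector of feature labels.
#' @export
enrichment_set <- function(a, b, quadrant, i, j) {
  quad <- quadrant_spec(quadrant)
  bounds <- quadrant_bounds(a, b, quadrant)
  if (i < 1 || j < 1 || i > bounds[["max_i"]] || j > bounds[["max_j"]]) {
    stop("coordinate (", i, ", ", j, ") outside quadrant '", quadrant,
         "' bounds (", bounds[["max_i"]], ", ", bounds[["max_j"]], ")",
         call. = FALSE)
  }
  intersect(utils::head(oriented_labels(a, quad$orient_a), i),
            utils::head(oriented_labels(b, quad$orient_b), j))
}

empty_quadrant_result <- function(quadrant) {
  list(quadrant = quadrant, found = FALSE, i = NA_integer_, j = NA_integer_,
       max_i = NA_integer_, max_j = NA_integer_, overlap = NA_integer_,
       log_p = 0, sign = quadrant_spec(quadrant)$expected_sign,
       p_adjusted = NA_real_, log_p_adjusted = NA_real_,
       evaluations = 0L, enriched = character(0))
}

#' Rank-rank hypergeometric overlap of two signatures
#'
#' The main entry point: aligns the two ranked signatures, locates the
#' minimal-P coordinate in each requested quadrant with the chosen search
#' (evolutionary algorithm or strided grid), extracts the enriched feature
#' set delimited by that coordinate, optionally computes a
#' permutation-adjusted P-value, and renders the full overlap map for
#' plotting.
#'
#' A quadrant with zero extent (no features on the relevant side of a zero
#' crossing) is reported empty; a quadrant in which no evaluated coordinate
#' shows enrichment of the expected direction reports `log_p = 0` and an
#' empty set rather than an opposite-direction coordinate.
#'
#' @param a,b Ranked signatures: `ranked_list` objects or data frames with
#'   the columns named by `id` and `value`.
#' @param id,value Column names used when `a`/`b` are data frames.
#' @param algorithm `"ea"` (default) or `"grid"`.
#' @param mode `"two_sided"` (default) or `"one_sided"` statistic.
#' @param step Grid stride; default `floor(sqrt(n))` via
#'   [default_grid_step()].
#' @param ea An [ea_params()] list for the evolutionary search.
#' @param quadrants Which quadrants to search (default all four).
#' @param adjust `"none"` (default), `"permutation"` (plain label
#'   permutation null) or `"hpp"` (correlation-aware null; requires
#'   expression matrices).
#' @param permutations Number of null permutations for the adjustment.
#' @param expr_a,expr_b Optional feature-by-sample log-expression matrices
#'   (rownames = feature labels) used by the `"hpp"` adjustment.
#' @param flavour Statistic flavour for HPP prediction: `"fold_change"`
#'   (slope model) or `"pvalue"` (correlation-weighted bootstrap mixture).
#' @param map Render the overlap map (`TRUE` by default; disable inside
#'   tight loops).
#' @param map_resolution Lattice resolution for the rendered map.
#' @param seed Integer seed making the EA search and the permutation null
#'   reproducible; `NULL` uses the ambient RNG stream.
#' @return An object of class `rrho`; see [tidy.rrho()] and
#'   [glance.rrho()].
#' @examples
#' sc <- make_scenario("identical", n = 200, seed = 1)
#' fit <- rrho(sc$a, sc$b, algorithm = "grid", step = 5)
#' tidy(fit)
#' @export
rrho <- function(a, b, id = "id", value = "value",
                 algorithm = c("ea", "grid"),
                 mode = c("two_sided", "one_sided"),
                 step = NULL, ea = ea_params(),
                 quadrants = QUADRANTS,
                 adjust = c("none", "permutation", "hpp"),
                 permutations = 100,
                 expr_a = NULL, expr_b = NULL,
                 flavour = c("fold_change", "pvalue"),
                 map = TRUE, map_resolution = 200,
                 seed = NULL) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  flavour <- match.arg(flavour)
  quadrants <- match.arg(quadrants, QUADRANTS, several.ok = TRUE)
  if (!inherits(a, "ranked_list")) a <- ranked_list(a, id = id, value = value)
  if (!inherits(b, "ranked_list")) b <- ranked_list(b, id = id, value = value)
  al <- align_ranked_lists(a, b)
  a <- al$a; b <- al$b

  assign_a <- assign_b <- NULL
  if (adjust == "hpp" && (!is.null(expr_a) || !is.null(expr_b))) {
    if (!is.null(expr_a)) {
      assign_a <- select_predictors(expr_a, flavour = flavour)
    }
    if (!is.null(expr_b)) {
      assign_b <- select_predictors(expr_b, flavour = flavour)
    }
  }

  run <- function() {
    quads <- lapply(quadrants, function(qn) {
      search_quadrant(a, b, qn, algorithm = algorithm, mode = mode,
                      step = step, ea = ea)
    })
    names(quads) <- quadrants
    null_samples <- NULL
    if (adjust != "none") {
      null_samples <- null_min_logp(
        a, b, quadrants = quadrants, algorithm = algorithm, mode = mode,
        step = step, ea = ea, assignment_a = assign_a,
        assignment_b = assign_b, flavour = flavour, R = permutations
      )
      # null of the analysis-wide minimal P: per permutation, the minimum
      # across the searched quadrants; shared by all quadrant adjustments
      # so the per-analysis type-I error is controlled at 5%
      min_lp <- tapply(null_samples$log_p, null_samples$rep, min)
      sample_p <- exp(unname(min_lp))
      fit <- fit_beta_mom(sample_p)
      for (qn in quadrants) {
        qr <- quads[[qn]]
        if (!qr$found) next
        la <- adjust_pvalue(qr$log_p, fit, sample_p, log = TRUE)
        quads[[qn]]$log_p_adjusted <- la
        quads[[qn]]$p_adjusted <- exp(la)
        quads[[qn]]$beta_fit <- fit
      }
    }
    list(quads = quads, null = null_samples)
  }
  res <- with_seed_if(seed, run())

  out <- structure(
    list(
      quadrants = res$quads,
      n = a$n,
      a = a, b = b,
      map = if (isTRUE(map)) {
        render_overlap_map(a, b, mode = mode, resolution = map_resolution)
      } else NULL,
      null = res$null,
      config = list(algorithm = algorithm, mode = mode, step = step,
                    ea = ea[setdiff(names(ea), "seed")], adjust = adjust,
                    permutations = if (adjust == "none") NULL else permutations,
                    flavour = if (adjust == "hpp") flavour else NULL,
                    quadrants = quadrants, seed = seed,
                    package_version = as.character(utils::packageVersion("rankoverlap")))
    ),
    class = "rrho"
  )
  out
}

# Search one quadrant and assemble its result record.
search_quadrant <- function(a, b, quadrant, algorithm, mode, step, ea) {
  bounds <- quadrant_bounds(a, b, quadrant)
  if (bounds[["max_i"]] < 1L || bounds[["max_j"]] < 1L) {
    res <- empty_quadrant_result(quadrant)
    res$max_i <- bounds[["max_i"]]; res$max_j <- bounds[["max_j"]]
    return(res)
  }
  best <- if (algorithm == "grid") {
    grid_search(a, b, quadrant, step = step, mode = mode)
  } else {
    ea_search(a, b, quadrant, params = ea, mode = mode)
  }
  quad <- quadrant_spec(quadrant)
  if (!best$found) {
    res <- empty_quadrant_result(quadrant)
    res$max_i <- bounds[["max_i"]]; res$max_j <- bounds[["max_j"]]
    res$evaluations <- best$evaluations
    return(res)
  }
  list(quadrant = quadrant, found = TRUE, i = best$i, j = best$j,
       max_i = bounds[["max_i"]], max_j = bounds[["max_j"]],
       overlap = best$overlap, log_p = best$log_p,
       sign = quad$expected_sign,
       p_adjusted = NA_real_, log_p_adjusted = NA_real_,
       evaluations = best$evaluations,
       enriched = enrichment_set(a, b, quadrant, best$i, best$j))
}

#' @export
print.rrho <- function(x, ...) {
  cat("<rrho> ", x$n, " aligned features; algorithm = ",
      x$config$algorithm, ", mode = ", x$config$mode, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy per-quadrant RRHO results
#'
#' @param x An `rrho` object.
#' @param ... Unused.
#' @return A tibble with one row per searched quadrant: the best coordinate
#'   (`i`, `j`), quadrant extents, overlap count, `log_p` (natural log,
#'   `<= 0`), the reported `sign` (+1 correlated, -1 anticorrelated),
#'   `signed_nlp = sign * -log_p`, the adjusted P (when computed) and the
#'   enriched-set size.
#' @method tidy rrho
#' @export
tidy.rrho <- function(x, ...) {
  purrr::map_dfr(x$quadrants, function(q) {
    tibble::tibble(
      quadrant = q$quadrant, found = q$found,
      i = q$i, j = q$j, max_i = q$max_i, max_j = q$max_j,
      overlap = q$overlap, log_p = q$log_p, sign = q$sign,
      signed_nlp = q$sign * -q$log_p,
      p_adjusted = q$p_adjusted, log_p_adjusted = q$log_p_adjusted,
      n_enriched = length(q$enriched), evaluations = q$evaluations
    )
  })
}

#' One-row RRHO summary
#'
#' @param x An `rrho` object.
#' @param ... Unused.
#' @return A tibble with the universe size, configuration, the most
#'   significant quadrant and its statistics.
#' @method glance rrho
#' @export
glance.rrho <- function(x, ...) {
  td <- tidy(x)
  best <- td[which.min(td$log_p), ]
  tibble::tibble(
    n = x$n, algorithm = x$config$algorithm, mode = x$config$mode,
    adjust = x$config$adjust,
    best_quadrant = if (nrow(best)) best$quadrant else NA_character_,
    min_log_p = if (nrow(best)) best$log_p else NA_real_,
    min_p_adjusted = suppressWarnings(min(td$p_adjusted, na.rm = TRUE)),
    n_enriched_total = sum(td$n_enriched)
  )
}

#' Export RRHO results to a directory
#'
#' Writes one TSV per quadrant (label, rank and value in each list), the
#' overlap-map TSV when a map was rendered, and a JSON summary echoing the
#' configuration and seed needed to regenerate the run.
#'
#' @param x An `rrho` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_rrho <- function(x, dir) {
  stopifnot(inherits(x, "rrho"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rank_a <- seq_len(x$a$n); names(rank_a) <- x$a$labels
  rank_b <- seq_len(x$b$n); names(rank_b) <- x$b$labels
  val_a <- x$a$values; names(val_a) <- x$a$labels
  val_b <- x$b$values; names(val_b) <- x$b$labels
  for (q in x$quadrants) {
    labs <- q$enriched
    tab <- tibble::tibble(
      label = labs,
      rank_a = unname(rank_a[labs]), rank_b = unname(rank_b[labs]),
      value_a = unname(val_a[labs]), value_b = unname(val_b[labs])
    )
    readr::write_tsv(tab, file.path(dir, paste0("quadrant_", q$quadrant,
                                                ".tsv")), progress = FALSE)
  }
  if (!is.null(x$map)) {
    write_overlap_map(x$map, file.path(dir, "overlap_map.tsv"))
  }
  summary <- list(
    n = x$n, config = x$config,
    quadrants = lapply(x$quadrants, function(q) {
      q$enriched <- NULL; q$beta_fit <- NULL; q
    })
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
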