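#' Default grid stride
#'
#' The classic traversal uses the square root of the list length as its
#' stride: `floor(sqrt(n))`, e.g. 141 for a 20,000-feature list. The stride
#' trades speed for accuracy — detected coordinates are only resolved to
#' within one stride.
#'
#' @param n List length.
#' @return Integer stride, at least 1.
#' @export
default_grid_step <- function(n) {
  max(1L, as.integer(floor(sqrt(n))))
}

# Pick the better of two candidate bests: lower log_p, ties by smaller i
# then smaller j.
better_best <- function(cur, cand) {
  if (is.null(cand)) return(cur)
  if (is.null(cur)) return(cand)
  if (cand$log_p < cur$log_p ||
      (cand$log_p == cur$log_p &&
       (cand$i < cur$i || (cand$i == cur$i && cand$j < cur$j)))) cand else cur
}

# Best quadrant-consistent cell of an evaluated batch, or NULL.
best_of_cells <- function(cells) {
  ok <- which(cells$sign > 0)
  if (!length(ok)) return(NULL)
  lp <- cells$log_p[ok]
  cand <- ok[lp == min(lp)]
  if (length(cand) > 1) {
    cand <- cand[order(cells$i[cand], cells$j[cand])]
  }
  k <- cand[1]
  list(i = cells$i[k], j = cells$j[k], overlap = cells$overlap[k],
       log_p = cells$log_p[k])
}

#' Grid search for the minimal-P coordinate of a quadrant
#'
#' Evaluates the signed statistic on the strided lattice
#' `{step, 2 step, ...}` on each axis (always including the quadrant's far
#' corner) and returns the coordinate with the lowest log P among cells
#' whose oriented statistic is an enrichment — the direction the quadrant
#' encodes. Ties go to the smaller `i`, then smaller `j`. The lattice is
#' evaluated in column chunks so only the running best is kept, never the
#' full map. With `step = 1` the search is an exhaustive enumeration of the
#' quadrant.
#'
#' @param a,b Aligned `ranked_list` objects.
#' @param quadrant Quadrant name (`"dd"`, `"uu"`, `"du"`, `"ud"`).
#' @param step Stride; default [default_grid_step()] of the universe size.
#' @param mode `"two_sided"` (default) or `"one_sided"`.
#' @return A list: `found`, best `i`, `j`, `overlap`, `log_p`
#'   (natural log, `<= 0`) and `evaluations`.
#' @export
grid_search <- function(a, b, quadrant = "dd", step = NULL,
                        mode = c("two_sided", "one_sided")) {
  mode <- match.arg(mode)
  quad <- quadrant_spec(quadrant)
  ctx <- pair_context(a, b)
  bounds <- quadrant_bounds(a, b, quadrant)
  max_i <- bounds[["max_i"]]; max_j <- bounds[["max_j"]]
  if (max_i < 1L || max_j < 1L) {
    stop("quadrant '", quadrant, "' is empty (extent ", max_i, " x ", max_j,
         "); nothing to search", call. = FALSE)
  }
  if (is.null(step)) step <- default_grid_step(ctx$n)
  step <- as.integer(step)
  stopifnot(step >= 1L)
  is_ <- lattice_axis(max_i, step)
  js <- lattice_axis(max_j, step)
  cur <- quadrant_cursor(ctx, quad)
  best <- NULL
  evals <- 0L
  # chunk i-columns so at most ~2^16 cells are materialised at once
  cols_per_chunk <- max(1L, 65536L %/% length(js))
  for (start in seq.int(1L, length(is_), by = cols_per_chunk)) {
    ii <- is_[start:min(length(is_), start + cols_per_chunk - 1L)]
    grid <- expand.grid(j = js, i = ii, KEEP.OUT.ATTRS = FALSE)
    cells <- eval_cells(cur, grid$i, grid$j, ctx$n, mode)
    evals <- evals + length(cells$i)
    best <- better_best(best, best_of_cells(cells))
  }
  if (is.null(best)) {
    return(list(found = FALSE, i = NA_integer_, j = NA_integer_,
                overlap = NA_integer_, log_p = 0, evaluations = evals))
  }
  c(list(found = TRUE), best, list(evaluations = evals))
}

#' Evolutionary-search parameters
#'
#' Defaults follow the method's stated behaviour: up to 200 generations
#' over a population of `500 + floor(sqrt(n))` coordinates initialised
#' uniformly on the quadrant diagonal, an elite fifth retained each
#' generation, and mutation by signed geometric offsets with a scale of
#' one twentieth of the quadrant extent. `population` and `mutation_scale`
#' left `NULL` are resolved against the instance at search time.
#'
#' @param generations Maximum number of generations (`>= 1`).
#' @param population Population size (`>= 4`); `NULL` for the default.
#' @param elite_fraction Fraction of the population kept as parents,
#'   in (0, 1).
#' @param mutation_scale Mean absolute geometric mutation offset; `NULL`
#'   for extent / 20.
#' @param seed Optional RNG seed for a self-contained deterministic search.
#' @return A list of class `ea_params`.
#' @export
ea_params <- function(generations = 200, population = NULL,
                      elite_fraction = 0.2, mutation_scale = NULL,
                      seed = NULL) {
  stopifnot(generations >= 1,
            is.null(population) || population >= 4,
            elite_fraction > 0, elite_fraction < 1,
            is.null(mutation_scale) || mutation_scale > 0)
  structure(list(generations = as.integer(generations),
                 population = population,
                 elite_fraction = elite_fraction,
                 mutation_scale = mutation_scale,
                 seed = seed),
            class = "ea_params")
}

#' Evolutionary search for the minimal-P coordinate of a quadrant
#'
#' Treats coordinates as individuals under selective pressure. The initial
#' population is spaced uniformly on the quadrant diagonal — so the search
#' starts at least as strong as a diagonal grid pass and, by elitism, can
#' never end worse than its own initialisation. Each generation the elite
#' (lowest log P with quadrant-consistent enrichment; inconsistent
#' coordinates get infinite fitness but stay in the population) is
#' retained; offspring are created by mating two elite parents (either one
#' parent contributes `i` and the other `j`, or the child takes the rounded
#' midpoint, chosen uniformly) and mutating both components by signed
#' geometric offsets clipped to the quadrant. The search stops when the
#' elite coordinate set is unchanged between generations or the generation
#' cap is reached, and returns the best coordinate ever evaluated.
#'
#' @inheritParams grid_search
#' @param params An [ea_params()] list.
#' @return As [grid_search()].
#' @export
ea_search <- function(a, b, quadrant = "dd", params = ea_params(),
                      mode = c("two_sided", "one_sided")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "ea_params"))
  with_seed_if(params$seed, ea_search_impl(a, b, quadrant, params, mode))
}

ea_search_impl <- function(a, b, quadrant, params, mode) {
  quad <- quadrant_spec(quadrant)
  ctx <- pair_context(a, b)
  bounds <- quadrant_bounds(a, b, quadrant)
  max_i <- bounds[["max_i"]]; max_j <- bounds[["max_j"]]
  if (max_i < 1L || max_j < 1L) {
    stop("quadrant '", quadrant, "' is empty (extent ", max_i, " x ", max_j,
         "); nothing to search", call. = FALSE)
  }
  p <- params$population
  if (is.null(p)) p <- 500L + as.integer(floor(sqrt(ctx$n)))
  p <- as.integer(p)
  scale <- params$mutation_scale
  if (is.null(scale)) scale <- max(1, max(max_i, max_j) / 20)
  geom_prob <- 1 / (1 + scale)
  elite_n <- max(2L, as.integer(ceiling(params$elite_fraction * p)))

  cur <- quadrant_cursor(ctx, quad)
  clip <- function(x, hi) pmin.int(pmax.int(as.integer(round(x)), 1L), hi)

  # diagonal initialisation
  ks <- seq_len(p)
  pop_i <- clip(ks * max_i / p, max_i)
  pop_j <- clip(ks * max_j / p, max_j)
  cells <- eval_cells(cur, pop_i, pop_j, ctx$n, mode)
  fitness <- ifelse(cells$sign > 0, cells$log_p, Inf)
  evals <- p
  best <- best_of_cells(cells)
  diag_best <- best

  prev_elite <- NULL
  for (gen in seq_len(params$generations)) {
    ord <- order(fitness, cells$i, cells$j, method = "radix")
    elite <- ord[seq_len(elite_n)]
    elite_key <- paste(cells$i[elite], cells$j[elite])
    if (!is.null(prev_elite) && setequal(elite_key, prev_elite)) break
    prev_elite <- elite_key

    m <- p - elite_n
    p1 <- elite[sample.int(elite_n, m, replace = TRUE)]
    p2 <- elite[sample.int(elite_n, m, replace = TRUE)]
    mid <- stats::runif(m) < 0.5
    off_i <- ifelse(mid, round((cells$i[p1] + cells$i[p2]) / 2), cells$i[p1])
    off_j <- ifelse(mid, round((cells$j[p1] + cells$j[p2]) / 2), cells$j[p2])
    off_i <- off_i + sample(c(-1L, 1L), m, replace = TRUE) *
      stats::rgeom(m, geom_prob)
    off_j <- off_j + sample(c(-1L, 1L), m, replace = TRUE) *
      stats::rgeom(m, geom_prob)
    off_i <- clip(off_i, max_i)
    off_j <- clip(off_j, max_j)

    off_cells <- eval_cells(cur, off_i, off_j, ctx$n, mode)
    evals <- evals + m
    best <- better_best(best, best_of_cells(off_cells))

    cells <- list(i = c(cells$i[elite], off_cells$i),
                  j = c(cells$j[elite], off_cells$j),
                  overlap = c(cells$overlap[elite], off_cells$overlap),
                  log_p = c(cells$log_p[elite], off_cells$log_p),
                  sign = c(cells$sign[elite], off_cells$sign))
    fitness <- ifelse(cells$sign > 0, cells$log_p, Inf)
  }

  if (is.null(best)) {
    return(list(found = FALSE, i = NA_integer_, j = NA_integer_,
                overlap = NA_integer_, log_p = 0, evaluations = evals))
  }
  # elitism guarantee: never worse than the diagonal initialisation
  stopifnot(is.null(diag_best) || best$log_p <= diag_best$log_p)
  c(list(found = TRUE), best, list(evaluations = evals))
}
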