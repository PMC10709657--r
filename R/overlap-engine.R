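#' Incremental prefix-intersection cursor
#'
#' The counting engine behind every overlap-map cell. Both ranked lists are
#' encoded as permutations of a fixed global feature indexing; the cursor
#' keeps one 64-bit bitset per list marking the features inside the current
#' prefix, plus the running intersection count. Moving from one coordinate
#' to a nearby one touches only the bits of features entering or leaving
#' each prefix, so a batch of coordinates visited in sorted order costs far
#' fewer updates than recomputing each intersection from scratch.
#'
#' @param a_order,b_order Integer permutations of `1:n`: the global feature
#'   index at each rank of the oriented lists.
#' @return An `overlap_cursor` object positioned at (0, 0).
#' @examples
#' cur <- overlap_cursor(c(1L, 2L, 3L, 4L, 5L), c(3L, 5L, 1L, 2L, 4L))
#' cursor_move(cur, 3, 2) # |{1,2,3} n {3,5}| = 1
#' @export
overlap_cursor <- function(a_order, b_order) {
  ptr <- .cursor_new(as.integer(a_order), as.integer(b_order))
  structure(list(ptr = ptr, n = length(a_order)), class = "overlap_cursor")
}

#' @rdname overlap_cursor
#' @param cursor An `overlap_cursor`.
#' @param i,j Target prefix lengths, `0 <= i, j <= n`; shrinking a prefix
#'   (moving backwards) is supported.
#' @return `cursor_move()`: the intersection count at `(i, j)`.
#' @export
cursor_move <- function(cursor, i, j) {
  stopifnot(inherits(cursor, "overlap_cursor"))
  .cursor_move(cursor$ptr, as.integer(i), as.integer(j))
}

#' @rdname overlap_cursor
#' @return `cursor_state()`: named vector with the current `i`, `j`, the
#'   incrementally maintained `count`, and the `popcount` recomputed from
#'   the bitset words (the two must always agree).
#' @export
cursor_state <- function(cursor) {
  stopifnot(inherits(cursor, "overlap_cursor"))
  .cursor_state(cursor$ptr)
}

# Counts for many coordinates; visits them sorted by (i, j) to bound bit
# updates, returns counts in the input order.
cursor_counts <- function(cursor, i, j) {
  ord <- order(i, j, method = "radix")
  out <- numeric(length(i))
  out[ord] <- .cursor_counts(cursor$ptr, as.integer(i[ord]),
                             as.integer(j[ord]))
  out
}

# Shared context for an aligned pair: global indexing is the ascending rank
# order of list a, so a's down-oriented permutation is the identity.
pair_context <- function(a, b) {
  stopifnot(inherits(a, "ranked_list"), inherits(b, "ranked_list"))
  if (a$n != b$n || !setequal(a$labels, b$labels)) {
    stop("lists are not aligned; call align_ranked_lists() first",
         call. = FALSE)
  }
  pos <- seq_len(a$n)
  names(pos) <- a$labels
  list(a = a, b = b, n = a$n, pos = pos)
}

quadrant_cursor <- function(ctx, quad) {
  a_ord <- oriented_index(ctx$a, quad$orient_a, ctx$pos)
  b_ord <- oriented_index(ctx$b, quad$orient_b, ctx$pos)
  overlap_cursor(a_ord, b_ord)
}

# Evaluate signed log P at the given oriented coordinates using an existing
# cursor. Hot path: returns a plain list of vectors, not a tibble.
eval_cells <- function(cursor, i, j, n, mode) {
  overlap <- cursor_counts(cursor, i, j)
  slp <- signed_log_pvalue(overlap, i, j, n, mode = mode)
  list(i = as.integer(i), j = as.integer(j), overlap = as.integer(overlap),
       log_p = slp$log_p, sign = slp$sign)
}

#' Signed log P-values at arbitrary quadrant coordinates
#'
#' Orients both lists according to the quadrant, counts the prefix
#' intersections with the bitset cursor (coordinates are visited sorted by
#' `(i, j)` to minimise cursor movement), and evaluates the signed
#' hypergeometric statistic at each coordinate against the full aligned
#' universe.
#'
#' @param a,b Aligned `ranked_list` objects.
#' @param quadrant Quadrant name: `"dd"`, `"uu"`, `"du"` or `"ud"`.
#' @param coords Data frame with integer columns `i` and `j`: prefix
#'   lengths counted from each list's quadrant extremity (1-based).
#' @param mode `"two_sided"` (default) or `"one_sided"`.
#' @return A tibble with columns `i`, `j`, `overlap`, `log_p`, `sign`,
#'   one row per input coordinate, in input order.
#' @export
evaluate_coordinates <- function(a, b, quadrant = "dd", coords,
                                 mode = c("two_sided", "one_sided")) {
  mode <- match.arg(mode)
  quad <- quadrant_spec(quadrant)
  ctx <- pair_context(a, b)
  bounds <- quadrant_bounds(a, b, quadrant)
  i <- as.integer(coords$i)
  j <- as.integer(coords$j)
  if (any(i < 1L) || any(j < 1L) || any(i > bounds[["max_i"]]) ||
      any(j > bounds[["max_j"]])) {
    stop("coordinates outside quadrant '", quadrant, "' bounds (",
         bounds[["max_i"]], ", ", bounds[["max_j"]], ")", call. = FALSE)
  }
  cur <- quadrant_cursor(ctx, quad)
  tibble::as_tibble(eval_cells(cur, i, j, ctx$n, mode))
}

lattice_axis <- function(extent, stride) {
  if (extent < 1L) return(integer(0))
  stride <- max(1L, as.integer(stride))
  sort(unique(c(seq.int(stride, extent, by = stride), extent)))
}

#' Render the full overlap map on a downsampled lattice
#'
#' Evaluates the signed statistic on an evenly spaced lattice spanning the
#' whole map in the global frame: both axes run from the most
#' down-regulated feature to the most up-regulated one and a cell `(i, j)`
#' compares the first `i` features of list a with the first `j` of list b.
#' In this frame, correlated signatures light up the dd/uu diagonal with
#' positive sign while anticorrelated ones produce depleted (negatively
#' signed) cells in the du/ud quadrants. Rendering is decoupled from the
#' minimal-P search: the lattice resolution only affects the picture, never
#' the reported coordinates, and cell values at shared coordinates are
#' identical across resolutions.
#'
#' @param a,b Aligned `ranked_list` objects.
#' @param mode `"two_sided"` (default) or `"one_sided"`.
#' @param resolution Maximum number of evaluated prefix lengths per axis
#'   (`>= 2`); the final coordinate `n` is always included.
#' @return An `overlap_map` object: tibble `cells` (`i`, `j`, `overlap`,
#'   `log_p`, `sign`), the evaluated `coords_a`/`coords_b`, the zero
#'   crossings `split_a`/`split_b`, `n` and `mode`.
#' @export
render_overlap_map <- function(a, b, mode = c("two_sided", "one_sided"),
                               resolution = 200) {
  mode <- match.arg(mode)
  stopifnot(resolution >= 2)
  ctx <- pair_context(a, b)
  stride <- max(1L, ctx$n %/% as.integer(resolution))
  coords_a <- lattice_axis(ctx$n, stride)
  coords_b <- lattice_axis(ctx$n, stride)
  grid <- expand.grid(i = coords_a, j = coords_b, KEEP.OUT.ATTRS = FALSE)
  cur <- overlap_cursor(oriented_index(ctx$a, "down", ctx$pos),
                        oriented_index(ctx$b, "down", ctx$pos))
  cells <- tibble::as_tibble(eval_cells(cur, grid$i, grid$j, ctx$n, mode))
  structure(
    list(cells = cells, coords_a = coords_a, coords_b = coords_b,
         split_a = a$split_index, split_b = b$split_index,
         n = ctx$n, mode = mode),
    class = "overlap_map"
  )
}

#' @export
print.overlap_map <- function(x, ...) {
  cat("<overlap_map> ", length(x$coords_a), "x", length(x$coords_b),
      " lattice over n = ", x$n, " features (", x$mode, ")\n", sep = "")
  cat("splits at (", x$split_a, ", ", x$split_b, "); strongest cell: ",
      sep = "")
  best <- x$cells[which.min(x$cells$log_p), ]
  cat("(", best$i, ", ", best$j, ") signed -log P = ",
      round(-best$log_p * best$sign, 2), "\n", sep = "")
  invisible(x)
}

#' Tidy an overlap map into its cell tibble
#'
#' @param x An `overlap_map`.
#' @param ... Unused.
#' @return The cell tibble with an added `signed_nlp` column,
#'   `sign * (-log_p)`: positive for enriched (correlated) cells, negative
#'   for depleted (anticorrelated) ones.
#' @method tidy overlap_map
#' @export
tidy.overlap_map <- function(x, ...) {
  dplyr::mutate(x$cells, signed_nlp = .data$sign * (-.data$log_p))
}

#' Export an overlap map as a TSV matrix
#'
#' Rows are list-a prefix lengths, columns list-b prefix lengths; each cell
#' holds the signed negative natural-log P (`sign * -log_p`).
#'
#' @param map An `overlap_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_overlap_map <- function(map, path) {
  stopifnot(inherits(map, "overlap_map"))
  wide <- tidyr::pivot_wider(
    dplyr::select(tidy(map), "i", "j", "signed_nlp"),
    names_from = "j", values_from = "signed_nlp"
  )
  names(wide)[1] <- "i\\j"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
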