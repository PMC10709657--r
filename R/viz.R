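#' Plot an overlap map
#'
#' Heatmap of the signed strength `sign * -log(P)` of every evaluated
#' cell: warm colours mark enriched (correlated) regions, cool colours
#' depleted (anticorrelated) ones. Dashed lines mark the zero crossing of
#' each list, delimiting the four quadrants.
#'
#' @param object An `overlap_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_map
#' @export
autoplot.overlap_map <- function(object, ...) {
  cells <- tidy(object)
  lim <- max(abs(cells$signed_nlp))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$i, y = .data$j,
                                      fill = .data$signed_nlp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "grey95", high = "#b2182b",
      limits = c(-lim, lim), name = expression("signed" ~ -log(P))
    ) +
    ggplot2::geom_vline(xintercept = object$split_a + 0.5,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$split_b + 0.5,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::labs(x = "list a rank (down → up)",
                  y = "list b rank (down → up)") +
    ggplot2::theme_minimal()
}

#' Plot an RRHO result
#'
#' The overlap-map heatmap annotated per quadrant with the maximal
#' `-log(P)` (and the adjusted P when computed). Annotations are
#' suppressed for quadrants failing the display threshold, so a map of two
#' random lists carries no quadrant labels.
#'
#' @param object An `rrho` object (run with `map = TRUE`).
#' @param display_threshold Minimal `-log(P)` (adjusted when available)
#'   for a quadrant annotation to be shown; defaults to
#'   `-log(0.05)` (about 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rrho
#' @export
autoplot.rrho <- function(object, display_threshold = -log(0.05), ...) {
  if (is.null(object$map)) {
    object$map <- render_overlap_map(object$a, object$b,
                                     mode = object$config$mode)
  }
  p <- autoplot(object$map)
  n <- object$n
  sa <- object$a$split_index
  sb <- object$b$split_index
  centre <- function(orientation, split, n) {
    if (orientation == "down") split / 2 else split + (n - split) / 2
  }
  ann <- purrr::map_dfr(object$quadrants, function(q) {
    if (!q$found) return(NULL)
    nlp_display <- if (!is.na(q$log_p_adjusted)) {
      -q$log_p_adjusted
    } else {
      -q$log_p
    }
    if (nlp_display < display_threshold) return(NULL)
    quad <- quadrant_spec(q$quadrant)
    # the down/up halves of the axes in the global frame
    half_a <- if (quad$orient_a == "down") c(0, sa) else c(sa, n)
    half_b <- if (quad$orient_b == "down") c(0, sb) else c(sb, n)
    lab <- paste0(q$quadrant, ": -log P = ", sprintf("%.1f", -q$log_p))
    if (!is.na(q$p_adjusted)) {
      lab <- paste0(lab, "\nP adj = ", signif(q$p_adjusted, 2))
    }
    tibble::tibble(x = mean(half_a), y = mean(half_b), label = lab)
  })
  if (nrow(ann)) {
    p <- p + ggplot2::geom_label(
      data = ann,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      inherit.aes = FALSE, size = 3, alpha = 0.85
    )
  }
  p
}
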