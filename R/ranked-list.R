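#' Build a ranked signature list from a data frame
#'
#' A `ranked_list` is the normal form both compared signatures are brought
#' into before any overlap computation: a set of uniquely labelled features,
#' each carrying one real-valued ranked statistic (log2 fold change, signed
#' P-value, slope, ...), sorted ascending so the most down-regulated feature
#' comes first. The position of the zero crossing (the number of strictly
#' negative values) anchors the four direction-of-regulation quadrants.
#'
#' Ties in the statistic are broken by the lexicographic order of the labels
#' so that ranks are deterministic across runs and platforms. Values exactly
#' zero count as up-regulated.
#'
#' @param data A data frame with one row per feature.
#' @param id Name of the column holding unique feature identifiers.
#' @param value Name of the column holding the ranked statistic.
#' @return An object of class `ranked_list` with elements `labels` and
#'   `values` (both in ascending rank order), `n`, and `split_index` (the
#'   count of strictly negative values).
#' @examples
#' sig <- data.frame(id = c("g1", "g2", "g3"), value = c(-2, 0.5, -0.1))
#' rl <- ranked_list(sig)
#' rl$labels      # "g1" "g3" "g2"
#' rl$split_index # 2
#' @export
ranked_list <- function(data, id = "id", value = "value") {
  data <- as.data.frame(data)
  for (col in c(id, value)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in input (columns: ",
           paste(names(data), collapse = ", "), ")", call. = FALSE)
    }
  }
  labels <- as.character(data[[id]])
  values <- data[[value]]
  if (!is.numeric(values)) {
    bad <- suppressWarnings(which(is.na(as.numeric(as.character(values)))))
    stop("value column '", value, "' is not numeric (first offending row: ",
         if (length(bad)) bad[1] else 1, ")", call. = FALSE)
  }
  values <- as.double(values)
  if (length(labels) < 2L) {
    stop("a ranked list needs at least 2 features, got ", length(labels),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("non-finite ranked statistic at row(s): ",
         paste(utils::head(which(!is.finite(values)), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dups <- unique(labels[duplicated(labels)])
    stop("duplicate feature labels: ",
         paste(utils::head(dups, 5), collapse = ", "),
         if (length(dups) > 5) " ..." else "", call. = FALSE)
  }
  ord <- order(values, labels, method = "radix")
  new_ranked_list(labels[ord], values[ord])
}

new_ranked_list <- function(labels_sorted, values_sorted) {
  structure(
    list(
      labels = labels_sorted,
      values = values_sorted,
      n = length(labels_sorted),
      split_index = sum(values_sorted < 0)
    ),
    class = "ranked_list"
  )
}

#' Read a ranked signature list from a TSV file
#'
#' Expects a tab-separated file with a header row containing the identifier
#' and statistic columns (defaults `id` and `value`). Gzipped files are
#' accepted. Validation and ordering rules are those of [ranked_list()].
#'
#' @param path Path to the TSV (optionally gzipped).
#' @inheritParams ranked_list
#' @return A `ranked_list`.
#' @export
read_ranked_list <- function(path, id = "id", value = "value") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  ranked_list(tab, id = id, value = value)
}

#' Restrict two ranked lists to their common label universe
#'
#' RRHO assumes both signatures rank the same features. Lists with
#' non-identical label sets are intersected (a message reports the dropped
#' counts); identical label sets are returned unchanged. The retained
#' universe does not depend on argument order.
#'
#' @param a,b `ranked_list` objects.
#' @return A list with elements `a` and `b`, both restricted to the common
#'   labels and re-sorted.
#' @export
align_ranked_lists <- function(a, b) {
  stopifnot(inherits(a, "ranked_list"), inherits(b, "ranked_list"))
  common <- intersect(a$labels, b$labels)
  if (length(common) == 0L) {
    stop("the two ranked lists share no feature labels", call. = FALSE)
  }
  if (length(common) == a$n && length(common) == b$n) {
    return(list(a = a, b = b))
  }
  message("aligning ranked lists: dropped ", a$n - length(common),
          " feature(s) from list a and ", b$n - length(common),
          " from list b; ", length(common), " in common")
  restrict <- function(x) {
    keep <- x$labels %in% common
    new_ranked_list(x$labels[keep], x$values[keep])
  }
  list(a = restrict(a), b = restrict(b))
}

#' Feature order from one extremity of a ranked list
#'
#' Returns the labels ordered so that a prefix of length `i` is "the top
#' `i` features" seen from the chosen extremity: `orientation = "down"`
#' starts at the most down-regulated feature, `"up"` at the most
#' up-regulated. The up order is exactly the reverse of the down order.
#'
#' @param x A `ranked_list`.
#' @param orientation `"down"` or `"up"`.
#' @return Character vector of labels.
#' @export
oriented_labels <- function(x, orientation = c("down", "up")) {
  stopifnot(inherits(x, "ranked_list"))
  orientation <- match.arg(orientation)
  if (orientation == "down") x$labels else rev(x$labels)
}

# Integer positions (into the aligned global indexing 1..n) rather than
# labels; used to feed the bitset cursor.
oriented_index <- function(x, orientation, universe_pos) {
  idx <- universe_pos[oriented_labels(x, orientation)]
  as.integer(idx)
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list> ", x$n, " features, split_index = ", x$split_index,
      " (", x$split_index, " down / ", x$n - x$split_index, " up)\n", sep = "")
  show <- utils::head(tibble::tibble(label = x$labels, value = x$values), 5)
  print(show)
  invisible(x)
}

#' @export
as.data.frame.ranked_list <- function(x, ...) {
  data.frame(label = x$labels, value = x$values, rank = seq_len(x$n),
             stringsAsFactors = FALSE)
}

#' Tidy a ranked list into a tibble
#'
#' @param x A `ranked_list`.
#' @param ... Unused.
#' @return A tibble with columns `label`, `value`, `rank` (ascending,
#'   most down-regulated first) and `direction` (`"down"`/`"up"`).
#' @method tidy ranked_list
#' @export
tidy.ranked_list <- function(x, ...) {
  tibble::tibble(
    label = x$labels,
    value = x$values,
    rank = seq_len(x$n),
    direction = ifelse(seq_len(x$n) <= x$split_index, "down", "up")
  )
}

# Rebuild a ranked list from (labels, new values), e.g. after a permutation.
reranked <- function(labels, values) {
  ord <- order(values, labels, method = "radix")
  new_ranked_list(labels[ord], values[ord])
}
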