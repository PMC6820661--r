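#' Drop-plot table and figure
#'
#' The drop plot shows the expression map as a grid: colour encodes the
#' group-median ABC on a log10 scale (monotone colour mapping), and dot area
#' is proportional to the median percentage of positive cells, so a
#' zero-positivity cell has no visible dot.
#'
#' `drop_plot_data()` returns the exact plotted table — the expression map
#' restricted to (and ordered by) the requested subset and marker orders.
#'
#' @param map An [expression_map][aggregate_donors].
#' @param subsets,markers Display orders; default to every subset/marker in
#'   the map. Unknown ids raise a configuration error.
#' @return `plot_drop()` a ggplot; `drop_plot_data()` a tibble.
#' @export
plot_drop <- function(map, subsets = NULL, markers = NULL) {
  dat <- drop_plot_data(map, subsets = subsets, markers = markers)
  ggplot(dat, aes(x = .data$subset, y = .data$marker)) +
    geom_point(aes(size = .data$pct_pos, colour = .data$abc)) +
    scale_size_area(max_size = 6, limits = c(0, 100)) +
    scale_colour_viridis_c(trans = "log10") +
    labs(colour = "median ABC", size = "% positive") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_drop
#' @export
drop_plot_data <- function(map, subsets = NULL, markers = NULL) {
  stopifnot(inherits(map, "expression_map"))
  subsets <- subsets %||% map$subsets
  markers <- markers %||% map$markers
  unknown <- c(setdiff(subsets, map$subsets), setdiff(markers, map$markers))
  if (length(unknown)) {
    abort(paste("Unknown subset/marker id(s):", paste(unknown, collapse = ", ")),
          class = "flowabc_config_error")
  }
  map$long |>
    filter(.data$subset %in% subsets, .data$marker %in% markers) |>
    mutate(subset = factor(.data$subset, levels = subsets),
           marker = factor(.data$marker, levels = rev(markers))) |>
    arrange(.data$marker, .data$subset)
}

#' @method autoplot expression_map
#' @export
autoplot.expression_map <- function(object, ...) plot_drop(object, ...)

#' Maturation profile series
#'
#' Per-marker series of group-median ABC over a user-supplied subset order
#' (e.g. a differentiation sequence). The series follows the given order
#' exactly — it is never re-sorted — and carries the median percent positive
#' for dot sizing.
#'
#' @param map An [expression_map][aggregate_donors].
#' @param subsets Ordered subset sequence (must exist in the map).
#' @param markers Markers to profile; defaults to all.
#' @return `maturation_profile()` a tibble with `marker`, `subset` (ordered
#'   factor), `position`, `abc`, `pct_pos`; `plot_maturation()` the
#'   corresponding line/dot ggplot.
#' @export
maturation_profile <- function(map, subsets, markers = NULL) {
  stopifnot(inherits(map, "expression_map"))
  markers <- markers %||% map$markers
  unknown <- c(setdiff(subsets, map$subsets), setdiff(markers, map$markers))
  if (length(unknown)) {
    abort(paste("Unknown subset/marker id(s):", paste(unknown, collapse = ", ")),
          class = "flowabc_config_error")
  }
  tidyr::expand_grid(marker = markers, subset = subsets) |>
    mutate(position = match(.data$subset, subsets)) |>
    left_join(map$long |> select("marker", "subset", "abc", "pct_pos"),
              by = c("marker", "subset")) |>
    mutate(subset = factor(.data$subset, levels = subsets)) |>
    arrange(.data$marker, .data$position)
}

#' @rdname maturation_profile
#' @export
plot_maturation <- function(map, subsets, markers = NULL) {
  dat <- maturation_profile(map, subsets, markers)
  ggplot(dat, aes(x = .data$position, y = .data$abc,
                  colour = .data$marker, group = .data$marker)) +
    geom_line() +
    geom_point(aes(size = .data$pct_pos)) +
    scale_size_area(max_size = 5, limits = c(0, 100)) +
    scale_y_log10() +
    scale_x_continuous(breaks = seq_along(subsets), labels = subsets) +
    labs(x = NULL, y = "median ABC", size = "% positive", colour = "marker") +
    theme_minimal()
}

#' Ordered expression and positivity profile of one subset
#'
#' Markers of one subset ordered by rising value, the view in which the
#' positivity sigmoid and the expression turning point live.
#'
#' @param map An [expression_map][aggregate_donors].
#' @param subset Subset id.
#' @param what `"abc"` or `"pct_pos"`.
#' @return A ggplot of the ordered per-marker values.
#' @export
plot_ordered_profile <- function(map, subset, what = c("abc", "pct_pos")) {
  what <- match.arg(what)
  stopifnot(inherits(map, "expression_map"))
  dat <- map$long |>
    filter(.data$subset == .env$subset) |>
    arrange(.data[[what]], .data$marker) |>
    mutate(rank = dplyr::row_number())
  p <- ggplot(dat, aes(x = .data$rank, y = .data[[what]])) +
    geom_point(aes(colour = .data$abc)) +
    scale_colour_viridis_c(trans = "log10") +
    labs(x = "marker rank", colour = "median ABC",
         y = if (what == "abc") "median ABC" else "% positive") +
    theme_minimal()
  if (what == "abc") p + scale_y_log10() else p
}
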