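#' Aggregate donor-level records into an expression map
#'
#' Collapses per-(subset, marker, donor) statistics into group centrality
#' values per (marker, subset) cell: the median across donors (the map value),
#' the mean (retained alongside), the number of contributing donors and the
#' cross-donor CV. Cells with no donor record are simply absent (missing),
#' never zero.
#'
#' @param records A data frame of donor-level records with columns `marker`,
#'   `subset`, `donor`, `median_abc` and `pct_positive` (as produced by
#'   [subset_statistics()] with a calibration curve).
#' @return An `expression_map` object; `tidy()` it for the long table, or use
#'   [expr_matrix()] for the marker-by-subset matrices.
#' @export
aggregate_donors <- function(records) {
  records <- as_tibble(records)
  need <- c("marker", "subset", "donor", "median_abc", "pct_positive")
  if (!all(need %in% names(records))) {
    abort(paste("`records` must have columns", paste(need, collapse = ", ")),
          class = "flowabc_invalid_argument")
  }
  long <- records |>
    group_by(.data$marker, .data$subset) |>
    summarise(
      abc = median(.data$median_abc),
      abc_mean = mean(.data$median_abc),
      pct_pos = median(.data$pct_positive),
      n_donors = dplyr::n_distinct(.data$donor),
      cv_donor = cv_of(.data$median_abc),
      .groups = "drop"
    )
  structure(
    list(long = long,
         markers = sort(unique(long$marker)),
         subsets = sort(unique(long$subset))),
    class = "expression_map"
  )
}

#' @export
print.expression_map <- function(x, ...) {
  cat("<expression_map> ", length(x$markers), " markers x ",
      length(x$subsets), " subsets (", nrow(x$long), " populated cells)\n",
      sep = "")
  invisible(x)
}

#' Tidy an expression map
#' @param x An `expression_map`.
#' @param ... Unused.
#' @return The long tibble: one row per populated (marker, subset) cell with
#'   `abc`, `abc_mean`, `pct_pos`, `n_donors`, `cv_donor`.
#' @method tidy expression_map
#' @export
tidy.expression_map <- function(x, ...) x$long

#' Extract an expression-map matrix
#'
#' @param map An `expression_map`.
#' @param what `"abc"` (group-median corrected ABC) or `"pct_pos"`.
#' @return A markers-by-subsets matrix with `NA` for unpopulated cells.
#' @export
expr_matrix <- function(map, what = c("abc", "pct_pos")) {
  what <- match.arg(what)
  stopifnot(inherits(map, "expression_map"))
  m <- matrix(NA_real_, length(map$markers), length(map$subsets),
              dimnames = list(map$markers, map$subsets))
  m[cbind(map$long$marker, map$long$subset)] <- map$long[[what]]
  m
}

#' Per-marker coefficient of variation profiles
#'
#' The CV (sample SD / mean) of expression per marker, either of the
#' group-median ABC across subsets (expression heterogeneity over the
#' leukocyte landscape) or of the cross-donor CVs summarised per marker
#' (biological replication noise).
#'
#' @param map An `expression_map`.
#' @param axis `"across_subsets"` or `"across_donors"`.
#' @return A tibble `marker`, `cv`, `n`, ordered by rising CV. Markers with
#'   fewer than two values on the chosen axis get `NA`.
#' @export
cv_profile <- function(map, axis = c("across_subsets", "across_donors")) {
  axis <- match.arg(axis)
  stopifnot(inherits(map, "expression_map"))
  out <- if (axis == "across_subsets") {
    map$long |>
      group_by(.data$marker) |>
      summarise(cv = cv_of(.data$abc), n = dplyr::n(), .groups = "drop")
  } else {
    map$long |>
      group_by(.data$marker) |>
      summarise(cv = median(.data$cv_donor, na.rm = TRUE),
                n = sum(!is.na(.data$cv_donor)), .groups = "drop") |>
      mutate(cv = ifelse(.data$n < 1, NA_real_, .data$cv))
  }
  out |> arrange(.data$cv)
}
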