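#' Clean fluorescence values
#'
#' Replaces every non-positive value by 1 (log-scale statistics and the
#' calibration transform require positive input); positive values pass
#' through unchanged.
#'
#' @param x Numeric vector of fluorescence values.
#' @return Cleaned vector of the same length.
#' @examples
#' clean_values(c(-5, 0, 3))  # 1 1 3
#' @export
clean_values <- function(x) {
  x[!is.na(x) & x <= 0] <- 1
  x
}

#' Build a gate tree
#'
#' A gate tree is a hierarchy of axis-aligned rules that assigns each event to
#' at most one leaf subset. Each node may carry a `rule` — either a threshold
#' (`channel`, `threshold`, `side = "above"|"below"`) or a rectangle
#' (`channel_x`, `xmin`, `xmax`, `channel_y`, `ymin`, `ymax`) — plus either
#' `children` (a list of nodes) or a leaf `subset` id. An event is labelled
#' with the subset of the first leaf (depth-first, in configuration order)
#' whose path of rules it satisfies; events failing all leaves are
#' `"ungated"`.
#'
#' @param x A nested list as described, or a path to a YAML file holding it.
#' @return A `gate_tree` object.
#' @export
gate_tree <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (!is.list(x)) {
    abort("A gate tree must be a list (or a YAML file containing one).",
          class = "flowabc_config_error")
  }
  structure(x, class = "gate_tree")
}

#' Default one-channel-per-subset gate tree
#'
#' Matches the simulator's backbone design: subset `S` is gated as events
#' above the lo/hi geometric midpoint on its own backbone channel `BB_S`.
#'
#' @param subsets Character vector of subset ids.
#' @param gain Instrument gain used at acquisition.
#' @param backbone_low,backbone_high Template medians used by the simulator.
#' @return A `gate_tree`.
#' @export
default_gate_tree <- function(subsets, gain = 1,
                              backbone_low = 100, backbone_high = 1000) {
  thr <- sqrt(backbone_low * backbone_high) * gain
  gate_tree(list(children = lapply(subsets, function(s) {
    list(rule = list(channel = backbone_channel(s), threshold = thr,
                     side = "above"),
         subset = s)
  })))
}

rule_mask <- function(rule, events) {
  need <- function(ch) {
    if (is.null(events[[ch]])) {
      abort(sprintf("Gate rule references missing channel '%s'.", ch),
            class = "flowabc_config_error")
    }
    events[[ch]]
  }
  if (!is.null(rule$channel)) {
    v <- need(rule$channel)
    if (identical(rule$side, "below")) v < rule$threshold else v > rule$threshold
  } else {
    vx <- need(rule$channel_x); vy <- need(rule$channel_y)
    vx >= rule$xmin & vx <= rule$xmax & vy >= rule$ymin & vy <= rule$ymax
  }
}

#' Label events with gate-tree subsets
#'
#' @param events An event table (any data frame of channels).
#' @param tree A [gate_tree].
#' @return The input as a tibble with an added `subset` column (`"ungated"`
#'   for events matching no leaf). Per-subset counts are one
#'   `dplyr::count(out, subset)` away.
#' @export
apply_gates <- function(events, tree) {
  stopifnot(inherits(tree, "gate_tree"))
  n <- nrow(events)
  labels <- rep("ungated", n)
  assigned <- logical(n)

  walk <- function(node, mask) {
    if (!is.null(node$rule)) mask <- mask & rule_mask(node$rule, events)
    if (!is.null(node$subset)) {
      hit <- mask & !assigned
      labels[hit] <<- node$subset
      assigned[hit] <<- TRUE
    }
    for (child in node$children) walk(child, mask)
  }
  walk(unclass(tree), rep(TRUE, n))

  out <- as_tibble(as.data.frame(events))
  out$subset <- labels
  out
}

#' Acquisition-level quality control
#'
#' A sample passes if (i) at least `min_events` events fall in the leukocyte
#' (CD45-positive) gate and (ii) CD45 expression is stable over acquisition
#' time: events are split into `n_blocks` equal blocks by acquisition order
#' and no block's CD45 median may deviate from the whole-sample median by more
#' than `drift_tol` (relative), a proxy for the clogging-induced drift that is
#' otherwise curated by eye.
#'
#' @param events An event table (row order = acquisition order).
#' @param leukocyte_channel Channel gating leukocytes (default `"CD45"`).
#' @param cd45_threshold Fluorescence threshold defining CD45-positive.
#' @param min_events Minimum CD45-positive events (default 500,000).
#' @param n_blocks,drift_tol Drift-check granularity and relative tolerance.
#' @return A list: `pass` (logical), `n_leukocyte_events`, and `reasons`
#'   (character vector among `"leukocyte-count"`, `"cd45-drift"`).
#' @export
qc_sample <- function(events, leukocyte_channel = "CD45",
                      cd45_threshold = 1000, min_events = 500000,
                      n_blocks = 10L, drift_tol = 0.3) {
  ch <- events[[leukocyte_channel]]
  if (is.null(ch)) {
    abort(sprintf("QC requires channel '%s'.", leukocyte_channel),
          class = "flowabc_config_error")
  }
  pos <- ch > cd45_threshold
  n_pos <- sum(pos)
  reasons <- character(0)
  if (n_pos < min_events) reasons <- c(reasons, "leukocyte-count")

  vals <- ch[pos]
  if (length(vals) >= n_blocks) {
    whole <- median(vals)
    block <- ceiling(seq_along(vals) / (length(vals) / n_blocks))
    block_med <- tapply(vals, block, median)
    if (any(abs(block_med / whole - 1) > drift_tol)) {
      reasons <- c(reasons, "cd45-drift")
    }
  }
  list(pass = length(reasons) == 0L, n_leukocyte_events = n_pos,
       reasons = reasons)
}

#' Drop subsets below the minimum cell count
#'
#' Subsets with fewer than `min_cells` events are omitted from statistical
#' evaluation (default 100).
#'
#' @param counts A data frame with columns `subset` and `n` (per-subset event
#'   counts), e.g. from `dplyr::count()`.
#' @param min_cells Minimum retained count.
#' @return The retained rows; dropped subsets are reported via `message()`,
#'   and an all-dropped result triggers a warning.
#' @export
filter_min_cells <- function(counts, min_cells = 100L) {
  counts <- as_tibble(counts)
  dropped <- counts |> filter(.data$n < min_cells)
  kept <- counts |> filter(.data$n >= min_cells)
  if (nrow(dropped) > 0) {
    message("Dropping subset(s) below ", min_cells, " cells: ",
            paste0(dropped$subset, " (n=", dropped$n, ")", collapse = ", "))
  }
  if (nrow(kept) == 0) {
    warn("All subsets fell below the minimum cell count; no records retained.")
  }
  kept
}

#' FMO-anchored positivity cutoff
#'
#' The positivity threshold for a subset is the 99.5th percentile (linear
#' interpolation between order statistics) of the matched subset's PE
#' distribution in the fluorescence-minus-one control well. A per-subset
#' cutoff is used because autofluorescence background differs by lineage.
#'
#' @param fmo_pe Cleaned PE values of the FMO well, either the full vector for
#'   one subset or all events when `labels`/`subset` select them.
#' @param labels Optional per-event subset labels matching `fmo_pe`.
#' @param subset Optional subset id to select from `labels`.
#' @param percentile Tail percentile of the negative control (default 0.995).
#' @param min_events Minimum FMO events required in the subset (default 100);
#'   below it the cutoff is unavailable (`NA`, with a warning).
#' @return The fluorescence threshold (or `NA_real_` if unavailable).
#' @export
positivity_cutoff <- function(fmo_pe, labels = NULL, subset = NULL,
                              percentile = 0.995, min_events = 100L) {
  if (!is.null(labels) && !is.null(subset)) fmo_pe <- fmo_pe[labels == subset]
  fmo_pe <- fmo_pe[!is.na(fmo_pe)]
  if (length(fmo_pe) < min_events) {
    warn(sprintf("Only %d FMO event(s)%s: positivity cutoff unavailable.",
                 length(fmo_pe),
                 if (!is.null(subset)) paste0(" in subset ", subset) else ""))
    return(NA_real_)
  }
  unname(quantile(fmo_pe, percentile, type = 7))
}

# mode of a continuous sample: midpoint of the tallest of 256 bins on log10
# scale, reported back on the fluorescence scale
mode_log_hist <- function(x, n_bins = 256L) {
  lx <- log10(x)
  r <- range(lx)
  if (r[1] == r[2]) return(10^r[1])
  h <- graphics::hist(lx, breaks = seq(r[1], r[2], length.out = n_bins + 1L),
                      plot = FALSE)
  10^h$mids[which.max(h$counts)]
}

#' Per-subset expression statistics
#'
#' Computes the exported statistics set for one (subset, marker, donor)
#' record: median, mean, mode, CV and the 10/25/50/75/90th percentiles on the
#' fluorescence scale, the percentage of events strictly above the FMO
#' cutoff, and — when a calibration curve is supplied — the same location
#' statistics converted to conjugation-corrected ABC. Quantiles use linear
#' interpolation between order statistics; CV is sample SD / mean; the mode of
#' the continuous distribution is the midpoint of the tallest of 256 log10
#' bins.
#'
#' @param pe Cleaned PE values of the subset (>= 100 events).
#' @param cutoff FMO positivity cutoff (fluorescence units).
#' @param curve Optional [calibration_curve][fit_calibration]; when present,
#'   `*_abc` columns are added.
#' @param factor Conjugation correction factor for the marker (default 1).
#' @param subset,marker,donor Record identifiers.
#' @return A one-row tibble (class `subset_stats` rows bind naturally).
#' @export
subset_statistics <- function(pe, cutoff, curve = NULL, factor = 1,
                              subset = NA_character_, marker = NA_character_,
                              donor = NA_character_) {
  pe <- pe[!is.na(pe)]
  if (length(pe) < 100L) {
    abort("At least 100 events are required for statistical evaluation.",
          class = "flowabc_invalid_argument")
  }
  q <- quantile(pe, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7, names = FALSE)
  out <- tibble(
    subset = subset, marker = marker, donor = donor,
    n_events = length(pe),
    median = q[3], mean = mean(pe), mode = mode_log_hist(pe),
    cv = cv_of(pe),
    p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    fmo_cutoff = cutoff,
    pct_positive = if (is.na(cutoff)) NA_real_ else 100 * mean(pe > cutoff)
  )
  if (!is.null(curve)) {
    to_abc <- function(v) apply_correction(fluorescence_to_abc(curve, v), factor)
    out <- out |> mutate(
      median_abc = to_abc(.data$median), mean_abc = to_abc(.data$mean),
      mode_abc = to_abc(.data$mode),
      p10_abc = to_abc(.data$p10), p25_abc = to_abc(.data$p25),
      p50_abc = to_abc(.data$p50), p75_abc = to_abc(.data$p75),
      p90_abc = to_abc(.data$p90)
    )
  }
  out
}
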