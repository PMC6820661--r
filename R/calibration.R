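#' Locate the four bead peaks of a calibration acquisition
#'
#' Identifies the `k` bead populations of a quantitation-bead well by 1-D
#' k-means on log10 fluorescence, initialised deterministically at the
#' 12.5/37.5/62.5/87.5th percentiles (evenly spaced percentile centres for
#' general `k`), and returns the ascending cluster medians on the original
#' scale.
#'
#' @param beads An `event_table` with a `PE` channel (>= `100 * k` events).
#' @param k Number of bead levels (default 4).
#' @param channel Channel holding the bead fluorescence.
#' @return Numeric vector of `k` ascending peak medians (fluorescence units).
#' @section Degenerate peaks: if any two cluster medians lie within twice each
#'   other's MAD the modes are not separable and a `flowabc_degenerate_peaks`
#'   error is thrown (e.g. a two-level bead set clustered with `k = 4`).
#' @export
find_bead_peaks <- function(beads, k = 4L, channel = "PE") {
  k <- check_count(k, "k")
  x <- beads[[channel]]
  if (is.null(x)) {
    abort(sprintf("Channel '%s' not present in bead events.", channel),
          class = "flowabc_config_error")
  }
  if (length(x) < 100 * k) {
    abort(sprintf("Need at least %d bead events for k = %d peaks.", 100 * k, k),
          class = "flowabc_invalid_argument")
  }
  if (any(x <= 0)) x <- pmax(x, .Machine$double.xmin)
  lx <- log10(x)

  centers <- quantile(lx, probs = (seq_len(k) - 0.5) / k, names = FALSE, type = 7)
  if (length(unique(centers)) < k || length(unique(lx)) < k) {
    abort("Fewer separable bead modes than requested peaks.",
          class = "flowabc_degenerate_peaks")
  }
  km <- tryCatch(
    kmeans(lx, centers = matrix(centers, ncol = 1), iter.max = 100L),
    error = function(e) {
      abort("Fewer separable bead modes than requested peaks.",
            class = "flowabc_degenerate_peaks", parent = e)
    }
  )

  stats_by_cluster <- tibble(cluster = km$cluster, value = x, lvalue = lx) |>
    group_by(.data$cluster) |>
    summarise(med = median(.data$value), lmed = median(.data$lvalue),
              lmad = mad(.data$lvalue), .groups = "drop") |>
    arrange(.data$med)

  # separability on the log scale: adjacent cluster medians closer than twice
  # their combined MADs indicate one mode split in two, not two bead levels
  meds <- stats_by_cluster$med
  lmeds <- stats_by_cluster$lmed
  lmads <- stats_by_cluster$lmad
  for (i in seq_len(k - 1L)) {
    gap <- lmeds[i + 1L] - lmeds[i]
    if (gap <= 2 * (lmads[i] + lmads[i + 1L])) {
      abort(sprintf(
        "Degenerate bead peaks: medians %g and %g are not separable.",
        meds[i], meds[i + 1L]), class = "flowabc_degenerate_peaks")
    }
  }
  meds
}

#' Fit the PE calibration curve
#'
#' Ordinary least squares of log10(PE molecules per bead) on log10(measured
#' peak fluorescence) across the bead levels. The slope is fitted rather than
#' fixed at 1, so instrument miscalibration shows up as a slope away from 1 or
#' a depressed R-squared.
#'
#' @param peaks Ascending positive peak medians (fluorescence units).
#' @param lot The [bead_lot] whose `pe_per_bead` values match the peaks.
#' @return A `calibration_curve` object with `slope`, `intercept`
#'   (log10 PE molecules), `fit_r2` and the `peak_table`.
#' @examples
#' lot <- bead_lot()
#' curve <- fit_calibration(lot$pe_per_bead, lot)  # identity calibration
#' fluorescence_to_abc(curve, 1000)
#' @export
fit_calibration <- function(peaks, lot) {
  stopifnot(inherits(lot, "bead_lot"))
  if (length(peaks) != length(lot$pe_per_bead)) {
    abort("`peaks` must have one median per bead level.",
          class = "flowabc_invalid_argument")
  }
  if (any(peaks <= 0) || any(!is.finite(peaks))) {
    abort("Peak medians must be positive and finite.",
          class = "flowabc_invalid_argument")
  }
  if (is.unsorted(peaks, strictly = TRUE)) {
    abort("Peak medians must be strictly ascending.",
          class = "flowabc_invalid_argument")
  }
  lf <- log10(peaks)
  lm_fit <- lm(log10(lot$pe_per_bead) ~ lf)
  # a perfect fit is the expected outcome on clean beads; lm's "essentially
  # perfect fit" warning is noise here
  r2 <- suppressWarnings(summary(lm_fit)$r.squared)
  structure(
    list(
      slope = unname(coef(lm_fit)[2]),
      intercept = unname(coef(lm_fit)[1]),
      fit_r2 = r2,
      peak_table = tibble(fluorescence = peaks, pe_per_bead = lot$pe_per_bead)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> log10(ABC) = %.4f * log10(F) + %.4f  (R2 = %.5f)\n",
              x$slope, x$intercept, x$fit_r2))
  invisible(x)
}

#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(r.squared = x$fit_r2, n_peaks = nrow(x$peak_table))
}

#' Convert fluorescence to antibody binding capacity
#'
#' Applies the calibration curve: `ABC = 10^(slope * log10(mfi) + intercept)`,
#' mapping a (median) fluorescence intensity to PE molecules, i.e. antibody
#' binding capacity under ~1:1 PE:antibody conjugation. Monotone increasing
#' in `mfi`. Vectorised.
#'
#' @param curve A `calibration_curve`.
#' @param mfi Positive fluorescence value(s); non-positive values must be
#'   cleaned upstream (see [clean_values()]).
#' @return ABC value(s), PE molecules per cell.
#' @export
fluorescence_to_abc <- function(curve, mfi) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(mfi)) || any(mfi <= 0)) {
    abort("`mfi` must be positive; clean non-positive values first.",
          class = "flowabc_invalid_argument")
  }
  10^(curve$slope * log10(mfi) + curve$intercept)
}

#' Conjugation correction factors from capture-bead medians
#'
#' For each antibody, the correction factor is its capture-bead median PE
#' divided by the median of all antibodies' medians, so a factor above 1 means
#' the conjugate carries more than one PE per antibody. Factors below 0.7 or
#' above 1.3 are flagged for re-measurement. When replicate measurements are
#' supplied for a marker, replicate factors outside one standard deviation of
#' that marker's replicate mean are excluded as outliers and the final factor
#' is the mean of the concordant replicates.
#'
#' @param medians A data frame with columns `marker` and `median_pe` (one row
#'   per measurement; repeated markers are replicates), or a named numeric
#'   vector of medians.
#' @return A `correction_table`: tibble with `marker`, `factor`, `flagged`,
#'   `n_replicates`, carrying `mean_factor` / `sd_factor` summary attributes.
#' @examples
#' correction_factors(c(M1 = 80, M2 = 100, M3 = 130))
#' @export
correction_factors <- function(medians) {
  if (is.numeric(medians)) {
    medians <- tibble(marker = names(medians) %||% paste0("M", seq_along(medians)),
                      median_pe = as.numeric(medians))
  }
  medians <- as_tibble(medians)
  if (!all(c("marker", "median_pe") %in% names(medians)) || nrow(medians) < 1) {
    abort("`medians` needs columns marker, median_pe and at least one row.",
          class = "flowabc_invalid_argument")
  }
  if (any(medians$median_pe <= 0) || any(!is.finite(medians$median_pe))) {
    abort("All medians must be positive.", class = "flowabc_invalid_argument")
  }
  medians$median_pe <- as.numeric(unname(medians$median_pe))

  grand <- median(medians$median_pe)
  per_meas <- medians |> mutate(factor = .data$median_pe / grand)

  out <- per_meas |>
    group_by(.data$marker) |>
    summarise(
      factor = {
        f <- .data$factor
        if (length(f) > 1L) {
          keep <- abs(f - mean(f)) <= sd(f)   # concordance: within 1 SD
          mean(f[keep])
        } else f
      },
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(flagged = .data$factor < 0.7 | .data$factor > 1.3) |>
    select("marker", "factor", "flagged", "n_replicates") |>
    arrange(match(.data$marker, unique(medians$marker)))

  structure(out,
            mean_factor = mean(out$factor),
            sd_factor = if (nrow(out) > 1) sd(out$factor) else NA_real_,
            class = c("correction_table", class(out)))
}

#' Apply a conjugation correction factor
#'
#' Corrected ABC = ABC / factor: a conjugate carrying twice the PE per
#' antibody inflates apparent ABC two-fold, so the measured value is divided
#' by its factor. Vectorised over both arguments.
#'
#' @param abc ABC value(s).
#' @param factor Positive correction factor(s).
#' @return Corrected ABC.
#' @export
apply_correction <- function(abc, factor) {
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    abort("`factor` must be positive.", class = "flowabc_invalid_argument")
  }
  abc / factor
}
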