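#' Logistic model of rank-ordered positivity
#'
#' Orders a subset's markers by rising percentage of positive cells (stable
#' tie-break on marker id so ranks are reproducible), assigns ranks
#' `cds = 1..n`, and fits the three-parameter logistic
#' \deqn{PE(cds) = PE_{max} / (1 + e^{-a_1 (cds - cds_{mid})})}
#' by bounded Levenberg–Marquardt nonlinear least squares. The slope of the
#' fitted curve at the midpoint is, identically in the parameters,
#' `a1 * pe_max / 4`, and is reported as `slope_mid`.
#'
#' Each marker is classified from the fitted curve value at its rank:
#' `negative` if at most `neg_frac * pe_max`, `positive` if at least
#' `pos_frac * pe_max`, otherwise `intermediate`. A fit that cannot converge
#' (e.g. an all-zero sequence) yields a degenerate result with
#' `converged = FALSE` and every marker classified `negative` when the
#' sequence is flat at zero.
#'
#' @param pct_pos A data frame with columns `marker` and `pct_pos`
#'   (percentages in \[0, 100\]), or a named numeric vector.
#' @param neg_frac,pos_frac Plateau fractions for the class thresholds.
#' @return A `sigmoid_fit` object; `tidy()` gives the parameter table,
#'   `glance()` the fit summary, and `$data` the per-marker ranks, fitted
#'   values and classes.
#' @examples
#' y <- 100 / (1 + exp(-0.3 * (1:40 - 20)))
#' fit <- fit_sigmoid(setNames(y, sprintf("M%02d", 1:40)))
#' glance(fit)
#' @export
fit_sigmoid <- function(pct_pos, neg_frac = 0.1, pos_frac = 0.9) {
  if (is.numeric(pct_pos)) {
    pct_pos <- tibble(marker = names(pct_pos) %||% paste0("M", seq_along(pct_pos)),
                      pct_pos = as.numeric(pct_pos))
  }
  pct_pos <- as_tibble(pct_pos)
  if (!all(c("marker", "pct_pos") %in% names(pct_pos)) || nrow(pct_pos) < 10) {
    abort("`pct_pos` needs columns marker, pct_pos and at least 10 markers.",
          class = "flowabc_invalid_argument")
  }
  if (any(pct_pos$pct_pos < 0 | pct_pos$pct_pos > 100, na.rm = TRUE)) {
    abort("`pct_pos` values must lie in [0, 100].",
          class = "flowabc_invalid_argument")
  }

  dat <- pct_pos |>
    arrange(.data$pct_pos, .data$marker) |>
    mutate(cds = dplyr::row_number())
  y <- dat$pct_pos
  n <- length(y)

  pe_max0 <- max(y)
  fit <- NULL
  if (pe_max0 > 0) {
    cds_mid0 <- dat$cds[which(y >= pe_max0 / 2)[1]]
    a1_0 <- 4 * (max(y) - min(y)) / (n * pe_max0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        pct_pos ~ pe_max / (1 + exp(-a1 * (cds - cds_mid))),
        data = dat,
        start = list(pe_max = pe_max0, cds_mid = cds_mid0, a1 = max(a1_0, 1e-3)),
        lower = c(pe_max = 1e-6, cds_mid = -Inf, a1 = 1e-8),
        upper = c(pe_max = 110, cds_mid = Inf, a1 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  if (is.null(fit)) {
    dat$fitted <- rep(0, n)
    dat$class <- rep("negative", n)
    out <- list(pe_max = NA_real_, cds_mid = NA_real_, a1 = NA_real_,
                slope_mid = NA_real_, rss = NA_real_, converged = FALSE,
                data = dat)
  } else {
    p <- as.list(coef(fit))
    dat$fitted <- as.numeric(predict(fit))
    dat$class <- dplyr::case_when(
      dat$fitted <= neg_frac * p$pe_max ~ "negative",
      dat$fitted >= pos_frac * p$pe_max ~ "positive",
      TRUE ~ "intermediate"
    )
    out <- list(pe_max = p$pe_max, cds_mid = p$cds_mid, a1 = p$a1,
                slope_mid = p$a1 * p$pe_max / 4,
                rss = sum(stats::residuals(fit)^2), converged = TRUE,
                data = dat)
  }
  structure(out, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<sigmoid_fit> pe_max = %.3f, cds_mid = %.3f, a1 = %.4f (slope at midpoint %.3f)\n",
      x$pe_max, x$cds_mid, x$a1, x$slope_mid))
  } else {
    cat("<sigmoid_fit> degenerate (no converged fit)\n")
  }
  invisible(x)
}

#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("pe_max", "cds_mid", "a1"),
         estimate = c(x$pe_max, x$cds_mid, x$a1))
}

#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(pe_max = x$pe_max, cds_mid = x$cds_mid, a1 = x$a1,
         slope_mid = x$slope_mid, rss = x$rss, converged = x$converged,
         n_markers = nrow(x$data))
}

#' Plot a fitted positivity sigmoid
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot: observed percent positive by rank, coloured by class,
#'   with the fitted logistic overlaid.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$cds, y = .data$pct_pos)) +
    geom_point(aes(colour = .data$class)) +
    geom_line(aes(y = .data$fitted)) +
    labs(x = "marker rank (rising positivity)", y = "% positive cells",
         colour = "class") +
    theme_minimal()
}
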