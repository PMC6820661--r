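#' Generate a ground-truth surface-expression design
#'
#' Builds the hidden truth behind a simulated quantitative immunophenotyping
#' experiment: a marker-by-subset matrix of true antibody binding capacities
#' (ABC, molecules per cell), true positive-cell fractions, per-subset
#' autofluorescence background, per-antibody conjugation-ratio factors, and
#' the subset mixture of a sample.
#'
#' Subsets are organised into `n_lineage_blocks` lineage blocks (emulating
#' e.g. T-cell / B-cell / myeloid compartments). Each non-ubiquitous marker is
#' planted in one block: its ABC is drawn log-uniformly from `abc_high` on
#' subsets of its own block and from `abc_low` elsewhere, so each block
#' carries at least a 10-fold expression contrast that downstream clustering
#' should recover. A fraction `prop_ubiquitous` of markers is highly expressed
#' on every subset (pan-leukocyte markers such as CD45 behave this way).
#'
#' When `n_lineage_blocks >= 2` the first block is treated as myeloid and
#' receives the higher autofluorescence background; all other subsets are
#' lymphoid. Backgrounds default to the centres of the reported "gray zone"
#' ranges (200-700 ABC for lymphocytes, 1,000-10,000 for myeloid cells).
#'
#' @param n_markers Number of drop-in markers (>= 2).
#' @param n_subsets Number of leukocyte subsets (>= 2).
#' @param n_lineage_blocks Number of planted lineage blocks (1..`n_subsets`).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param abc_high,abc_low Ranges (length 2) for log-uniform true ABC of
#'   markers on their own block vs off-block background expression.
#' @param frac_pos_high,frac_pos_low Ranges for the true positive-cell
#'   fraction of expressed vs unexpressed markers.
#' @param prop_ubiquitous Fraction of markers expressed on all subsets.
#' @param autofluor_lymphoid,autofluor_myeloid Additive autofluorescence
#'   background in ABC-equivalents.
#' @param conj_sd,conj_range Spread (normal SD around 1) and truncation range
#'   of true PE:antibody conjugation factors; conjugation is consistent with
#'   1:1 labelling, so factors centre on 1.
#'
#' @return An object of class `abc_ground_truth`: a list with matrices
#'   `abc_true` and `frac_pos_true` (markers x subsets), vectors
#'   `autofluor_abc`, `conj_factor_true`, `subset_mix`, block assignments
#'   `marker_block` / `subset_block` (0 = ubiquitous marker), and `lineage`.
#' @examples
#' gt <- generate_ground_truth(n_markers = 10, n_subsets = 4,
#'                             n_lineage_blocks = 2, seed = 1)
#' tidy(gt)
#' @export
generate_ground_truth <- function(n_markers, n_subsets, n_lineage_blocks = 2L,
                                  seed = 1L,
                                  abc_high = c(1e4, 1e5),
                                  abc_low = c(1e2, 1e3),
                                  frac_pos_high = c(0.95, 1),
                                  frac_pos_low = c(0, 0.05),
                                  prop_ubiquitous = 0.2,
                                  autofluor_lymphoid = 450,
                                  autofluor_myeloid = 3000,
                                  conj_sd = 0.15,
                                  conj_range = c(0.7, 1.3)) {
  n_markers <- check_count(n_markers, "n_markers", min = 2L)
  n_subsets <- check_count(n_subsets, "n_subsets", min = 2L)
  n_lineage_blocks <- check_count(n_lineage_blocks, "n_lineage_blocks")
  if (n_lineage_blocks > n_subsets) {
    abort("`n_lineage_blocks` cannot exceed `n_subsets`.",
          class = "flowabc_invalid_argument")
  }

  markers <- sprintf("M%02d", seq_len(n_markers))
  subsets <- sprintf("S%d", seq_len(n_subsets))

  withr::local_seed(derive_seed(seed, "ground_truth"))

  subset_block <- rep_len(seq_len(n_lineage_blocks), n_subsets)
  lineage <- if (n_lineage_blocks >= 2) {
    ifelse(subset_block == 1L, "myeloid", "lymphoid")
  } else {
    rep("lymphoid", n_subsets)
  }

  n_ubiq <- max(1L, round(prop_ubiquitous * n_markers))
  marker_block <- integer(n_markers)
  marker_block[seq_len(n_ubiq)] <- 0L
  if (n_ubiq < n_markers) {
    marker_block[(n_ubiq + 1L):n_markers] <-
      rep_len(seq_len(n_lineage_blocks), n_markers - n_ubiq)
  }

  runif_log <- function(n, range) 10^runif(n, log10(range[1]), log10(range[2]))

  on_grid <- outer(marker_block, subset_block,
                   function(mb, sb) mb == 0L | mb == sb)
  abc_true <- matrix(0, n_markers, n_subsets, dimnames = list(markers, subsets))
  frac_pos_true <- abc_true
  abc_true[on_grid] <- runif_log(sum(on_grid), abc_high)
  abc_true[!on_grid] <- runif_log(sum(!on_grid), abc_low)
  frac_pos_true[on_grid] <- runif(sum(on_grid), frac_pos_high[1], frac_pos_high[2])
  frac_pos_true[!on_grid] <- runif(sum(!on_grid), frac_pos_low[1], frac_pos_low[2])

  autofluor_abc <- setNames(
    ifelse(lineage == "myeloid", autofluor_myeloid, autofluor_lymphoid),
    subsets
  )
  # truncated normal around 1: inverse-CDF sampling within the range
  p_lo <- stats::pnorm(conj_range[1], 1, conj_sd)
  p_hi <- stats::pnorm(conj_range[2], 1, conj_sd)
  conj_factor_true <- setNames(
    stats::qnorm(runif(n_markers, p_lo, p_hi), 1, conj_sd), markers)
  mix_raw <- stats::rgamma(n_subsets, shape = 10)
  subset_mix <- setNames(mix_raw / sum(mix_raw), subsets)

  structure(
    list(
      abc_true = abc_true,
      frac_pos_true = frac_pos_true,
      autofluor_abc = autofluor_abc,
      conj_factor_true = conj_factor_true,
      subset_mix = subset_mix,
      marker_block = setNames(marker_block, markers),
      subset_block = setNames(subset_block, subsets),
      lineage = setNames(lineage, subsets),
      seed = as.integer(seed)
    ),
    class = "abc_ground_truth"
  )
}

#' @export
print.abc_ground_truth <- function(x, ...) {
  cat("<abc_ground_truth> ", nrow(x$abc_true), " markers x ",
      ncol(x$abc_true), " subsets, ",
      max(x$subset_block), " lineage block(s), seed ", x$seed, "\n", sep = "")
  cat("true ABC range: ", format(min(x$abc_true), digits = 3), " - ",
      format(max(x$abc_true), digits = 3), " molecules/cell\n", sep = "")
  invisible(x)
}

#' Tidy a ground-truth design into a long tibble
#'
#' @param x An `abc_ground_truth` object.
#' @param ... Unused.
#' @return A tibble with one row per (marker, subset) cell: true ABC, true
#'   positive fraction, block assignments, lineage and background level.
#' @method tidy abc_ground_truth
#' @export
tidy.abc_ground_truth <- function(x, ...) {
  markers <- rownames(x$abc_true)
  subsets <- colnames(x$abc_true)
  tidyr::expand_grid(marker = markers, subset = subsets) |>
    mutate(
      abc_true = x$abc_true[cbind(.data$marker, .data$subset)],
      frac_pos_true = x$frac_pos_true[cbind(.data$marker, .data$subset)],
      marker_block = unname(x$marker_block[.data$marker]),
      subset_block = unname(x$subset_block[.data$subset]),
      lineage = unname(x$lineage[.data$subset]),
      autofluor_abc = unname(x$autofluor_abc[.data$subset])
    )
}
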