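#' Transform an expression matrix for clustering
#'
#' The clustering transform chain: raise the matrix minimum strictly above
#' zero (adding `1 - min` when the minimum is at or below zero, otherwise no
#' shift), take log10, remove FMO pseudo-markers and any marker or subset
#' with missing values, and z-score each marker across subsets (mean 0,
#' SD 1). Markers left with zero variance after the log are dropped with a
#' warning (their z-score is undefined).
#'
#' @param x An [expression_map][aggregate_donors] or a markers-by-subsets
#'   numeric matrix of group-median ABC.
#' @param fmo_labels Row names treated as FMO pseudo-markers and removed.
#' @return The transformed matrix, carrying a `"transform_log"` attribute
#'   recording the shift and everything dropped.
#' @export
transform_expression <- function(x, fmo_labels = "FMO") {
  m <- if (inherits(x, "expression_map")) expr_matrix(x, "abc") else as.matrix(x)
  if (length(m) == 0) {
    abort("Empty expression matrix.", class = "flowabc_invalid_argument")
  }
  log_rec <- list()

  fmo_rows <- rownames(m) %in% fmo_labels
  if (any(fmo_rows)) {
    log_rec$dropped_fmo <- rownames(m)[fmo_rows]
    m <- m[!fmo_rows, , drop = FALSE]
  }

  min_val <- min(m, na.rm = TRUE)
  shift <- if (min_val <= 0) 1 - min_val else 0
  log_rec$shift <- shift
  m <- log10(m + shift)

  na_rows <- apply(m, 1, anyNA)
  if (any(na_rows)) {
    log_rec$dropped_markers_missing <- rownames(m)[na_rows]
    m <- m[!na_rows, , drop = FALSE]
  }
  na_cols <- apply(m, 2, anyNA)
  if (any(na_cols)) {
    log_rec$dropped_subsets_missing <- colnames(m)[na_cols]
    m <- m[, !na_cols, drop = FALSE]
  }

  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(paste("Dropping zero-variance marker(s):",
               paste(rownames(m)[sds == 0], collapse = ", ")))
    log_rec$dropped_markers_constant <- rownames(m)[sds == 0]
    m <- m[sds > 0, , drop = FALSE]
  }
  m <- t(scale(t(m)))            # z-score each marker across subsets
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  attr(m, "transform_log") <- log_rec
  m
}

#' Hierarchical clustering of expression profiles
#'
#' Euclidean distances between profiles and Ward minimum-variance linkage
#' (the `ward.D2` squared-distance variant), with the tree cut into `k`
#' clusters. By default the subsets (columns) are clustered on their
#' transformed marker profiles; `margin = "markers"` clusters the markers
#' instead.
#'
#' @param tmat A transformed matrix from [transform_expression()] (or any
#'   numeric markers-by-subsets matrix).
#' @param k Number of clusters to cut (default 5).
#' @param margin `"subsets"` or `"markers"`.
#' @return A `cluster_result`: the `hclust` tree, the `labels` cut at `k`,
#'   and the transform log. `tidy()` returns an item/cluster tibble.
#' @export
hca <- function(tmat, k = 5L, margin = c("subsets", "markers")) {
  margin <- match.arg(margin)
  k <- check_count(k, "k")
  profiles <- if (margin == "subsets") t(tmat) else tmat
  if (k > nrow(profiles)) {
    abort(sprintf("k = %d exceeds the number of %s (%d).", k, margin,
                  nrow(profiles)), class = "flowabc_invalid_argument")
  }
  tree <- hclust(dist(profiles, method = "euclidean"), method = "ward.D2")
  labels <- cutree(tree, k = k)
  structure(
    list(tree = tree, labels = labels, k = k, margin = margin,
         transform_log = attr(tmat, "transform_log")),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$labels), " ", x$margin,
      " in k = ", x$k, " clusters (Euclidean / ward.D2)\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(item = names(x$labels), cluster = unname(x$labels))
}

#' Plot a clustering dendrogram with its cut
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot dendrogram; leaf labels are coloured by cluster.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  seg <- dendrogram_segments(object$tree)
  leaves <- tibble(
    label = object$tree$labels[object$tree$order],
    x = seq_along(object$tree$order)
  ) |>
    mutate(cluster = factor(object$labels[.data$label]))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend)) +
    geom_text(data = leaves,
              aes(x = .data$x, y = -0.02 * max(seg$y),
                  label = .data$label, colour = .data$cluster),
              angle = 90, hjust = 1, size = 3) +
    scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    labs(x = NULL, y = "merge height (ward.D2)", colour = "cluster") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_blank())
}

# hclust -> segment table for a ggplot dendrogram
dendrogram_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- setNames(seq_len(n), tree$order)
  node_x <- numeric(nrow(tree$merge))
  node_y <- tree$height
  segs <- vector("list", nrow(tree$merge))
  pos <- function(id) if (id < 0) leaf_x[[as.character(-id)]] else node_x[id]
  hgt <- function(id) if (id < 0) 0 else node_y[id]
  for (i in seq_len(nrow(tree$merge))) {
    a <- tree$merge[i, 1]; b <- tree$merge[i, 2]
    xa <- pos(a); xb <- pos(b)
    node_x[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xa, xb),
      xend = c(xa, xb, xb),
      y = c(hgt(a), node_y[i], node_y[i]),
      yend = c(node_y[i], node_y[i], hgt(b))
    )
  }
  dplyr::bind_rows(segs)
}

#' Differential marker comparison between two groups
#'
#' For each marker, compares donor-level median ABC between two groups of
#' samples with a two-sided test (Wilcoxon rank-sum by default, or Welch t on
#' log10 values), reports the fold change of cleaned group medians (both
#' forced to at least 1 by the value-cleaning rule), assigns significance
#' tiers at the raw p < 0.01 and p < 0.001 thresholds (no multiplicity
#' correction by default, `p_adjust = "BH"` turns Benjamini-Hochberg on), and
#' flags markers whose symmetric fold change `max(fc, 1/fc)` reaches
#' `fold_min`.
#'
#' @param data A data frame with columns `marker`, `group` (exactly two
#'   levels), and `value` (donor-level median ABC; one row per donor).
#' @param test `"ranksum"` or `"t_log10"`.
#' @param fold_min Symmetric fold-change threshold (default 10).
#' @param min_donors Minimum donors per group per marker; below it the marker
#'   is reported `untested`, never significant.
#' @param p_adjust `"none"` (default) or any `stats::p.adjust` method.
#' @return A tibble (class `diff_table`): per marker the group medians, raw
#'   `fold_change` (group A / group B), `p_value`, `tier` (`ns`, `p<0.01`,
#'   `p<0.001`, `untested`) and `passes_fold10`.
#' @export
differential_markers <- function(data, test = c("ranksum", "t_log10"),
                                 fold_min = 10, min_donors = 3L,
                                 p_adjust = "none") {
  test <- match.arg(test)
  data <- as_tibble(data)
  if (!all(c("marker", "group", "value") %in% names(data))) {
    abort("`data` needs columns marker, group, value.",
          class = "flowabc_invalid_argument")
  }
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2) {
    abort("Exactly two groups are required.", class = "flowabc_invalid_argument")
  }

  out <- data |>
    group_by(.data$marker) |>
    summarise(
      n_a = sum(.data$group == groups[1]),
      n_b = sum(.data$group == groups[2]),
      median_a = median(clean_values(.data$value[.data$group == groups[1]])),
      median_b = median(clean_values(.data$value[.data$group == groups[2]])),
      p_value = {
        va <- .data$value[.data$group == groups[1]]
        vb <- .data$value[.data$group == groups[2]]
        if (length(va) < min_donors || length(vb) < min_donors) {
          NA_real_
        } else if (test == "ranksum") {
          suppressWarnings(wilcox.test(va, vb, alternative = "two.sided")$p.value)
        } else {
          stats::t.test(log10(clean_values(va)), log10(clean_values(vb)),
                        alternative = "two.sided")$p.value
        }
      },
      .groups = "drop"
    ) |>
    mutate(
      p_value = if (p_adjust == "none") .data$p_value else
        stats::p.adjust(.data$p_value, method = p_adjust),
      fold_change = .data$median_a / .data$median_b,
      tier = dplyr::case_when(
        is.na(.data$p_value) ~ "untested",
        .data$p_value < 0.001 ~ "p<0.001",
        .data$p_value < 0.01 ~ "p<0.01",
        TRUE ~ "ns"
      ),
      passes_fold10 = pmax(.data$fold_change, 1 / .data$fold_change) >= fold_min
    )
  attr(out, "groups") <- groups
  class(out) <- c("diff_table", class(out))
  out
}
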