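# Shared fixtures, built in code at test time.

small_gt <- function(seed = 1, ...) {
  generate_ground_truth(n_markers = 10, n_subsets = 4, n_lineage_blocks = 2,
                        seed = seed, ...)
}

# a ground truth with hand-set values for exact recovery checks
fixed_gt <- function(abc = 1e4, frac = 1, autofluor = 450, conj = 1,
                     n_subsets = 2) {
  gt <- small_gt()
  markers <- rownames(gt$abc_true)[1:2]
  subsets <- colnames(gt$abc_true)[seq_len(n_subsets)]
  gt$abc_true <- matrix(abc, 2, n_subsets, dimnames = list(markers, subsets))
  gt$frac_pos_true <- matrix(frac, 2, n_subsets,
                             dimnames = list(markers, subsets))
  gt$autofluor_abc <- setNames(rep(autofluor, n_subsets), subsets)
  gt$conj_factor_true <- setNames(rep(conj, 2), markers)
  gt$subset_mix <- setNames(rep(1 / n_subsets, n_subsets), subsets)
  gt$marker_block <- setNames(c(1L, 1L), markers)
  gt$subset_block <- setNames(rep(1L, n_subsets), subsets)
  gt$lineage <- setNames(rep("lymphoid", n_subsets), subsets)
  gt
}

# identity calibration curve (fluorescence == PE molecules)
identity_curve <- function() {
  lot <- bead_lot()
  fit_calibration(lot$pe_per_bead, lot)
}

# exact two-sided rank-sum p-value by full enumeration of group-A rank sets
enum_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  pooled_ranks <- rank(c(a, b))
  w_all <- apply(combos, 2, function(idx) {
    sum(pooled_ranks[idx]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# independent curvature from the circumradius formula abc / (4K), with the
# triangle area by Kahan's numerically stable variant of Heron's formula
circumradius_curvature <- function(p, q, r) {
  sides <- sort(c(sqrt(sum((q - p)^2)), sqrt(sum((r - q)^2)),
                  sqrt(sum((p - r)^2))), decreasing = TRUE)
  a <- sides[1]; b <- sides[2]; c <- sides[3]
  t <- (a + (b + c)) * (c - (a - b)) * (c + (a - b)) * (a + (b - c))
  if (t <= 0) return(0)
  area <- 0.25 * sqrt(t)
  4 * area / (a * b * c)
}

# brute-force turning point: argmax of interior Menger curvatures on
# min-max normalised axes, computed without turning_point()
brute_turning_index <- function(values) {
  n <- length(values)
  xs <- (seq_len(n) - 1) / (n - 1)
  r <- range(values)
  ys <- if (r[1] == r[2]) rep(0, n) else (values - r[1]) / (r[2] - r[1])
  curv <- sapply(2:(n - 1), function(i) {
    circumradius_curvature(c(xs[i - 1], ys[i - 1]), c(xs[i], ys[i]),
                           c(xs[i + 1], ys[i + 1]))
  })
  if (all(curv <= 1e-12)) return(NA_integer_)
  (2:(n - 1))[which.max(curv)]
}
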