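test_that("value cleaning maps non-positives to one", {
  expect_equal(clean_values(c(-5, 0, 3)), c(1, 1, 3))
  expect_equal(clean_values(c(2.5, 7)), c(2.5, 7))
  expect_equal(median(clean_values(c(-1, -2, 0))), 1)
})

test_that("threshold gating recovers the simulator's true labels", {
  gt <- small_gt()
  w <- simulate_well(gt, "M02", n_events = 20000, seed = 8, gain = 3)
  tree <- default_gate_tree(colnames(gt$abc_true), gain = 3)
  gated <- apply_gates(w, tree)
  expect_identical(gated$subset, attr(w, "true_subset"))
})

test_that("degenerate trees leave everything ungated", {
  gt <- small_gt()
  w <- simulate_well(gt, "M01", n_events = 1000, seed = 1)
  empty <- gate_tree(list())
  expect_true(all(apply_gates(w, empty)$subset == "ungated"))

  inf_root <- gate_tree(list(
    rule = list(channel = "CD45", threshold = Inf, side = "above"),
    children = list(list(rule = list(channel = "BB_S1", threshold = 0,
                                     side = "above"), subset = "S1"))
  ))
  expect_true(all(apply_gates(w, inf_root)$subset == "ungated"))
})

test_that("missing gate channels raise a config error naming them", {
  gt <- small_gt()
  w <- simulate_well(gt, "M01", n_events = 500, seed = 1)
  tree <- gate_tree(list(children = list(
    list(rule = list(channel = "CD99", threshold = 1, side = "above"),
         subset = "X"))))
  expect_error(apply_gates(w, tree), "CD99", class = "flowabc_config_error")
})

test_that("rectangle rules gate two channels jointly", {
  events <- tibble::tibble(A = c(1, 5, 5, 9), B = c(5, 5, 9, 5))
  tree <- gate_tree(list(children = list(
    list(rule = list(channel_x = "A", xmin = 4, xmax = 6,
                     channel_y = "B", ymin = 4, ymax = 6),
         subset = "mid"))))
  expect_equal(apply_gates(events, tree)$subset,
               c("ungated", "mid", "ungated", "ungated"))
})

test_that("the leukocyte-count QC rule is exact at the printed threshold", {
  make_events <- function(n) tibble::tibble(CD45 = rep(5000, n))
  fail <- qc_sample(make_events(499999))
  expect_false(fail$pass)
  expect_true("leukocyte-count" %in% fail$reasons)
  pass <- qc_sample(make_events(500000))
  expect_true(pass$pass)
  expect_length(pass$reasons, 0)
})

test_that("CD45 drift trips QC; constant CD45 does not", {
  steady <- tibble::tibble(CD45 = rep(5000, 10000))
  expect_true(qc_sample(steady, min_events = 1000)$pass)

  drifting <- tibble::tibble(
    CD45 = c(rep(5000, 9000), rep(2000, 1000))  # last block 60% below median
  )
  res <- qc_sample(drifting, min_events = 1000)
  expect_false(res$pass)
  expect_true("cd45-drift" %in% res$reasons)
})

test_that("the 100-cell filter drops and logs small subsets", {
  counts <- tibble::tibble(subset = c("A", "B", "C"), n = c(99L, 100L, 5000L))
  kept <- suppressMessages(filter_min_cells(counts))
  expect_setequal(kept$subset, c("B", "C"))
  expect_message(filter_min_cells(counts), "A \\(n=99\\)")

  all_ok <- tibble::tibble(subset = c("A", "B"), n = c(100L, 200L))
  expect_equal(nrow(filter_min_cells(all_ok)), 2)

  all_small <- tibble::tibble(subset = "A", n = 10L)
  expect_warning(suppressMessages(filter_min_cells(all_small)),
                 "no records retained")
})

test_that("the FMO cutoff is the 99.5th percentile tail", {
  x <- withr::with_seed(1, rlnorm(100000, log(450), 0.25))
  cut <- positivity_cutoff(x)
  expect_equal(cut, quantile(x, 0.995, type = 7, names = FALSE))
  # definitional tail mass: the FMO against its own cutoff is ~0.5% positive
  expect_equal(100 * mean(x > cut), 0.5, tolerance = 0.05)
  expect_equal(positivity_cutoff(rep(1, 1000)), 1)
  expect_warning(res <- positivity_cutoff(rnorm(50) + 10), "unavailable")
  expect_true(is.na(res))
})

test_that("subset statistics match direct enumeration", {
  s <- subset_statistics(1:100, cutoff = 90)
  expect_equal(s$p50, 50.5)
  expect_equal(s$median, 50.5)
  expect_equal(s$pct_positive, 10)
  expect_equal(s$p10, quantile(1:100, 0.1, names = FALSE))
  expect_equal(s$cv, sd(1:100) / mean(1:100))

  const <- subset_statistics(rep(7, 150), cutoff = 10)
  expect_equal(const$median, 7)
  expect_equal(const$mean, 7)
  expect_equal(const$mode, 7)
  expect_equal(const$cv, 0)
  expect_true(all(c(const$p10, const$p25, const$p75, const$p90) == 7))
})

test_that("quantile ordering holds and n >= 100 is enforced", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rlnorm(500, 5, 1))
    s <- subset_statistics(x, cutoff = median(x))
    expect_true(s$p10 <= s$p25 && s$p25 <= s$p50 &&
                  s$p50 <= s$p75 && s$p75 <= s$p90)
  }
  expect_error(subset_statistics(1:99, cutoff = 50),
               class = "flowabc_invalid_argument")
})

test_that("percent positive is invariant to monotone transforms", {
  x <- withr::with_seed(2, rlnorm(1000, 3, 1))
  cut <- quantile(x, 0.7, names = FALSE)
  p1 <- subset_statistics(x, cut)$pct_positive
  p2 <- subset_statistics(log1p(x) * 10, log1p(cut) * 10)$pct_positive
  expect_equal(p1, p2)
})

test_that("ABC columns convert through the curve and correction", {
  curve <- identity_curve()
  x <- rep(c(500, 1500), 100)
  s <- subset_statistics(x, cutoff = 1000, curve = curve, factor = 2)
  expect_equal(s$median_abc, s$median / 2, tolerance = 1e-9)
  expect_equal(s$p90_abc, s$p90 / 2, tolerance = 1e-9)
})
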