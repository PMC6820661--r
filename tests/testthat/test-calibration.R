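test_that("noiseless bead peaks are found exactly", {
  pe <- rep(c(10, 100, 1000, 10000), each = 250)
  beads <- new_event_table(tibble::tibble(PE = pe),
                           meta = list(marker = "beads"))
  expect_equal(find_bead_peaks(beads), c(10, 100, 1000, 10000))
})

test_that("noisy bead peaks land within 3% of the true centres", {
  lot <- bead_lot(c(474, 5359, 23843, 62336))
  beads <- simulate_bead_set(lot, noise_cv = 0.1, n_events = 20000, seed = 2)
  peaks <- find_bead_peaks(beads)
  expect_equal(peaks / lot$pe_per_bead, rep(1, 4), tolerance = 0.03)
})

test_that("two-level beads cannot yield four peaks", {
  pe <- rep(c(100, 10000), each = 2000) *
    withr::with_seed(1, rlnorm(4000, 0, 0.1))
  beads <- new_event_table(tibble::tibble(PE = pe),
                           meta = list(marker = "beads"))
  expect_error(find_bead_peaks(beads, k = 4),
               class = "flowabc_degenerate_peaks")
})

test_that("calibration fits identity and pure-gain curves exactly", {
  lot <- bead_lot()
  ident <- fit_calibration(lot$pe_per_bead, lot)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-10)
  expect_equal(ident$fit_r2, 1, tolerance = 1e-12)

  gain2 <- fit_calibration(2 * lot$pe_per_bead, lot)
  expect_equal(gain2$slope, 1, tolerance = 1e-12)
  expect_equal(gain2$intercept, -log10(2), tolerance = 1e-10)
  expect_error(fit_calibration(c(-1, 2, 3, 4), lot),
               class = "flowabc_invalid_argument")
})

test_that("calibration equals the closed-form normal equations", {
  lot <- bead_lot()
  peaks <- withr::with_seed(42, lot$pe_per_bead * exp(rnorm(4, 0, 0.05)))
  peaks <- sort(peaks)
  curve <- fit_calibration(peaks, lot)
  x <- log10(peaks); y <- log10(lot$pe_per_bead)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(curve$slope, slope, tolerance = 1e-12)
  expect_equal(curve$intercept, intercept, tolerance = 1e-12)
})

test_that("fluorescence converts to ABC monotonically and exactly", {
  ident <- identity_curve()
  expect_equal(fluorescence_to_abc(ident, 1000), 1000, tolerance = 1e-9)
  lot <- bead_lot()
  gain2 <- fit_calibration(2 * lot$pe_per_bead, lot)
  expect_equal(fluorescence_to_abc(gain2, 2000), 1000, tolerance = 1e-9)
  mfi <- sort(withr::with_seed(3, runif(50, 1, 1e5)))
  expect_true(all(diff(fluorescence_to_abc(ident, mfi)) > 0))
  expect_error(fluorescence_to_abc(ident, 0),
               class = "flowabc_invalid_argument")
})

test_that("correction factors follow the median-of-medians ratio rule", {
  one <- correction_factors(c(A = 100))
  expect_equal(one$factor, 1)
  expect_false(one$flagged)

  three <- correction_factors(c(A = 50, B = 100, C = 200))
  expect_equal(three$factor, c(0.5, 1, 2))
  expect_equal(three$flagged, c(TRUE, FALSE, TRUE))

  # the flag rule is strictly < 0.7 or > 1.3: boundary values stay unflagged
  boundary <- correction_factors(c(A = 80, B = 100, C = 130))
  expect_equal(boundary$factor, c(0.8, 1, 1.3))
  expect_false(any(boundary$flagged))
})

test_that("a single-replicate factor set always has median 1", {
  for (seed in 1:10) {
    meds <- withr::with_seed(seed, 10^runif(7, 2, 5))
    tab <- correction_factors(setNames(meds, paste0("M", 1:7)))
    expect_equal(median(tab$factor), 1, tolerance = 1e-12)
  }
})

test_that("replicates average after discarding discordant measurements", {
  tab <- correction_factors(tibble::tibble(
    marker = c("A", "A", "A", "B"),
    median_pe = c(100, 104, 160, 100)
  ))
  a <- tab[tab$marker == "A", ]
  expect_equal(a$n_replicates, 3L)
  # 160 is > 1 SD from the replicate mean and is excluded; A's factor is the
  # mean of the two concordant replicate ratios
  grand <- median(c(100, 104, 160, 100))
  expect_equal(a$factor, mean(c(100, 104) / grand), tolerance = 1e-12)
})

test_that("applying a correction divides the ABC", {
  expect_equal(apply_correction(1000, 1), 1000)
  expect_equal(apply_correction(1000, 2), 500)
  expect_error(apply_correction(1000, 0), class = "flowabc_invalid_argument")
})
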