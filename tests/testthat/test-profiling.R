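make_records <- function() {
  tibble::tibble(
    marker = rep(c("M1", "M2"), each = 3),
    subset = "S1",
    donor = rep(c("D1", "D2", "D3"), 2),
    median_abc = c(1000, 2000, 4000, 100, 100, 400),
    pct_positive = c(90, 95, 92, 10, 12, 11)
  )
}

test_that("donor aggregation takes medians and keeps dispersion", {
  map <- aggregate_donors(make_records())
  long <- tidy(map)
  m1 <- long[long$marker == "M1", ]
  expect_equal(m1$abc, 2000)
  expect_equal(m1$abc_mean, mean(c(1000, 2000, 4000)), tolerance = 1e-9)
  expect_equal(m1$pct_pos, 92)
  expect_equal(m1$n_donors, 3L)
})

test_that("aggregation is invariant to donor order and single donors give NA CV", {
  rec <- make_records()
  map1 <- aggregate_donors(rec)
  map2 <- aggregate_donors(rec[sample(nrow(rec)), ])
  expect_equal(tidy(map1), tidy(map2))

  single <- rec[rec$donor == "D1", ]
  m <- tidy(aggregate_donors(single))
  expect_equal(m$abc, c(1000, 100))
  expect_true(all(is.na(m$cv_donor)))
})

test_that("expression matrices mark empty cells as missing, not zero", {
  rec <- make_records()
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec[1:3, ], subset = "S2"))
  m <- expr_matrix(aggregate_donors(rec2), "abc")
  expect_true(is.na(m["M2", "S2"]))
  expect_equal(m["M1", "S2"], 2000)
})

test_that("CV across subsets follows the documented sample-SD convention", {
  rec <- tidyr::expand_grid(marker = "M1", subset = c("S1", "S2", "S3"),
                            donor = "D1") |>
    dplyr::mutate(median_abc = c(100, 100, 400), pct_positive = 50)
  prof <- cv_profile(aggregate_donors(rec), "across_subsets")
  expect_equal(prof$cv, sd(c(100, 100, 400)) / mean(c(100, 100, 400)))
  expect_equal(prof$cv, 0.866, tolerance = 1e-3)

  rec10 <- dplyr::mutate(rec, median_abc = median_abc * 10)
  prof10 <- cv_profile(aggregate_donors(rec10), "across_subsets")
  expect_equal(prof10$cv, prof$cv, tolerance = 1e-12)

  const <- dplyr::mutate(rec, median_abc = 300)
  expect_equal(cv_profile(aggregate_donors(const), "across_subsets")$cv, 0)
})

test_that("noiseless logistic data is recovered to high precision", {
  cds <- 1:100
  y <- 100 / (1 + exp(-0.3 * (cds - 50)))
  fit <- fit_sigmoid(setNames(y, sprintf("M%03d", cds)))
  expect_true(fit$converged)
  expect_equal(fit$pe_max, 100, tolerance = 1e-3)
  expect_equal(fit$cds_mid, 50, tolerance = 1e-3)
  expect_equal(fit$a1, 0.3, tolerance = 1e-3)
  expect_equal(fit$slope_mid, 7.5, tolerance = 1e-2)
})

test_that("the midpoint-slope identity holds to machine precision", {
  cds <- 1:60
  y <- pmin(pmax(80 / (1 + exp(-0.2 * (cds - 30))) +
                   withr::with_seed(4, rnorm(60, 0, 2)), 0), 100)
  fit <- fit_sigmoid(setNames(y, sprintf("M%03d", cds)))
  # analytic derivative of the fitted logistic at its midpoint
  d_analytic <- fit$a1 * fit$pe_max / 4
  expect_equal(fit$slope_mid, d_analytic, tolerance = 1e-12)
  h <- 1e-6
  f <- function(c) fit$pe_max / (1 + exp(-fit$a1 * (c - fit$cds_mid)))
  expect_equal((f(fit$cds_mid + h) - f(fit$cds_mid - h)) / (2 * h),
               fit$slope_mid, tolerance = 1e-6)
})

test_that("noisy logistic parameters are recovered within 5% (median over seeds)", {
  cds <- 1:100
  truth <- c(pe_max = 100, cds_mid = 50, a1 = 0.3)
  errs <- sapply(1:100, function(seed) {
    y <- 100 / (1 + exp(-0.3 * (cds - 50))) +
      withr::with_seed(seed, rnorm(100, 0, 2))
    y <- pmin(pmax(y, 0), 100)
    fit <- fit_sigmoid(setNames(y, sprintf("M%03d", cds)))
    abs(c(fit$pe_max, fit$cds_mid, fit$a1) / truth - 1)
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
  expect_lt(median(errs[3, ]), 0.05)
})

test_that("degenerate all-zero sequences classify everything negative", {
  fit <- fit_sigmoid(setNames(rep(0, 15), sprintf("M%02d", 1:15)))
  expect_false(fit$converged)
  expect_true(all(fit$data$class == "negative"))
})

test_that("marker ranking breaks ties stably by marker id", {
  y <- setNames(c(5, 5, 5, 1, 2, 3, 4, 6, 7, 8, 9, 10),
                c("Mc", "Ma", "Mb", sprintf("Mz%d", 1:9)))
  fit <- fit_sigmoid(y)
  tied <- fit$data[fit$data$pct_pos == 5, ]
  expect_equal(tied$marker, c("Ma", "Mb", "Mc"))
})
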