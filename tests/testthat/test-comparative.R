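planted_matrix <- function(n_markers = 30, seed = 5, contrast = 50) {
  # 3 lineage blocks of subsets with block-specific high markers
  withr::with_seed(seed, {
    subsets <- sprintf("S%d", 1:9)
    block <- rep(1:3, each = 3)
    markers <- sprintf("M%02d", seq_len(n_markers))
    mblock <- rep_len(1:3, n_markers)
    m <- matrix(10^runif(n_markers * 9, 2, 3), n_markers, 9,
                dimnames = list(markers, subsets))
    for (i in seq_len(n_markers)) {
      hi <- block == mblock[i]
      m[i, hi] <- m[i, hi] * contrast
    }
    list(m = m, block = setNames(block, subsets))
  })
}

test_that("the transform chain z-scores every retained marker", {
  pm <- planted_matrix()
  tm <- transform_expression(pm$m)
  expect_equal(unname(rowMeans(tm)), rep(0, nrow(tm)), tolerance = 1e-12)
  expect_equal(unname(apply(tm, 1, sd)), rep(1, nrow(tm)), tolerance = 1e-12)
  expect_equal(attr(tm, "transform_log")$shift, 0)  # all-positive: no shift
})

test_that("the shift raises a non-positive minimum strictly above zero", {
  m <- matrix(c(-3, 1, 5, 2, 8, 4), 2, 3,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  tm <- transform_expression(m)
  expect_equal(attr(tm, "transform_log")$shift, 4)  # 1 - (-3)
  expect_equal(nrow(tm), 2)
})

test_that("missing values and FMO rows are removed per the transform rule", {
  pm <- planted_matrix()
  m <- pm$m
  m["M03", "S2"] <- NA
  m <- rbind(m, FMO = rep(500, ncol(m)))
  tm <- transform_expression(m)
  expect_false("M03" %in% rownames(tm))
  expect_false("FMO" %in% rownames(tm))
  lg <- attr(tm, "transform_log")
  expect_equal(lg$dropped_markers_missing, "M03")
  expect_equal(lg$dropped_fmo, "FMO")
})

test_that("zero-variance markers are dropped with a warning", {
  pm <- planted_matrix()
  m <- pm$m
  m["M01", ] <- 1000
  expect_warning(tm <- transform_expression(m), "M01")
  expect_false("M01" %in% rownames(tm))
})

test_that("clustering recovers planted lineage blocks exactly", {
  skip_if_not_installed("mclust")
  pm <- planted_matrix(contrast = 50)
  tm <- transform_expression(pm$m)
  res <- hca(tm, k = 3)
  ari <- mclust::adjustedRandIndex(res$labels[names(pm$block)], pm$block)
  expect_equal(ari, 1)
})

test_that("duplicated subsets merge at height zero and k = n isolates all", {
  pm <- planted_matrix()
  m <- cbind(pm$m, S1copy = pm$m[, "S1"])
  tm <- transform_expression(m)
  res <- hca(tm, k = 2)
  expect_equal(min(res$tree$height), 0)
  pair <- cutree(res$tree, h = 0)
  expect_equal(pair[["S1"]], pair[["S1copy"]])

  res_n <- hca(tm, k = ncol(tm))
  expect_equal(length(unique(res_n$labels)), ncol(tm))
  expect_error(hca(tm, k = ncol(tm) + 1), class = "flowabc_invalid_argument")
})

test_that("merge heights are monotone non-decreasing", {
  pm <- planted_matrix(seed = 11)
  res <- hca(transform_expression(pm$m), k = 3)
  expect_true(all(diff(res$tree$height) >= -1e-12))
})

test_that("scaling raw ABC by a positive constant leaves clustering unchanged", {
  pm <- planted_matrix(seed = 7)
  t1 <- transform_expression(pm$m)
  t2 <- transform_expression(pm$m * 37.5)
  expect_equal(t1, t2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rank-sum p-values match exact enumeration for small groups", {
  for (seed in 1:20) {
    na <- withr::with_seed(seed, sample(3:6, 1))
    nb <- withr::with_seed(seed + 99, sample(3:6, 1))
    a <- withr::with_seed(seed + 200, rlnorm(na, 7, 1))
    b <- withr::with_seed(seed + 300, rlnorm(nb, 8, 1))
    dat <- tibble::tibble(
      marker = "M1",
      group = rep(c("A", "B"), c(na, nb)),
      value = c(a, b)
    )
    dt <- differential_markers(dat)
    expect_equal(dt$p_value, enum_ranksum_p(a, b), tolerance = 1e-9)
  }
})

test_that("identical groups are never significant", {
  v <- c(100, 200, 300, 400, 500)
  dat <- tibble::tibble(marker = "M1", group = rep(c("A", "B"), each = 5),
                        value = rep(v, 2))
  dt <- differential_markers(dat)
  expect_equal(dt$tier, "ns")
  expect_gte(dt$p_value, 0.9)
})

test_that("fully separated 9 vs 9 groups reach the exact extreme p", {
  dat <- tibble::tibble(marker = "M1", group = rep(c("A", "B"), each = 9),
                        value = c(1:9 * 100, 1:9 * 100000))
  dt <- differential_markers(dat)
  expect_equal(dt$p_value, 2 / choose(18, 9), tolerance = 1e-9)
  expect_equal(dt$tier, "p<0.001")
})

test_that("fold-change thresholding is exact and symmetric", {
  mk <- function(ma, mb) tibble::tibble(
    marker = "M1", group = rep(c("A", "B"), each = 3),
    value = c(rep(ma, 3), rep(mb, 3)))
  expect_true(differential_markers(mk(1000, 100))$passes_fold10)
  expect_false(differential_markers(mk(1000, 101))$passes_fold10)
  expect_true(differential_markers(mk(100, 1000))$passes_fold10)  # symmetric
})

test_that("markers with too few donors are untested, never significant", {
  dat <- tibble::tibble(marker = "M1", group = c("A", "A", "B", "B", "B"),
                        value = c(1, 2, 1000, 2000, 3000))
  dt <- differential_markers(dat)
  expect_equal(dt$tier, "untested")
  expect_true(is.na(dt$p_value))
})

test_that("drop-plot data equals the map restricted to the requested orders", {
  rec <- tidyr::expand_grid(marker = c("M1", "M2"), subset = c("S1", "S2"),
                            donor = c("D1", "D2")) |>
    dplyr::mutate(median_abc = 10^(2 + dplyr::row_number() / 4),
                  pct_positive = c(0, 0, 25, 25, 50, 50, 100, 100))
  map <- aggregate_donors(rec)
  dat <- drop_plot_data(map, subsets = c("S2", "S1"), markers = c("M2", "M1"))
  expect_equal(levels(dat$subset), c("S2", "S1"))
  expect_setequal(as.character(dat$marker), c("M1", "M2"))
  expect_equal(nrow(dat), 4)
  expect_error(drop_plot_data(map, subsets = "S9"),
               class = "flowabc_config_error")
  expect_s3_class(plot_drop(map), "ggplot")
})

test_that("maturation profiles preserve and reverse with the subset order", {
  rec <- tidyr::expand_grid(marker = "M1", subset = c("S1", "S2", "S3"),
                            donor = "D1") |>
    dplyr::mutate(median_abc = c(100, 1000, 10000), pct_positive = 50)
  map <- aggregate_donors(rec)
  fwd <- maturation_profile(map, c("S1", "S2", "S3"))
  rev <- maturation_profile(map, c("S3", "S2", "S1"))
  expect_equal(fwd$abc, c(100, 1000, 10000))
  expect_equal(rev$abc, c(10000, 1000, 100))
  single <- maturation_profile(map, "S2")
  expect_equal(nrow(single), 1)
  expect_error(maturation_profile(map, "S9"), class = "flowabc_config_error")
})
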