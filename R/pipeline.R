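# End-to-end orchestration: one validated run configuration drives
# simulation, calibration, gating, statistics, modelling, comparison and the
# static report. Everything is a pure function of (config, seed).

run_config_defaults <- function() {
  list(
    # synthetic resource
    n_markers = 20L, n_subsets = 6L, n_lineage_blocks = 3L, n_donors = 5L,
    n_events = 100000L, noise_cv = 0.25, gain = 2, tissue = "blood",
    bead_events = 10000L, bead_noise_cv = 0.1,
    conj_events = 10000L, conj_noise_cv = 0.1, conj_bead_capacity = 2e4,
    # analysis options
    cutoff_percentile = 0.995, min_cells = 100L,
    qc_min_events = 50000L, qc_cd45_threshold = 1000,
    qc_drift_blocks = 10L, qc_drift_tol = 0.3,
    neg_frac = 0.1, pos_frac = 0.9,
    hca_k = 5L, diff_test = "ranksum", fold_min = 10,
    diff_subsets = NULL,                # default: first two subsets
    seed = 1L
  )
}

#' Build and validate a run configuration
#'
#' Returns the full configuration of a pipeline run: the synthetic-resource
#' parameters (markers, subsets, donors, events per well, noise, gain), the
#' analysis options (FMO cutoff percentile, minimum cell count, QC rules,
#' sigmoid class thresholds, clustering k, comparison test) and the seed.
#' Every field not supplied keeps its default and is echoed into the run
#' manifest; unknown fields raise a schema error naming the field.
#'
#' The default QC event minimum scales with acquisition depth: the 500,000
#' leukocyte-event rule corresponds to million-event acquisitions, so the
#' default 100,000-event wells use the same 50% fraction.
#'
#' @param ... Named fields overriding the defaults (see
#'   `flowabc:::run_config_defaults()` for the full list).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste("Unknown configuration field(s):", paste(unknown, collapse = ", ")),
          class = "flowabc_config_error")
  }
  cfg <- utils::modifyList(defaults, user)
  for (f in c("n_markers", "n_subsets", "n_lineage_blocks", "n_donors",
              "n_events", "bead_events", "conj_events", "min_cells", "hca_k")) {
    cfg[[f]] <- check_count(cfg[[f]], f)
  }
  cfg$noise_cv <- check_fraction(cfg$noise_cv, "noise_cv")
  cfg$gain <- check_positive(cfg$gain, "gain")
  cfg$cutoff_percentile <- check_fraction(cfg$cutoff_percentile, "cutoff_percentile")
  if (!cfg$diff_test %in% c("ranksum", "t_log10")) {
    abort("`diff_test` must be 'ranksum' or 't_log10'.",
          class = "flowabc_config_error")
  }
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  structure(cfg, class = "run_config")
}

experiment_lot <- function(cfg) bead_lot()

#' Simulate a complete experiment to disk
#'
#' Writes the full synthetic fixture experiment for a configuration: one CSV
#' event table per stained well (marker x donor), one FMO well per donor, the
#' calibration-bead well, one conjugation-bead well per marker, the bead lot
#' sheet, the persisted ground truth and a JSON manifest echoing the
#' configuration. Byte-identical across repeated calls with the same
#' configuration.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
simulate_experiment <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wells_dir <- file.path(dir, "wells")
  dir.create(wells_dir, showWarnings = FALSE)

  gt <- experiment_ground_truth(config)
  write_ground_truth(gt, file.path(dir, "ground_truth"))

  lot <- experiment_lot(config)
  write_lot_sheet(lot, file.path(dir, "bead_lot.tsv"))
  beads <- simulate_bead_set(lot, gain = config$gain,
                             noise_cv = config$bead_noise_cv,
                             n_events = config$bead_events, seed = config$seed)
  write_events(beads, file.path(dir, "beads.csv"))

  conj <- simulate_conjugation_beads(gt, seed = config$seed,
                                     bead_capacity = config$conj_bead_capacity,
                                     noise_cv = config$conj_noise_cv,
                                     n_events = config$conj_events,
                                     gain = config$gain)
  for (m in names(conj)) {
    write_events(conj[[m]], file.path(wells_dir, paste0("conj_", m, ".csv")))
  }

  donors <- sprintf("D%d", seq_len(config$n_donors))
  for (d in donors) {
    for (m in c(rownames(gt$abc_true), "FMO")) {
      w <- simulate_well(gt, m, n_events = config$n_events,
                         noise_cv = config$noise_cv, seed = config$seed,
                         gain = config$gain, donor_id = d,
                         tissue = config$tissue)
      write_events(w, file.path(wells_dir, paste0(d, "_", m, ".csv")))
    }
  }

  manifest <- c(unclass(config),
                list(config_hash = rlang::hash(unclass(config)),
                     n_wells = config$n_donors * (config$n_markers + 1L)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

experiment_ground_truth <- function(config) {
  generate_ground_truth(config$n_markers, config$n_subsets,
                        config$n_lineage_blocks, seed = config$seed)
}

# shared per-well reduction: gate, count-filter, cut-offs, statistics
process_stained_well <- function(well, cfg, tree, cutoffs, curve, corr) {
  meta <- event_meta(well)
  marker <- meta$marker
  donor <- meta$donor_id
  qc <- qc_sample(well, cd45_threshold = cfg$qc_cd45_threshold * cfg$gain,
                  min_events = cfg$qc_min_events,
                  n_blocks = cfg$qc_drift_blocks, drift_tol = cfg$qc_drift_tol)
  if (!qc$pass) {
    return(list(stats = NULL,
                qc = tibble(well_id = meta$well_id, marker = marker,
                            donor = donor, pass = FALSE,
                            reasons = paste(qc$reasons, collapse = ";"))))
  }
  gated <- apply_gates(well, tree)
  counts <- gated |> count(subset = .data$subset) |>
    filter(.data$subset != "ungated")
  kept <- suppressMessages(filter_min_cells(counts, cfg$min_cells))

  factor <- corr$factor[match(marker, corr$marker)]
  if (is.na(factor)) factor <- 1

  rows <- lapply(kept$subset, function(s) {
    pe <- clean_values(gated$PE[gated$subset == s])
    cut <- cutoffs$cutoff[cutoffs$donor == donor & cutoffs$subset == s]
    cut <- if (length(cut) == 1) cut else NA_real_
    subset_statistics(pe, cut, curve = curve, factor = factor,
                      subset = s, marker = marker, donor = donor)
  })
  list(stats = dplyr::bind_rows(rows),
       qc = tibble(well_id = meta$well_id, marker = marker, donor = donor,
                   pass = TRUE, reasons = ""))
}

fmo_cutoffs_for <- function(fmo_well, cfg, tree) {
  meta <- event_meta(fmo_well)
  gated <- apply_gates(fmo_well, tree)
  subsets <- setdiff(unique(gated$subset), "ungated")
  purrr::map_dfr(subsets, function(s) {
    pe <- clean_values(gated$PE[gated$subset == s])
    cut <- suppressWarnings(
      positivity_cutoff(pe, percentile = cfg$cutoff_percentile)
    )
    tibble(donor = meta$donor_id, subset = s, cutoff = cut)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain — calibrate, correct, gate, QC, clean,
#' per-subset statistics, donor aggregation, positivity sigmoid and
#' turning-point models, hierarchical clustering and differential comparison
#' — either on an experiment directory written by [simulate_experiment()] or,
#' when `dir` is `NULL`, on wells simulated on the fly (well by well, so a
#' full-size experiment never sits in memory at once).
#'
#' @param config A [run_config()].
#' @param dir Optional experiment directory from [simulate_experiment()].
#' @param out_dir Optional output directory: per-donor flat statistics tables
#'   (tab-delimited, one per tube), expression matrices, model reports,
#'   cluster labels, the differential table and the run manifest are written
#'   there.
#' @return A `pipeline_result` list: `curve`, `correction`, `stats`, `map`,
#'   `sigmoid` and `turning` (per subset), `clusters`, `diff`, `qc`, `config`.
#' @export
run_pipeline <- function(config, dir = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  from_disk <- !is.null(dir)

  if (from_disk) {
    gt <- read_ground_truth(file.path(dir, "ground_truth"))
    lot <- read_lot_sheet(file.path(dir, "bead_lot.tsv"))
    beads <- read_events(file.path(dir, "beads.csv"))
  } else {
    gt <- experiment_ground_truth(cfg)
    lot <- experiment_lot(cfg)
    beads <- simulate_bead_set(lot, gain = cfg$gain,
                               noise_cv = cfg$bead_noise_cv,
                               n_events = cfg$bead_events, seed = cfg$seed)
  }
  markers <- rownames(gt$abc_true)
  subsets <- colnames(gt$abc_true)
  donors <- sprintf("D%d", seq_len(cfg$n_donors))

  # 1. calibration
  peaks <- find_bead_peaks(beads, k = length(lot$pe_per_bead))
  curve <- fit_calibration(peaks, lot)

  # 2. conjugation correction factors
  conj_median <- function(m) {
    tab <- if (from_disk) {
      read_events(file.path(dir, "wells", paste0("conj_", m, ".csv")))
    } else {
      simulate_conjugation_beads_one(gt, m, cfg)
    }
    median(tab$PE)
  }
  corr <- correction_factors(
    tibble(marker = markers,
           median_pe = vapply(markers, conj_median, numeric(1)))
  )

  tree <- default_gate_tree(subsets, gain = cfg$gain)

  get_well <- function(d, m) {
    if (from_disk) {
      read_events(file.path(dir, "wells", paste0(d, "_", m, ".csv")))
    } else {
      simulate_well(gt, m, n_events = cfg$n_events, noise_cv = cfg$noise_cv,
                    seed = cfg$seed, gain = cfg$gain, donor_id = d,
                    tissue = cfg$tissue)
    }
  }

  # 3. FMO cut-offs per donor and subset
  cutoffs <- purrr::map_dfr(donors, function(d) {
    fmo_cutoffs_for(get_well(d, "FMO"), cfg, tree)
  })

  # 4. stained wells -> per-(subset, marker, donor) statistics
  stats_rows <- list(); qc_rows <- list()
  for (d in donors) {
    for (m in markers) {
      res <- process_stained_well(get_well(d, m), cfg, tree, cutoffs, curve, corr)
      stats_rows[[paste(d, m)]] <- res$stats
      qc_rows[[paste(d, m)]] <- res$qc
    }
  }
  stats <- dplyr::bind_rows(stats_rows)
  qc <- dplyr::bind_rows(qc_rows)
  if (nrow(stats) == 0) {
    abort("No well passed quality control; nothing to analyse.",
          class = "flowabc_data_error")
  }

  # 5. aggregate across donors
  map <- aggregate_donors(stats)

  # 6. per-subset models
  sigmoid <- lapply(setNames(map$subsets, map$subsets), function(s) {
    cell <- map$long |> filter(.data$subset == s) |>
      select("marker", pct_pos = "pct_pos")
    if (nrow(cell) >= 10) {
      fit_sigmoid(cell, neg_frac = cfg$neg_frac, pos_frac = cfg$pos_frac)
    } else NULL
  })
  turning <- lapply(setNames(map$subsets, map$subsets), function(s) {
    ord <- map$long |> filter(.data$subset == s) |>
      arrange(.data$abc, .data$marker)
    if (nrow(ord) >= 3) {
      turning_point(tibble(rank = seq_len(nrow(ord)), value = ord$abc))
    } else NULL
  })

  # 7. clustering and differential comparison
  tmat <- transform_expression(map)
  clusters <- hca(tmat, k = min(cfg$hca_k, ncol(tmat)))
  diff_subsets <- cfg$diff_subsets %||% map$subsets[1:2]
  diff <- stats |>
    filter(.data$subset %in% diff_subsets) |>
    transmute(marker = .data$marker, group = .data$subset,
              value = .data$median_abc) |>
    differential_markers(test = cfg$diff_test, fold_min = cfg$fold_min)

  result <- structure(
    list(config = cfg, curve = curve, correction = corr, cutoffs = cutoffs,
         stats = stats, qc = qc, map = map, sigmoid = sigmoid,
         turning = turning, clusters = clusters, diff = diff,
         ground_truth = gt),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# single-marker variant used by the streaming pipeline (same seeds as the
# full simulate_conjugation_beads call)
simulate_conjugation_beads_one <- function(gt, m, cfg) {
  withr::local_seed(derive_seed(cfg$seed, paste0("conj_", m)))
  pe <- rlnorm_med(cfg$conj_events,
                   cfg$conj_bead_capacity * gt$conj_factor_true[m] * cfg$gain,
                   cfg$conj_noise_cv)
  new_event_table(tibble(PE = pe),
                  meta = list(well_id = paste0("conj_", m), marker = m,
                              is_fmo = FALSE, gain = cfg$gain))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$stats), " subset-marker-donor records, ",
      sum(x$qc$pass), "/", nrow(x$qc), " wells passed QC\n", sep = "")
  print(x$curve)
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name))
  }
  # one flat statistics table per tube (donor plate)
  for (d in unique(result$stats$donor)) {
    tsv(result$stats |> filter(.data$donor == d),
        paste0("stats_", d, ".tsv"))
  }
  tsv(result$map$long, "expression_long.tsv")
  for (what in c("abc", "pct_pos")) {
    m <- expr_matrix(result$map, what)
    utils::write.table(m, file.path(out_dir, paste0("expression_", what, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  tsv(as_tibble(result$correction), "correction_factors.tsv")
  tsv(tidy(result$clusters), "cluster_labels.tsv")
  tsv(as_tibble(result$diff), "differential.tsv")
  tsv(result$qc, "well_qc.tsv")

  fits <- purrr::imap_dfr(result$sigmoid, function(f, s) {
    if (is.null(f)) return(tibble())
    glance(f) |> mutate(subset = s, .before = 1)
  })
  if (nrow(fits)) tsv(fits, "sigmoid_fits.tsv")
  knees <- purrr::imap_dfr(result$turning, function(tp, s) {
    if (is.null(tp)) return(tibble())
    tibble(subset = s, index = tp$index, curvature = tp$curvature)
  })
  if (nrow(knees)) tsv(knees, "turning_points.tsv")

  manifest <- c(unclass(result$config),
                list(config_hash = rlang::hash(unclass(result$config)),
                     package_version = as.character(utils::packageVersion("flowabc")),
                     calibration = list(slope = result$curve$slope,
                                        intercept = result$curve$intercept,
                                        r2 = result$curve$fit_r2)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Write a static analysis report
#'
#' Renders a markdown report with the pipeline's standard views: the drop
#' plot, per-subset ordered expression/positivity profiles with the sigmoid
#' fit, CV profiles, the clustering dendrogram, the differential table and a
#' maturation profile over a configured subset order. Figure files are
#' written next to the report. Sections whose inputs are missing are skipped
#' with a notice in the report; regeneration is idempotent.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Report directory.
#' @param maturation_order Optional subset sequence for the maturation
#'   section; defaults to the map's subsets in order.
#' @return Path of the report file, invisibly.
#' @export
write_report <- function(result, dir, maturation_order = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Quantitative immunophenotyping report", "")
  fig <- function(plot, name, width = 7, height = 5) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    name
  }
  section <- function(title, body) {
    lines <<- c(lines, paste("##", title), "", body, "")
  }
  skip <- function(title, why) {
    lines <<- c(lines, paste("##", title), "",
                paste0("_Section skipped: ", why, "_"), "")
  }

  if (!is.null(result$map)) {
    section("Expression drop plot",
            paste0("![drop plot](", fig(plot_drop(result$map), "drop_plot.png"), ")"))
  } else skip("Expression drop plot", "no expression map available")

  ok_sig <- !vapply(result$sigmoid, is.null, logical(1))
  if (any(ok_sig)) {
    s <- names(result$sigmoid)[ok_sig][1]
    body <- c(
      paste0("Ordered profiles for subset ", s, "."),
      paste0("![ordered ABC](", fig(plot_ordered_profile(result$map, s, "abc"),
                                    "ordered_abc.png"), ")"),
      paste0("![sigmoid](", fig(autoplot(result$sigmoid[[s]]),
                                "sigmoid.png"), ")"))
    section("Ordered expression and positivity", body)
  } else skip("Ordered expression and positivity", "no converged sigmoid fit")

  if (!is.null(result$map)) {
    cvp <- cv_profile(result$map, "across_subsets")
    p <- ggplot(cvp, aes(x = stats::reorder(.data$marker, .data$cv),
                         y = .data$cv)) +
      geom_col() + coord_flip() +
      labs(x = NULL, y = "CV of median ABC across subsets") + theme_minimal()
    section("Expression heterogeneity (CV profiles)",
            paste0("![cv](", fig(p, "cv_profile.png"), ")"))
  } else skip("Expression heterogeneity (CV profiles)", "no expression map")

  if (!is.null(result$clusters)) {
    section("Hierarchical clustering",
            paste0("![dendrogram](", fig(autoplot(result$clusters),
                                         "dendrogram.png"), ")"))
  } else skip("Hierarchical clustering", "no clustering result")

  if (!is.null(result$diff) && nrow(result$diff)) {
    tab <- result$diff |> arrange(.data$p_value)
    body <- c(paste(names(tab), collapse = " | "),
              paste(rep("---", ncol(tab)), collapse = " | "),
              apply(tab, 1, function(r) paste(r, collapse = " | ")))
    section("Differential markers", body)
  } else skip("Differential markers", "no differential table")

  if (!is.null(result$map)) {
    ord <- maturation_order %||% result$map$subsets
    section("Maturation profiles",
            paste0("![maturation](", fig(plot_maturation(result$map, ord),
                                         "maturation.png"), ")"))
  } else skip("Maturation profiles", "no expression map")

  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
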