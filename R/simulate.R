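#' Construct an event table
#'
#' An event table is a tibble with one row per acquired cell (or bead) and one
#' column per fluorescence channel, carrying well metadata as attributes.
#' Channel values are in arbitrary instrument fluorescence units; acquisition
#' order is row order.
#'
#' @param channels A data frame of per-event channel values (all numeric).
#' @param meta A named list of well metadata. Exactly one of `marker` (the
#'   drop-in marker id) or `is_fmo = TRUE` must identify the stain; other
#'   recognised fields are `well_id`, `donor_id`, `tissue`, `tube_id`.
#' @return A tibble of class `event_table`.
#' @export
new_event_table <- function(channels, meta = list()) {
  channels <- as_tibble(channels)
  if (!all(vapply(channels, is.numeric, logical(1)))) {
    abort("All channel columns must be numeric.",
          class = "flowabc_invalid_argument")
  }
  meta$is_fmo <- isTRUE(meta$is_fmo)
  has_marker <- !is.null(meta$marker) && !is.na(meta$marker)
  if (has_marker == meta$is_fmo) {
    abort("Exactly one of `marker` or `is_fmo = TRUE` must be set in `meta`.",
          class = "flowabc_invalid_argument")
  }
  structure(channels,
            meta = meta,
            class = c("event_table", class(channels)))
}

#' Well metadata of an event table
#' @param x An `event_table`.
#' @return The named metadata list.
#' @export
event_meta <- function(x) attr(x, "meta", exact = TRUE)

#' @export
print.event_table <- function(x, ...) {
  m <- event_meta(x)
  cat("<event_table> ", nrow(x), " events, ", ncol(x), " channels (",
      paste(names(x), collapse = ", "), ")\n", sep = "")
  if (!is.null(m)) {
    stain <- if (isTRUE(m$is_fmo)) "FMO" else m$marker
    cat("well: ", m$well_id %||% "?", "  stain: ", stain %||% "?",
        "  donor: ", m$donor_id %||% "?", "\n", sep = "")
  }
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# channel naming scheme shared by the simulator and the default gate tree
backbone_channel <- function(subset) paste0("BB_", subset)

#' Simulate one acquisition well
#'
#' Draws `n_events` cells from the subset mixture of a ground-truth design and
#' synthesises their fluorescence. Backbone channels follow a bimodal lo/hi
#' template (each subset is high on its own backbone channel only, with a
#' 10-fold default separation so threshold gates recover membership), a CD45
#' channel is high on every leukocyte, and the PE channel carries additive
#' autofluorescence background plus, for cells positive for the drop-in
#' marker, a log-normal signal whose median is `abc_true * conj_factor_true`
#' (in ABC units) scaled into fluorescence by the instrument `gain`.
#' FMO wells (`marker = "FMO"`) contain background only in the PE channel.
#'
#' @param gt An [abc_ground_truth][generate_ground_truth] design.
#' @param marker A marker id present in `gt`, or `"FMO"`.
#' @param n_events Number of events to draw.
#' @param noise_cv Per-cell coefficient of variation of the PE signal and
#'   background, in (0, 1].
#' @param seed Integer seed.
#' @param gain Multiplicative instrument gain (fluorescence units per
#'   ABC-equivalent); calibration against beads measured at the same gain
#'   removes it.
#' @param backbone_cv CV of backbone/CD45 channels (kept small; gating
#'   robustness is not what the simulation probes).
#' @param backbone_low,backbone_high Lo/hi backbone template medians
#'   (fluorescence units before gain).
#' @param cd45_level CD45 channel median (before gain).
#' @param donor_id,tissue,well_id Metadata carried on the well.
#' @return An `event_table` with backbone channels, `CD45` and `PE`; the
#'   true per-event subset labels are stored in the `"true_subset"` attribute
#'   for use by recovery tests.
#' @export
simulate_well <- function(gt, marker, n_events, noise_cv = 0.25, seed = 1L,
                          gain = 1, backbone_cv = 0.1,
                          backbone_low = 100, backbone_high = 1000,
                          cd45_level = 5000,
                          donor_id = "D1", tissue = "blood", well_id = NULL) {
  stopifnot(inherits(gt, "abc_ground_truth"))
  n_events <- check_count(n_events, "n_events")
  noise_cv <- check_fraction(noise_cv, "noise_cv")
  gain <- check_positive(gain, "gain")
  is_fmo <- identical(marker, "FMO")
  if (!is_fmo && !marker %in% rownames(gt$abc_true)) {
    abort(sprintf("Unknown marker '%s'.", marker), class = "flowabc_lookup_error")
  }

  subsets <- colnames(gt$abc_true)
  withr::local_seed(derive_seed(seed, paste0("well_", marker, "_", donor_id)))

  subset_idx <- sample.int(length(subsets), n_events, replace = TRUE,
                           prob = gt$subset_mix)

  channels <- lapply(seq_along(subsets), function(j) {
    med <- ifelse(subset_idx == j, backbone_high, backbone_low) * gain
    rlnorm_med(n_events, med, backbone_cv)
  })
  names(channels) <- backbone_channel(subsets)
  channels$CD45 <- rlnorm_med(n_events, cd45_level * gain, backbone_cv)

  background <- rlnorm_med(n_events, gt$autofluor_abc[subset_idx] * gain,
                           noise_cv)
  if (is_fmo) {
    pe <- background
  } else {
    frac <- gt$frac_pos_true[marker, ]
    positive <- runif(n_events) < frac[subset_idx]
    signal_med <- gt$abc_true[marker, ] * gt$conj_factor_true[marker] * gain
    signal <- numeric(n_events)
    signal[positive] <- rlnorm_med(sum(positive),
                                   signal_med[subset_idx[positive]], noise_cv)
    pe <- background + signal
  }
  channels$PE <- pe

  well_id <- well_id %||%
    paste0(donor_id, "_", if (is_fmo) "FMO" else marker)
  out <- new_event_table(
    as_tibble(channels),
    meta = list(well_id = well_id, donor_id = donor_id, tissue = tissue,
                marker = if (is_fmo) NA_character_ else marker,
                is_fmo = is_fmo, gain = gain)
  )
  attr(out, "true_subset") <- subsets[subset_idx]
  out
}

#' Define a calibration bead lot
#'
#' @param pe_per_bead Four (or `k`) strictly ascending PE-molecule counts per
#'   bead, as printed on the lot sheet of a quantitation-bead kit.
#' @param proportions Mixture fractions of the bead populations (sum to 1).
#' @return A `bead_lot` object.
#' @examples
#' bead_lot()  # default four-level lot
#' @export
bead_lot <- function(pe_per_bead = c(474, 5359, 23843, 62336),
                     proportions = rep(1 / length(pe_per_bead),
                                       length(pe_per_bead))) {
  if (any(pe_per_bead <= 0) || is.unsorted(pe_per_bead, strictly = TRUE)) {
    abort("`pe_per_bead` must be strictly ascending and positive.",
          class = "flowabc_invalid_argument")
  }
  if (length(proportions) != length(pe_per_bead) ||
      abs(sum(proportions) - 1) > 1e-9 || any(proportions <= 0)) {
    abort("`proportions` must be positive and sum to 1.",
          class = "flowabc_invalid_argument")
  }
  structure(list(pe_per_bead = as.numeric(pe_per_bead),
                 proportions = as.numeric(proportions)),
            class = "bead_lot")
}

#' @export
print.bead_lot <- function(x, ...) {
  cat("<bead_lot> PE/bead:", paste(format(x$pe_per_bead), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a calibration bead acquisition
#'
#' Draws a mixture of `length(lot$pe_per_bead)` log-normal bead populations
#' whose PE medians are `gain * pe_per_bead`.
#'
#' @param lot A [bead_lot].
#' @param gain Instrument gain (fluorescence units per PE molecule).
#' @param noise_cv Per-bead CV (may be 0 for idealised point masses).
#' @param n_events Number of bead events.
#' @param seed Integer seed.
#' @return An `event_table` with a single `PE` channel; the generating bead
#'   population of each event is stored in the `"true_component"` attribute.
#' @export
simulate_bead_set <- function(lot, gain = 1, noise_cv = 0.1, n_events = 10000,
                              seed = 1L) {
  stopifnot(inherits(lot, "bead_lot"))
  gain <- check_positive(gain, "gain")
  noise_cv <- check_fraction(noise_cv, "noise_cv", open_lo = FALSE)
  n_events <- check_count(n_events, "n_events")
  withr::local_seed(derive_seed(seed, "beads"))

  comp <- sample.int(length(lot$pe_per_bead), n_events, replace = TRUE,
                     prob = lot$proportions)
  pe <- if (noise_cv == 0) {
    gain * lot$pe_per_bead[comp]
  } else {
    rlnorm_med(n_events, gain * lot$pe_per_bead[comp], noise_cv)
  }
  out <- new_event_table(tibble(PE = pe),
                         meta = list(well_id = "beads", marker = "beads",
                                     is_fmo = FALSE, gain = gain))
  attr(out, "true_component") <- comp
  out
}

#' Simulate antibody-capture conjugation-check beads
#'
#' One single-population bead well per marker: antibody-capture beads
#' saturated with the PE-labelled antibody, so the PE median is proportional
#' to the antibody's true conjugation factor times a shared bead capacity.
#' These wells drive [correction_factors()] recovery.
#'
#' @param gt An [abc_ground_truth][generate_ground_truth] design (supplies
#'   `conj_factor_true` per marker).
#' @param seed Integer seed.
#' @param bead_capacity Shared antibody capacity of the beads (PE molecules at
#'   a 1:1 conjugation ratio).
#' @param noise_cv Per-bead CV.
#' @param n_events Bead events per marker.
#' @param gain Instrument gain.
#' @return A named list of single-channel `event_table`s, one per marker.
#' @export
simulate_conjugation_beads <- function(gt, seed = 1L, bead_capacity = 2e4,
                                       noise_cv = 0.1, n_events = 10000,
                                       gain = 1) {
  stopifnot(inherits(gt, "abc_ground_truth"))
  markers <- names(gt$conj_factor_true)
  out <- lapply(markers, function(m) {
    withr::local_seed(derive_seed(seed, paste0("conj_", m)))
    pe <- rlnorm_med(n_events, bead_capacity * gt$conj_factor_true[m] * gain,
                     noise_cv)
    new_event_table(tibble(PE = pe),
                    meta = list(well_id = paste0("conj_", m), marker = m,
                                is_fmo = FALSE, gain = gain))
  })
  setNames(out, markers)
}
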