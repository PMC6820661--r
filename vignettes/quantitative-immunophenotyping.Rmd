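---
title: "Bead-calibrated quantitative immunophenotyping with flowabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead-calibrated quantitative immunophenotyping with flowabc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(flowabc)
library(dplyr)
```

## The measurement model

flowabc analyses plate-based flow cytometry experiments in which each well
carries a fixed multicolour *backbone* antibody cocktail (used only to gate
leukocyte subsets) plus one variable PE-conjugated *drop-in* antibody against
a single surface marker. Because every drop-in reagent carries the same
fluorochrome in the same channel, expression of every marker is measured on a
common scale, and that scale can be made absolute: quantitation beads bearing
four known PE amounts are acquired alongside each experiment, a log–log
calibration line maps fluorescence to PE molecules, and — assuming ~1:1
PE:antibody conjugation — PE molecules per cell equal the antibody binding
capacity (ABC), the number of antibodies a cell binds.

The chain implemented here is:

1. **Calibration.** The bead well is clustered into its four levels (1-D
   k-means on log10 fluorescence with deterministic percentile
   initialisation) and ordinary least squares fits
   `log10(PE molecules) = slope * log10(F) + intercept`. The slope is fitted
   rather than fixed at 1 so instrument miscalibration is visible in the
   slope and R². Any common multiplicative instrument gain cancels exactly:
   scaling all fluorescence (cells and beads) by `g` shifts the intercept by
   `-slope * log10(g)` and leaves every ABC unchanged. This is the
   computational content of instrument standardisation.
2. **Conjugation correction.** Antibody-capture beads saturated with each
   PE conjugate measure the relative PE load per antibody. Each antibody's
   correction factor is its bead median divided by the median of all
   antibodies' medians; measured ABC is divided by the factor. Factors below
   0.7 or above 1.3 are flagged for re-measurement; when replicates exist,
   replicate factors farther than one SD from their mean are excluded and the
   rest averaged.
3. **Gating, QC and statistics.** Events are assigned to subsets by an
   axis-aligned gate tree; samples need at least the configured number of
   CD45-positive events and stable CD45 over acquisition time; subsets below
   100 cells are dropped; non-positive fluorescence values are set to 1;
   per-(subset, marker, donor) statistics are the median, mean, mode, CV and
   10/25/50/75/90th percentiles, in fluorescence and corrected ABC, plus the
   percentage of events above the FMO-derived positivity cutoff.
4. **Profiling.** Donor records aggregate by median into the markers ×
   subsets expression map. Per subset, markers ordered by rising positivity
   follow a three-parameter logistic `PE(cds) = PEmax / (1 + exp(-a1 (cds -
   cdsmid)))`, fitted by bounded Levenberg–Marquardt least squares; the slope
   at the midpoint is identically `a1 * PEmax / 4`. Markers ordered by rising
   expression get a knee estimate: the interior point of maximal Menger
   curvature (reciprocal circumradius) after min–max normalising both axes.
5. **Comparison.** For clustering, the ABC map is shifted strictly above
   zero if needed, log10-transformed, stripped of FMO rows and missing
   values, z-scored per marker, and clustered with Euclidean distance and
   Ward (ward.D2) linkage. Differential markers between two groups of donors
   use a two-sided Wilcoxon rank-sum test on donor-level median ABC with raw
   p < 0.01 / p < 0.001 tiers and a symmetric 10-fold-change flag.

## What the synthetic generator emulates

Real acquisitions of this design are distributed through an interactive web
resource rather than as raw event files, so the package ships a first-class,
seeded generator that reproduces the statistical structure the analysis
relies on:

- multi-subset samples with subset-specific backbone signatures (bimodal
  lo/hi templates with 10× separation, so threshold gating is exact by
  construction — gating robustness is deliberately not the object of study);
- per-subset, per-marker true ABC, log-uniform over 10²–10⁵ molecules/cell,
  organised in lineage blocks (a marker is high on its own block and at
  background elsewhere; a ubiquitous set is high everywhere) so cluster
  recovery has a known answer;
- additive autofluorescence background, 450 ABC-equivalents for lymphoid and
  3,000 for myeloid subsets — the centres of the reported 200–700 and
  1,000–10,000 "gray zones";
- log-normal per-cell signal with configurable CV (`sigma =
  sqrt(ln(1 + CV²))`, so the CV parameter is exact); per-cell CVs of real
  data are not published, and the default 0.25 is a fixture choice, not an
  estimate;
- four-level calibration beads and per-antibody conjugation factors drawn
  from a truncated normal centred on 1 (SD 0.15, range 0.7–1.3, matching the
  reported 0.73–1.32 band);
- FMO wells containing background only, identical in law to the background
  component of stained wells.

It does **not** simulate spillover/compensation, doublets, acquisition-time
drift (beyond what the QC hook needs), or the specific 8-colour panels of
the real study. Passing tests therefore demonstrate correctness of the
analysis chain under its stated assumptions, not robustness to instrument
artefacts the generator does not produce.

An important structural property: because correction factors are *ratios to
the cohort median*, corrected ABC is determined only up to the cohort's
median true conjugation ratio. The recoverable truth for a marker `m` on a
subset with background `B` is `med(conj) * (B / conj_m + ABC_true)`, and
that is what the recovery tests compare against. With factors centred on 1
this coincides with `B + ABC_true` up to a few percent.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff_percentile` | 0.995 | — | FMO positivity cutoff: a strict negative-control tail; the control defines negativity, the statistic is a convention and is configurable. Cutoffs are per subset because autofluorescence differs by lineage. |
| `min_cells` | 100 | cells | minimum subset size for statistical evaluation |
| `qc_min_events` | 50,000 | events | leukocyte-gate minimum; the published 500,000 rule corresponds to million-event acquisitions, and the default well depth here is 10⁵ events, so the same 50% fraction is kept. `qc_sample()` itself defaults to 500,000. |
| `qc_drift_tol` | 0.3 | relative | CD45 drift check: 10 acquisition-order blocks, any block median deviating >30% from the well median fails; an automated, logged stand-in for manual curation of clogging. |
| `noise_cv` | 0.25 | — | per-cell log-normal CV of PE signal and background |
| `gain` | 2 | F/ABC | instrument gain; calibration must (and does) remove it |
| `neg_frac`, `pos_frac` | 0.1, 0.9 | of PEmax | sigmoid class thresholds: negative/intermediate/positive by fitted plateau fraction — thresholds are config, since no published values exist |
| `hca_k` | 5 | clusters | dendrogram cut |
| `fold_min` | 10 | fold | symmetric fold-change flag threshold |

## Numerical and design choices

- **Quantiles** use linear interpolation between order statistics (R type 7),
  fixed so worked examples are exact. **CV** is sample SD (n−1) over mean
  throughout. **Mode** of a continuous sample is the midpoint of the tallest
  of 256 bins on log10 scale.
- **Menger curvature** is computed as `2 |cross| / (|pq| |qr| |rp|)` — the
  cross-product form is numerically stable near collinearity. The quantity
  equals 4·area/(product of side lengths) = 1/circumradius. Published
  renderings of this formula sometimes end the denominator in `|rq|`; with
  that literal reading the quantity is neither 1/circumradius nor
  rigid-motion invariant, so the standard `|rp|` form is used and treated as
  the intended one.
- **Axis normalisation before knee detection** is on by default: curvature
  is scale-dependent and rank units are incommensurable with ABC units. Ties
  in the curvature maximum break to the smallest index; an exactly linear
  sequence returns "no turning point" rather than an arbitrary index.
- **Sigmoid fitting** initialises at `PEmax = max(y)`, `cdsmid` = first
  half-max crossing, `a1 = 4 (max - min) / (n PEmax)`, with bounds
  `PEmax ∈ (0, 110]`, `a1 > 0`. Non-convergence yields a flagged degenerate
  record, never an error; an all-zero sequence classifies every marker
  negative.
- **Correction direction** is division: a factor above 1 means more PE per
  antibody, which inflates apparent ABC. The replicate rule is read as
  "re-measure flagged antibodies, average the concordant replicate factors"
  (concordance: within 1 SD), i.e. a per-antibody average — a single global
  average could not differ per marker.
- **Peak separability**: adjacent bead-cluster medians closer (on log scale)
  than twice their combined MADs indicate a split mode, not two levels, and
  raise a degenerate-peaks error.
- **z-scoring for clustering** is per marker across subsets (markers are the
  clustered features); the axis is exposed as the `margin` argument of
  `hca()` since either orientation is defensible.
- **Differential testing** defaults to the exact Wilcoxon rank-sum on donor
  medians — a conservative choice for ≤12 skewed values per group; a Welch t
  on log10 ABC is available. No multiplicity correction by default, matching
  raw-threshold reporting; Benjamini–Hochberg is one argument away.
- **Seeding** is hierarchical: every well derives its stream from the run
  seed plus its own identity, so adding a well never perturbs another well's
  draws, and every generator is bit-reproducible.

## Problem sizes

The default synthetic resource is 20 markers × 6 subsets × 5 donors at 10⁵
events per well (plus one FMO well per donor, a 10⁴-event bead well and
10⁴-event conjugation wells per marker). The test suite exercises smaller
variants (e.g. 12 × 4 × 3 at 10⁴ events) for speed; the full-size resource
is what `scripts/acceptance.R` runs. These sizes were chosen so each subset
comfortably clears the 100-cell rule and median statistics have sub-percent
sampling error.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
res <- run_pipeline(cfg)
res$curve                      # fitted calibration line
head(res$correction)           # per-antibody correction factors
tidy(res$map)                  # marker x subset expression map, long form
glance(res$sigmoid$S2)         # logistic fit of subset S2's positivity
res$turning$S2                 # knee of S2's ordered expression sequence
tidy(res$clusters)             # subset cluster labels at the configured cut
plot_drop(res$map)             # colour = median ABC, dot area = % positive
```

## Known limitations

- The synthetic resource validates the pipeline, not the biology: block
  structure and effect sizes are planted, and real marker-subset structure
  is richer.
- ABC accuracy is bounded by the conjugation model: monovalent vs bivalent
  binding alone introduces up to a factor-2 ambiguity in molecules per cell,
  and correction factors share the cohort-median scale indeterminacy
  described above.
- Gate geometry is axis-aligned only; curved manual gates and compensation
  are out of scope.
- The FCS adapter writes/reads minimal FCS 3.1 (list-mode float32) for
  interoperability; the CSV dialect is the canonical, fully-tested format.
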