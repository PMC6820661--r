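# flowabc

Quantitative immunophenotyping for plate-based flow cytometry: from raw
per-well event tables to absolute surface-marker expression maps, with every
stage testable against a seeded synthetic ground truth.

## The problem

Multicolour flow cytometry panels in which one channel is reserved for a
single PE-conjugated "drop-in" antibody per well measure every surface
marker on the same fluorescence scale. With quantitation beads carrying four
known PE amounts acquired alongside, that scale becomes absolute: median
fluorescence intensity (MFI) converts to PE molecules per cell and — under
~1:1 PE:antibody conjugation — to **antibody binding capacity (ABC)**, the
number of antibodies bound per cell. flowabc implements the full analysis
chain for such experiments, for immunologists and cytometrists who want
reproducible, scripted versions of what is usually done interactively:

- **calibration**: four-level bead peak finding, the log–log line
  `log10(ABC) = slope · log10(F) + intercept`, and per-antibody conjugation
  correction factors `f_m = median_m / median(all medians)` (ABC is divided
  by `f_m`; factors outside [0.7, 1.3] are flagged);
- **gating and statistics**: threshold gate trees, leukocyte-count and
  CD45-drift QC, the 100-cell rule, value cleaning (non-positives → 1),
  median/mean/mode/CV/percentile exports, and percent positivity against a
  per-subset FMO (fluorescence-minus-one) cutoff;
- **profiling**: donor-median expression maps; the logistic model
  `PE(cds) = PEmax / (1 + e^{-a1 (cds - cdsmid)})` over rank-ordered
  positivity (slope at midpoint = `a1·PEmax/4`); Menger-curvature
  (1/circumradius) turning points on ordered expression sequences;
- **comparison**: shift → log10 → z-score transform, Euclidean/ward.D2
  hierarchical clustering with a k-cut, Wilcoxon rank-sum differential
  markers with p < 0.01 / p < 0.001 tiers and a symmetric 10-fold flag;
- **synthetic data**: a seeded generator producing wells, FMO controls,
  calibration beads and conjugation beads with known ground truth, so every
  claim above is tested end to end.

## Worked example

```r
library(flowabc)

cfg <- run_config(seed = 1)   # 20 markers x 6 subsets x 5 donors, 1e5 events/well
res <- run_pipeline(cfg)
res
#> <pipeline_result> 600 subset-marker-donor records, 100/100 wells passed QC
#> <calibration_curve> log10(ABC) = 1.0001 * log10(F) + -0.3008  (R2 = 1.00000)
```

The calibration slope is ~1 and the intercept ~ `-log10(2)`: the simulated
instrument ran at gain 2 and the bead fit absorbed it exactly. Correction
factors sit around 1, as conjugation chemistry warrants:

```r
head(as.data.frame(res$correction), 4)
#>   marker    factor flagged n_replicates
#> 1    M01 1.0271857   FALSE            1
#> 2    M02 0.8735886   FALSE            1
#> 3    M03 1.0087644   FALSE            1
#> 4    M04 1.1566013   FALSE            1
```

The expression map gives, per marker × subset, the donor-median corrected
ABC and percent positivity (M01 is one of the ubiquitously expressed
markers — tens of thousands of molecules per cell, near-100% positive
everywhere):

```r
tidy(res$map)
#> # A tibble: 120 x 7
#>   marker subset    abc abc_mean pct_pos n_donors cv_donor
#> 1 M01    S1     41097.   41084.   100.0        5  0.00329
#> 2 M01    S2     76977.   76968.    97.1        5  0.00133
#> 3 M01    S3     18000.   18003.    97.4        5  0.00194
```

Per subset, markers ordered by rising positivity follow the fitted logistic,
and the ordered expression sequence has a knee where expression switches
from background to real signal:

```r
glance(res$sigmoid$S2)
#> # A tibble: 1 x 7
#>   pe_max cds_mid    a1 slope_mid   rss converged n_markers
#> 1   98.2    11.5  6.46      159.  29.8 TRUE             20
res$turning$S2
#> <turning_point> index 11 (curvature 11.4, normalised axes)
```

(A plateau of ~98% positive, a midpoint between the 11th and 12th of 20
rank-ordered markers — this subset expresses roughly half the panel — and
the expression knee at the same rank, as it should be when positivity and
expression rise together.)

Differential comparison between the first two subsets, donor-level rank-sum
on median ABC:

```r
head(as.data.frame(res$diff[, c("marker", "fold_change", "p_value", "tier")]), 3)
#>   marker fold_change     p_value   tier
#> 1    M01   0.5338895 0.007936508 p<0.01
#> 2    M02   4.3498507 0.007936508 p<0.01
#> 3    M03   1.6804668 0.007936508 p<0.01
```

(5 donors per group: the most extreme two-sided exact rank-sum p is
`2/choose(10,5) ≈ 0.0079`.) `plot_drop(res$map)` draws the expression map
with colour = median ABC and dot area = percent positive;
`autoplot(res$clusters)` the dendrogram; `write_report(res, "report/")` a
static report with all standard views.

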