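---
title: "Methods: immune-niche quantification and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-niche quantification and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immuniche)
```

This vignette is the package's account of its own methods: the models and
their assumptions, the parameters that matter, the design choices made
where the design was genuinely open, and the limits of what a green test
establishes. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. Setting

A single-arm phase 2 neoadjuvant trial in locally advanced non-metastatic
ccRCC (17 patients, 12 weeks of cabozantinib before nephrectomy,
NCT04022343) motivates two analysis tracks:

* **Tissue track.** Whole-slide mIF images are segmented upstream
  (QuPath); the pipeline starts at the per-cell export — planar
  coordinates in µm plus mean fluorescence intensity per marker (DAPI,
  CD4, CD8, MHC-II, TCF1). From these it calls phenotypes, maps cell
  densities, and quantifies *immune niches*: regions where MHC-II+
  antigen-presenting cells and TCF1+ stem-like CD8+ T cells co-occur above
  stated per-mm² densities.
* **Trial track.** Lesion measurements, survival times, plasma analyte
  panels and ctDNA calls feed RECIST 1.1, ORR, Simon-design operating
  characteristics, Kaplan–Meier estimation, and rank-based correlative
  statistics.

Because the image-level data are not public, a synthetic generator with
planted ground truth stands in for tissue and cohort inputs everywhere.

## 2. Phenotype calling

A cell is positive for a marker when its intensity reaches the marker's
threshold, after DAPI gating; TCF1 is evaluated only inside CD8+ cells
(stem-like T cells are by definition a CD8 subset). Two resolution rules
close gaps the upstream assay leaves open:

* **CD4/CD8 double positives** are assigned to the lineage with the larger
  intensity z-score. The downstream analysis treats the lineages as
  disjoint and no published rule exists; a z-score comparison is
  scale-free across markers.
* **DAPI** is gated as *any positive intensity* in auto mode. Segmentation
  is DAPI-driven, so every exported object carries DAPI signal; deriving an
  interior threshold on that unimodal all-positive distribution would
  wrongly drop cells. An explicit DAPI threshold is honored when supplied.

**Auto-thresholding.** No positivity thresholds were published, so auto
mode derives one per marker per tissue. The default is the *largest-gap
split*: the midpoint of the widest gap between consecutive sorted log1p
intensities above the marker median. Under the separation assumption the
generator guarantees (positive and negative means ≥ 5 sd apart) the
between-population gap dominates all within-population spacings and the
split is essentially exact, *regardless of the positive fraction*. The
classic Otsu criterion — implemented and available as
`auto_threshold(method = "otsu")` — maximizes between-class variance and
therefore drifts into the negative bulk whenever positives are a small
minority (TCF1+CD8+ cells are typically < 1% of cells) or when the
zero-floor spike dominates the log histogram; measured on planted tissues
it broke the ≥ 99.9% label-recoverability requirement, which is why it is
not the default. For markers with *no* positive population the gap method
thresholds in the extreme upper tail, so the false-positive rate stays at
the order of a few cells per tissue. Auto thresholds are a stand-in for
expert review: with genuinely continuous marker expression (no separation)
they are not reliable, and explicit thresholds should be supplied.

Composition fractions are percents of DAPI+ cells. `MHCII` excludes cells
already assigned to a T-cell lineage so that
`CD4 + CD8 + MHCII + other = 100` exactly; `TCF1_CD8` is reported
alongside as a subset of `CD8`.

## 3. Niche detection

The niche definition is a conjunction of densities "in the same area":
≥ 16 MHC-II+ cells and ≥ 4 TCF1+CD8+ cells per mm². The unit area is
published; the windowing scheme is not. Choices, all configurable via
`niche_params()`:

* **Sliding square windows** of area 1 mm² on a 250-µm center lattice
  (`mode = "tiles"` gives disjoint tiling). Half-open window membership
  makes disjoint tiles partition cells exactly.
* **Boundary windows** count cells in window ∩ mask and normalize by the
  clipped area; windows with < 25% of their area in the mask are excluded
  ("outside") rather than allowed to produce unstable densities from
  slivers.
* **Niche region = stride-cell rasterization of qualifying window
  centers**, clipped to the mask; coverage = that area / tumor area. The
  alternative reading — rasterizing each full 1-mm² window — dilates a
  planted 1-mm² niche roughly threefold (every window within half a window
  side of the niche qualifies), so the center-cell raster is the faithful
  estimator of niche extent. Area is computed at stride resolution, with
  the in-mask fraction of each stride cell estimated on a deterministic
  5×5 sample lattice (10×10 for the window-overlap fractions).

Coverage is exactly monotone non-increasing in either threshold (raising a
threshold can only shrink the qualifying-window set), translation
invariant (the lattice is anchored to the mask bounding box), and bounded
in [0, 1].

**Resolution limits.** A 1-mm² window estimating a density near a
threshold of 4 cells/mm² works with Poisson counts whose sd is half their
mean; niche boundaries are therefore intrinsically noisy at the
single-window scale, and single-tissue coverage of a 1-mm² niche carries
~30% relative noise. Tests and acceptance checks therefore compare the
*mean* relative error across replicate tissues (bound: 25%). The
stride-refinement bound (halving the stride moves coverage by less than a
perimeter-to-area term, ≤ 10%) is checked on a noise-free lattice tissue
with a 2-mm² niche; at exactly 1 mm² and 250-µm stride the discretization
term alone exceeds 10%, a stated limitation rather than a defect.

Nearest-neighbor distances (e.g., each CD8+ cell to its nearest MHC-II+
neighbor) are 2-D Euclidean in µm via a bucket-grid search, self-excluding
when the two phenotypes coincide; tests verify exact agreement with the
O(n²) scan. No slide-stitching or 3-D corrections are applied.

## 4. The synthetic world

`generate_tissue()` draws an inhomogeneous Poisson point pattern on the
tumor polygon: per-phenotype background intensities plus hard circular
niche discs inside which the MHC-II+ and TCF1+CD8+ intensities are raised
to stated values (overlapping discs take the max, so the planted region is
exactly the disc union and its true coverage is analytic). Defaults:

| parameter | default | rationale |
|---|---|---|
| frame | 4 × 4 mm | a small whole-slide region |
| background CD4 / CD8 | 50 / 50 per mm² | ~10% T cells of ~500 cells/mm² |
| background MHC-II | 8 per mm² | half the niche threshold: non-niche tissue stays sub-threshold |
| background TCF1+CD8+ | 1 per mm² | rare outside niches |
| background other | 400 per mm² | tumor/stroma bulk |
| niche disc densities | 32 MHC-II+, 12 TCF1+CD8+ per mm² | smallest 2×/3× threshold multiples for which an interior 1-mm² window qualifies with ≥ 99% probability under Poisson noise — i.e. planted niches are *unambiguous* niches |
| intensities | positive 100, negative 10, sd 8 (floored at 0) | > 10 sd separation; only order statistics matter for thresholding |

The generator emulates: planted coverage, Poisson cell counts, separated
intensity distributions, and determinism under seed (byte-identical
outputs). It does **not** emulate segmentation errors, spectral bleed,
intensity gradients across a slide, cell-size variation, or spatial
autocorrelation beyond the planted discs — so a green phenotyping test
certifies the thresholding logic under separation, not robustness to
assay artifacts.

`generate_cohort()` plants the trial's stated world: 17 patients, 6
forced below the −30% PR boundary at week 12 (week-12 changes uniform in
−42..−30% for PR, −29..−8% for SD: every patient shrinks, matching the
8–42% reduction range), baseline sizes uniform in 3.31–24.41 cm,
log-normal analyte fold changes with planted medians (1.6 at W6D1 for the
treatment-responsive markers, below 1 for VEGFR2; sdlog 0.25), Bernoulli
ctDNA detection at the per-timepoint rates 4/13, 6/14, 5/16, 1/11, and
exponential event times calibrated to one-year DFS 82.4% / OS 94.1% with
administrative censoring at 25 months.

## 5. Clinical statistics

* **RECIST 1.1, target lesions only.** Per timepoint: CR when the diameter
  sum is 0; PR at ≤ −30% from baseline; PD at ≥ +20% *from the nadir*
  (series minimum, baseline included) with an absolute floor of 0.5 cm
  (RECIST's 5 mm, in cm units); SD otherwise. Non-target and new-lesion
  rules are omitted — the trial tracked the primary renal tumor — and this
  is the package's main clinical-scope limitation.
* **ORR.** Responders are CR + PR; the CI is Clopper–Pearson (exact beta
  quantiles) by default, Wilson by option. The trial's "clinical benefit"
  (CR + PR + SD) is a separate function, not folded into ORR.
* **Simon design.** Exact binomial computation over stage-1 outcomes; the
  test suite verifies it against full outcome-path enumeration to < 1e-12
  and checks monotonicity of the rejection probability in p.
* **Kaplan–Meier.** Product-limit with Greenwood variance on the log-S
  scale (`conf.type = "log"` in `survival` terms); with no censoring
  before the landmark it equals the empirical survivor fraction exactly.

## 6. Correlative statistics

Fold changes divide each patient's trajectory by that patient's baseline;
zero/missing baselines are excluded with a warning and an exclusion
report, never divided by. Missing timepoints mean complete-pairs analysis
throughout — no imputation, matching the trial's "samples not available"
handling.

Rank tests use mid-ranks for ties. The signed-rank test drops zero
differences and uses the exact sign-flip null (computed by convolution on
doubled ranks, valid under ties) up to n = 25, then a tie-corrected normal
approximation with continuity correction; the Mann–Whitney test is exact
(via the `pwilcox` null) for min(n) ≤ 8 without ties, tie-corrected
normal otherwise. Spearman's rho is the Pearson correlation of mid-ranks,
with a t-approximate p-value by default and a full-permutation option for
n ≤ 9. Note that the signed-rank test is *not* invariant under general
monotone transforms of the raw measurements (the transform reorders the
absolute differences); positive affine invariance holds and is tested.
Per-analyte p-values are reported unadjusted, as per-comparison figure
conventions do; a Holm-adjusted column is emitted alongside, labelled as
an extension.

Detection rates and AE percentages are printed round-half-up to one
decimal (the trial tables' convention; base R's `round()` is
round-half-even and would print 29.65 as 29.6 or 23.55 as 23.5 vs 23.6
inconsistently). Published marginal tables (detection counts per
timepoint, AE counts per term) are expanded to record level by synthetic
reconstruction helpers: per-term and per-timepoint summaries are exact,
but cross-term patient overlap is arbitrary and the helpers say so.

The end-to-end power property (PR patients' niche coverage shifted vs SD)
is simulated at the summary level: per-patient coverages drawn log-normal
(sdlog 0.5 around 5% coverage) with a planted 2-sd log-scale shift for the
6 PR patients — a large, clearly-separated effect in keeping with the
trial's strongly significant PR-vs-SD niche difference — giving the
6-vs-11 Mann–Whitney ≥ 80% power at α = 0.05 across 500 replicates.
Full-tissue simulation at 500 replicates would exceed the test budget and
adds nothing to this property, which is about the test, not the imaging.

## 7. Numerical choices and degenerate inputs

* Window membership is half-open; counts at disjoint tiling partition the
  cell set exactly. Window/raster in-mask fractions use centered k×k
  sample lattices (deterministic), not random sampling.
* GeoJSON coordinates are rounded to 1e-6 µm before writing, making
  write → read → write byte-identical.
* Degenerate inputs fail loudly and early: zero-area masks, missing marker
  columns (named in the error), all-zero DAPI, empty target phenotype in
  distance queries, all-zero paired differences, constant inputs to
  correlation, probabilities outside [0, 1], negative survival times.
* Empty phenotype tables are *not* an error for density grids (all-zero
  grid) or immunomap export (valid file, empty layers).
* The pipeline hashes its configuration (output directory excluded) into
  every artifact's provenance block; reruns with the same config are
  byte-identical, and a changed seed changes only stochastic outputs
  (design operating characteristics are invariant by construction).

## 8. Known limitations

* Niche coverage at the single-tissue, single-mm² scale is Poisson-limited
  (Section 3); comparisons should be made on replicate or large tissues.
* Auto-thresholding assumes separated intensity populations; it is a
  stand-in for unpublished expert thresholds, and recorded thresholds
  should always be reviewed.
* RECIST handles target-lesion sums only; KM confidence intervals use the
  log (not log-log) transform.
* The historical-control comparisons and per-patient published spatial
  results depend on unreleased image data and are out of scope; the
  property-based synthetic surface is what the tests certify.
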