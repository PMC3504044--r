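---
title: "Methods: multi-parametric phenotyping of GRMD dogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-parametric phenotyping of GRMD dogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmdpheno)
```

`grmdpheno` implements the quantitative phenotyping battery used in
preclinical studies of the GRMD (golden retriever muscular dystrophy) dog,
the canine model of Duchenne muscular dystrophy. Treatment studies in this
model are evaluated on several axes at once — muscle histology, in-vivo
isometric force, gait quality measured by 3D-accelerometry, a clinical motor
score, and serum creatine kinase (CK) — because single-axis read-outs can
point in opposite directions under disease-modifying co-treatments such as
immunosuppression. This vignette describes each method as implemented, the
synthetic data the package generates to validate them, and the numerical
and design choices made.

## Histomorphometry

### Point-count stereology and the pathological index

Whole-section H&E images are sampled with a square grid of 10,000 µm² cells
(`overlay_grid()`), i.e. one intercept every 100 µm, offset half a spacing
from the image origin so no intercept falls on the border. Each intercept is
captioned with one of seven categories (`lesion_categories()`): normal
fiber, abnormal fiber, connective tissue, inflammatory focus, adipose,
other structure, artifact. The **pathological index** is the percentage of
intercepts over tissue that are *not* normal fibers.

Two choices here were genuinely open:

* the caption vocabulary is not standardized across laboratories; the seven
  categories above cover the dystrophic lesion spectrum and an explicit
  artifact class;
* artifact intercepts are excluded from the denominator: the index should
  reflect tissue composition, not mounting or staining defects.

Classification uses the single pixel under the intercept (no neighbourhood
vote), the most literal reading of "the tissue underlying the intercept".
By construction the intercept estimate converges on the exhaustive
pixel-census value as the grid is refined; the test suite verifies the
shrinking sampling error at 200/100/50/25 µm spacings, and checks the
100 µm estimate against the census within three binomial standard errors.

### Collagen, calcification, fiber size, fiber types, inflammation

* **Fibrosis** (picrosirius–fast green): collagen is segmented in
  hue–saturation space (red band vs the green cytoplasm band; thresholds in
  `seg_config()`), and the fraction is red area over total section area.
* **Calcification** (alizarin red S): calcified cytoplasm is segmented by
  saturation, connected components are counted per fiber (fibers are
  separated by the unstained boundary network), and each component is
  classified moderate (deep pink) or severe (red). A fiber containing both
  bands is severe when ≥ 25 % of its calcified pixels are in the red band —
  severity dominates; the threshold ships in `seg_config()`. Counts are
  normalized by a total-fiber estimate obtained by counting five random
  fields covering ~6 % of the section and extrapolating by area
  (`estimate_total_fibers()`), which is exact under exhaustive tiling and
  unbiased under uniform random field placement.
* **Fiber morphometry** (ATPase): fiber outlines are dark; interiors are
  labelled as connected components and each fiber's **equivalent diameter**
  is that of the equal-area circle, `2·sqrt(area/π)`. The section mean and
  the coefficient of variation (SD/mean) summarize size and size
  inequality. A validator refuses sections with fewer than 400 measured
  fibers.
* **Fiber types** (slow-myosin immunostain): the percentage of
  slow-positive fibers pooled over five randomly sampled zones, with a
  minimum of 300 fibers counted.
* **Inflammation** (CD4/CD8/CD11b): marker-positive cells counted over the
  whole section and normalized to its area (cells/mm²).

## In-vivo force indices

Force sessions follow the protocol of six 2-s, 50 Hz tetanic stimulations
at 1-minute spacing, then forty 3-s-spaced tetani to probe fatigue. From a
stimulus-annotated trace the package computes:

* **Tetanic force**: the mean of the baseline-subtracted force over the
  second half of the stimulation epoch. The operational definition (plateau
  mean rather than peak) was an open choice; the plateau is robust to onset
  dynamics and noise. Baseline is the mean over the 200 ms preceding onset.
  Whether the original analysis subtracted baseline is unstated; we
  subtract and say so.
* **Relative force**: mean tetanic force over the six tetani divided by
  body weight (N/kg).
* **Fatigue index**: force of the last of the 40 tetani as a percentage of
  the first.
* **100 ms relaxation level** (`r100`): the percentage of the tetanic force
  lost 100 ms after stimulation end, read from a 5 ms median-smoothed
  trace. The smoothing suppresses single-sample noise without biasing
  100 ms kinetics; the relaxation clock is anchored at stimulation end.
* **Post-tetanic residual contraction**: the baseline elevation 500 ms
  after the tetanus (mean over a ±50 ms window around the 500 ms instant,
  since the definition names an instant) relative to the pre-tetanus
  baseline, as a percentage of tetanic force.

On noiseless exponential relaxation with time constant τ these definitions
give `r100 = 100·(1 − exp(−0.1/τ))` and recover an injected baseline
offset exactly once relaxation is complete before the 450 ms window; both
closed forms are asserted in the tests. When relaxation is slow (τ
≳ 150 ms) the 500 ms window still contains part of the exponential tail,
so the measured residual exceeds the injected offset — a property of the
definition itself, visible equally in real traces. Left and right legs are
kept as separate observations and feed the repeated-measures ANOVA below.

## Gait: reference PCA and the gait quality index

Raw accelerometric gait variables per trial are speed, stride frequency,
stride length, regularity, three axial powers (dorso-ventral,
cranio-caudal, medio-lateral), total power, plus the height at withers.
Normalization (`normalize_record()`): speed and stride length are divided
by height; axial powers become relative powers (axial/total). A **force
index** (total power / speed) isolates gait power from speed differences.

The **reference PCA** (`fit_reference()`) is fitted once on a reference
cohort of adult healthy and adult GRMD dogs using seven variables: stride
frequency, height-normalized stride length, regularity, the three relative
powers, and total power. Speed is not among them, which also accommodates
trials where speed was not measured. Whether the original plane used raw or
height-normalized stride length is ambiguous; the normalized variant is
used, consistently with the stated variable normalizations. Variables are
standardized by the reference means and SDs; the first two principal axes
are retained (the reference "plane"); the sign convention puts the healthy
centroid at the lower component-1 coordinate.

Evaluated dogs are projected as **supplementary individuals** — they never
influence the plane — and the **GQI** is the Euclidean distance from a
dog's projection to the healthy centroid. When session ages are available,
healthy centroids are binned by month and the nearest non-empty bin is used
(the original age-matching rule is unstated; monthly binning with
nearest-bin fallback is documented here as the package's choice). The GQI
is invariant to unit rescaling of any raw variable (standardization by
reference SDs) and to the loading sign convention, and the plane distance
can never exceed the full 7-D standardized distance; all three are tested.

## Clinical score and CK

The motor grid has 11 items, each scored 0 (normal) to 2 (worst), totalling
0–22; a healthy dog scores 0/22. Group comparisons use the percentage of
22, the scale on which group values are conventionally reported. CK
(UI/L) is summarized per dog as the mean of in-window samples (window
±2 weeks around a monthly timepoint; the aggregation rule is the package's
documented choice) before group means/SDs are formed, so dogs with more
samples do not dominate. Duplicate timestamps are deduplicated keeping the
first record.

## Statistics

* `two_group_t()`: two-sided two-sample t-test, pooled-variance by default
  (the classical "Student" dialect; the variance assumption was unstated,
  so a Welch variant is available behind a flag). Significance at p ≤ 0.05.
* `mixed_anova_side()`: repeated-measures ANOVA with side (left/right) as
  the within-subject factor and group as the between-subject factor,
  reporting the group main effect tested against the between-dog stratum
  (`stats::aov` with an `Error(dog/side)` term).
* `timepoint_scan()`: a t-test per timepoint with no multiplicity
  correction, matching the original per-timepoint testing; a Holm-adjusted
  column is emitted alongside, clearly labelled as supplementary.

Calibration is part of the acceptance surface: under the null the t-test
rejects at 0.05 ± 0.005 (10,000 replicates, n = 5/group) and the ANOVA
group effect at 0.05 ± 0.02 (1,000 replicates).

## The synthetic cohort: what it emulates and what it does not

All validation runs on synthetic data with known ground truth.

**Sections** are jittered-lattice Voronoi tessellations: fiber interiors
separated by a thin boundary network, rendered in fixed per-stain RGB
palettes (`stain_palette()`) with additive Gaussian pixel noise. Lesion
classes are carved as smooth blobs (thresholded Gaussian random fields)
with exact pixel-count area fractions; the picrosirius dialect is a
two-class collagen/cytoplasm image whose collagen fraction is exact at
pixel quantization. Every ground-truth quantity stored by the generator is
recoverable by a brute-force pixel census, which is what the quantification
tests compare against. The sections are deliberately *not* photorealistic:
no stain variability between slides, no mosaic-stitching seams, no
out-of-focus regions, near-circular fibers. Passing tests therefore
demonstrate that the measurement definitions are implemented correctly and
are well-calibrated on well-posed images — not that the colour thresholds
would survive real-slide variability, which would require stain
normalization out of scope here.

**Force traces** rise with a saturating onset (30 ms time constant),
relax exponentially and settle at baseline plus a residual offset that is
held for 1 s and then ramps away, so the next epoch starts from a clean
baseline at the 1-minute spacing of the tetanic phase. In the 3-s-spaced
fatigue train the offset is still present at the next onset — as in real
recordings with incomplete relaxation — which slightly depresses measured
fatigue-train amplitudes when an offset is present; the closed-form fatigue
checks therefore use offset-free traces.

**Cohorts.** Group trajectories are parameterized from the reported group
values where available: CK at 6 months 1445.8 UI/L (treated) vs
27,326.7 UI/L (untreated GRMD); motor score 32.6 % vs 63.8 %; and the
treated gait position intermediate between GRMD and healthy — the treated
gait-parameter blend (54 % of the GRMD-to-healthy span, reached by 5
months of age) is the ratio implied by the reported group GQI means
(0.78 / 2.09 / 3.62). Where no value is reported (raw gait-variable
means, force plateaus, per-biopsy lesion parameters), values were chosen
once as field-realistic for growing dogs of these sizes and are listed in
the parameter tables (`grmdpheno:::gait_param_table()`,
`grmdpheno:::force_param_table()`,
`grmdpheno:::histology_param_table()`). CK noise is log-normal (CK cannot
be negative and spans orders of magnitude) with a dog-level and a
week-level component. Because the reference PCA is refitted on synthetic
reference cohorts, GQI magnitudes are comparable to, but not numerically
identical with, values computed on the original (unpublished) reference
plane; what the pipeline reproduces is the group ordering and effect
directions, which is what the direction-reproduction acceptance check
asserts across 20 seeds.

## Numerical choices and problem sizes

* PRNG: a single seed per entry point; sub-seeds for internal stages are
  derived by a fixed integer recurrence kept inside the 32-bit range.
  Identical inputs and seed give bit-identical outputs everywhere.
* Tessellation: nearest-seed assignment over the 3×3 lattice
  neighbourhood, with jitter bounded at 0.35 cells; boundary pixels are
  those with a 4-neighbour in a different cell.
* Blob carving picks the exact top-k pixels of a blurred noise field, so
  target fractions are met to one pixel.
* Demo problem sizes (`pipeline_config()` defaults): 5 treated / 8 GRMD /
  8 healthy dogs, 18 + 11 adult reference dogs for the PCA, 320 px
  sections (512 px for ATPase so that ≥ 400 fibers are measurable),
  1 kHz force sampling, two biopsies per group per timepoint. These sizes
  keep a full run near half a minute while leaving every estimator inside
  its validated operating range; tests use the same generators at equal or
  smaller sizes, and the sampling-theory checks (binomial SEs,
  extrapolation bias) scale accordingly.

## Known limitations

* Colour segmentation thresholds are validated against the package's own
  palettes, not against scanner or stain variability.
* Raw 100 Hz accelerometer processing (stride segmentation, spectral
  power extraction) is out of scope; the pipeline starts from per-trial
  gait variables.
* The motor grid's item-level clinical semantics (hopping test, etc.) are
  not modelled; synthetic sheets target realistic totals, not realistic
  item correlations.
* Whole-slide mosaic stitching, stain deconvolution and interactive
  annotation are out of scope.
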