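---
title: "Quantitative IHC scoring and CyCIF gating: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative IHC scoring and CyCIF gating: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcgate)
```

## The problem

Tumor-suppressor loss is often read out at the protein level by
immunohistochemistry (IHC): sections are stained with a DAB chromogen at the
antigen (here p16^INK4A^) over a hematoxylin nuclear counterstain, and a
section is scored by the fraction of hematoxylin-positive cells that are also
DAB-positive. `ihcgate` implements this scoring pipeline end to end —
brightfield RGB to optical density, H-DAB color deconvolution, nucleus
detection, compartment-wise positivity calling, percent-positive statistics,
observer-calibrated threshold selection, and cohort classification at a 30%
cutoff — together with the companion single-cell workflow for cyclic
immunofluorescence (CyCIF) intensity tables: cross-sample normalization,
two-Gaussian mixture gating, and rule-based phenotyping.

## Brightfield model: Beer–Lambert and color deconvolution

Stain amounts combine additively in optical density, not in RGB. Per channel,

$$\mathrm{OD}_c = -\log_{10}\!\left(\frac{\max(I_c, 1)}{I^{0}_c}\right),$$

with background $I^0$ = 255 per channel (a clean unstained field) and a floor
of 1 count to keep the logarithm finite. The OD vector at each pixel is
modelled as a nonnegative combination of stain-specific unit OD vectors:
hematoxylin $\approx (0.650, 0.704, 0.286)$ and DAB
$\approx (0.269, 0.568, 0.778)$ after normalization — the standard published
H-DAB pair — completed by their normalized cross product so the $3\times 3$
basis is invertible. `deconvolve_stains()` solves the linear system per pixel
and clips negative concentrations to zero. On nonnegative-concentration
inputs the round trip is exact to well below $10^{-6}$ OD; quantizing to
8-bit RGB and back introduces errors of order $10^{-2}$ OD per pixel, which
the test tolerances budget for.

## Cell detection and positivity

The original analysis used a CellProfiler pipeline whose internals are not
published; we re-implement the simplest detector honoring the stated uniform
hematoxylin threshold:

1. threshold the hematoxylin concentration map at 0.3 (OD units),
2. 3×3 morphological opening to remove speckle,
3. 8-connected component labeling, minimum-area filter (default 20 px),
4. per nucleus, mean DAB OD over the nucleus and over a cytoplasmic annulus
   (Euclidean dilation by 3 px, excluding all nucleus pixels),
5. DAB-positive iff either compartment mean strictly exceeds the DAB
   threshold (default 0.3, calibrated as below).

Choices worth making explicit:

* **Thresholds are in OD units.** Whether the original 0.3 values were raw
  intensity or OD is not stated; we fix OD and document it. The calibration
  machinery makes the choice self-correcting against manual counts.
* **Strict inequalities everywhere.** Ties fall negative, matching the `>`
  notation used for every published threshold in this workflow.
* **"Above background" is operationalized** as the compartment mean OD
  exceeding the DAB threshold, OR-ed over nucleus and cytoplasm annulus. The
  annulus is our operationalization of "cytoplasm"; its width (3 px) matches
  the generator's ring so the synthetic loop is consistent.
* **No watershed splitting.** The detector's contract allows an optional
  split of touching nuclei; the synthetic generator guarantees a minimum
  inter-nucleus gap, so touching nuclei cannot arise in any tested world and
  the splitter would be dead, untestable code. On real tissue with dense
  nuclei this is a known limitation.

Percent positive is $100\, n_\mathrm{DAB} / n_\mathrm{hema}$ per ROI;
sections aggregate three ROIs as mean ± sample SD ($n-1$). A single-ROI
section reports SD 0 with an explicit `sd_defined = FALSE` flag rather than
`NA`, so downstream tabulation never silently drops it.

## Threshold calibration by Bland–Altman agreement

Manual observers score a set of test images; the automated pipeline scores
the same images at each candidate DAB threshold (the studied grid is 0.15,
0.25, 0.30). Differences are taken on counts, manual minus automated, with
the manual reference being the across-observer mean. For differences $d_i$:

* bias $= \bar d$,
* limits of agreement $= \bar d \pm 1.96\, s_d$,
* 95% CI of the bias $= \bar d \pm t_{0.975, n-1}\, s_d/\sqrt n$.

The selected threshold minimizes $|\mathrm{bias}|$; ties break toward the
larger threshold (fewer false positives). Published intervals of this kind
are sometimes limits of agreement mislabeled as confidence intervals — the
two differ by a factor of roughly $1.96\sqrt n / t$ — so both are computed
and labelled unambiguously; we do not guess which one a given report meant.
Pairwise inter-observer Pearson concordance (`cor.test`) is reported
alongside, since the calibration is only meaningful when observers agree.

## CyCIF gating

The normalization applied to raw mean fluorescence intensities is not fully
specified upstream ("normalized across all samples"); we fix the simplest
invertible, order-preserving choice: $x \mapsto \log_{10}(x+1)$, then one
additive shift per sample and marker aligning the sample median to the
pooled median. The stored shifts make the transform exactly invertible,
which the gate's "map back to raw values" step requires.

Per marker, a two-component univariate Gaussian mixture is fitted to the
pooled normalized values by EM: initialization splits the data at the median
(further restarts at random quantiles, 5 restarts, best log-likelihood
kept), convergence at a log-likelihood gain below $10^{-8}$ or 500
iterations, variances floored at $10^{-6}$ to prevent collapse. The
log-likelihood trace is retained and asserted non-decreasing in the tests.
Components are reported with $\mu_1 < \mu_2$.

The positive threshold is the **peak of the positive component**, i.e.
$\mu_2$ (a Gaussian's density peaks at its mean). Note what this rule
implies: cells between the components' crossing point and $\mu_2$ — roughly
the lower half of the positive population — are called negative. That is the
quoted gating rule, implemented literally; tests assert agreement with a
brute-force application of the same rule, not with the planted positive
fraction. The per-sample raw threshold is $10^{\mu_2 - \mathrm{shift}_s}-1$.

Fitting is global per marker (pooled across samples after normalization);
per-sample fitting is available via `gate_cycif(..., per_sample = TRUE)` but
is not the default, since the normalization exists precisely to justify one
pooled fit.

## Cell typing

`typing_rules()` encodes the rule set on the normalized scale: tumor iff
cytokeratin > 2.5; tumor cells are then flagged per marker at Lamin B1 >
3.3, cleaved caspase-3 > 1.9, pH2Ax > 2.9, p16 > 2.8, p-RB > 2.7, PCNA >
3.3 (all strict). The source sentence "Lamin B1 positive if Lamin B1 > 3.3,
cleaved Caspase-3 > 1.9" is grammatically ambiguous between two independent
rules and a conjunction; we default to independent rules — matching the
pattern of every other threshold in the list — and provide
`laminb1_requires_caspase3 = TRUE` for the conjunctive reading. Marker flags
of non-tumor cells are `NA`, never `FALSE`: the rules are only defined for
tumor cells. Condition summaries aggregate per-section positive fractions
(mean ± sample SD across sections) and compare conditions with two-sided
unpaired Student's t-tests (Welch by flag), refusing the comparison when a
condition has fewer than two sections.

## Cohort classification

A sample is p16-positive when its percent-positive strictly exceeds 30%.
The source states positivity as ">30%" and deficiency as "<30%", leaving
exactly 30% unassigned; a single strict rule puts the boundary case in the
deficient class. CDKN2A copy number is carried as annotation only — the
scientific point of the workflow is that CNV does not linearly predict
protein loss, so no CNV-based logic exists. Matched PDX/patient
concordance uses Pearson correlation over pairs plus an unpaired two-sided
t-test between sources (a paired option exists; the published comparisons
use the unpaired form with mean ± SD).

## The synthetic world

The generator's defaults are a single stated world, chosen once:

| parameter | default | rationale |
|---|---|---|
| field size | 512 × 512 px | holds 200 well-separated nuclei, ~1 s to score |
| nuclei per field | 200 | a typical 40× ROI cell count |
| nucleus radius | 5 ± 1 px | small-nucleus regime at this scale |
| min gap | 8 px | annuli (3 px) never touch a neighbor nucleus |
| hematoxylin OD | 0.7 | dark counterstain, >2× the 0.3 threshold |
| DAB OD | 0.6 | strong chromogen, well above every candidate threshold |
| OD noise sd | 0.01 | visible grain without flipping any call |
| cytoplasm ring | 3 px | matches the detector's annulus |

Exact-assignment mode is on by default: exactly
`round(fraction * n_cells)` cells are positive, so image-level ground truth
is noiseless and recovery tests measure the pipeline, not binomial noise
(i.i.d. Bernoulli mode is available by flag). Intensity tables are log10
Gaussian mixtures with per-sample additive shifts — an assumption consistent
with the gating model, since no upstream distributional detail is published
— and observer counts are truth + bias + Gaussian miscount noise, floored
at zero.

What the generator does **not** emulate: tissue autofluorescence, stromal
architecture, touching or overlapping nuclei, staining gradients within a
section, and imaging-cycle registration error. A green recovery test
therefore establishes that the computations are correct on data satisfying
the model's assumptions, not that the detector would segment dense real
tissue; on real slides the CellProfiler-class segmentation problem is much
harder.

One numerical corner is worth knowing: with a positive fraction of exactly
0.5, a sample's median sits in the gap between the two intensity modes and
is unstable, so median-based shift estimation degrades. Shift-recovery
tests use a 0.4 fraction; real panels are rarely balanced to the percent.

## Numerical and degenerate-input policy

* Zero-variance inputs to correlation or mixture fitting raise typed errors
  (`ihcgate_zero_variance`) rather than returning `NaN`.
* `percent_positive` with a zero denominator raises
  `ihcgate_undefined_score`; `score_section` flags and excludes such ROIs
  with a warning instead of failing the section.
* EM non-convergence returns the best fit with `converged = FALSE`;
  `gate_marker()` refuses it unless explicitly overridden.
* All simulators consume an explicit integer seed and restore the caller's
  RNG state (`withr::with_seed`); identical parameters and seed give
  bit-identical outputs, including the written PNG bytes.

## Limitations

Beyond the generator's idealizations above: stain vectors are fixed, not
estimated from the image (no Macenko-style estimation); whole-slide tiling
and tumor/stroma classification are out of scope (ROI selection is a manual
upstream step); and the gate-at-the-peak rule is reproduced as specified
even though a valley-based threshold would call the positive population
more completely.
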