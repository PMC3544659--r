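---
title: "Quantitative IHC scoring: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative IHC scoring: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The problem

Immunohistochemistry (IHC) visualises a target protein — here the human
sodium iodide symporter (hNIS) in breast tumor sections, but the method
is generic for any DAB-stained marker — as a brown
3,3'-diaminobenzidine (DAB) precipitate over a blue hematoxylin nuclear
counterstain. Clinical read-out is a four-tier grade (negative 0, low
positive 1+, positive 2+, high positive 3+) assigned by a pathologist by
eye, a process with well-documented inter- and intra-observer
variability. `ihcscore` implements a semi-automated alternative: a fixed,
reproducible function from the digital image to the grade.

## Stain separation

Brightfield absorption follows the Beer–Lambert law, so stains are
additive in optical density (OD), not in RGB. Per channel
$c \in \{R,G,B\}$ with white level $I_{0,c}$:

$$OD_c = -\log_{10}\!\left(\frac{\max(I_c, \varepsilon)}{I_{0,c}}\right),
\qquad OD = S\,\kappa,$$

where the columns of $S$ are unit-norm stain OD vectors (hematoxylin,
DAB, and a residual completing the basis) and $\kappa$ holds the per-pixel
stain concentrations. Color de-convolution is the linear inversion
$\kappa = S^{-1} OD$, after which the pure-DAB channel is re-expressed as
an 8-bit intensity image $I_{DAB} = 255 \cdot 10^{-\kappa_{DAB}}$, so 0
is the darkest brown and 255 is unstained white.

Numerical choices:

* **Stain vectors.** The published method names only ImageJ-style color
  de-convolution, not its vectors; the `"hdab"` preset therefore uses the
  widely published Ruifrok-derived H-DAB values, hematoxylin
  (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), with the residual
  the normalized cross product. Any 3×2 or 3×3 matrix (or a text file)
  can be substituted via `stain_matrix()` / the `stains` config field.
* **$\varepsilon$ = 1 intensity unit**, applied as a *floor* on the
  transmitted intensity. This bounds OD at $\log_{10} 255 \approx 2.4$
  and avoids $\log 0$, while leaving every intensity $\ge 1$ exactly
  unbiased. An additive form ($I + \varepsilon$) was considered and
  rejected: once amplified by $S^{-1}$ its systematic bias inflates the
  reconstruction error of the DAB channel beyond the 8-bit quantization
  budget (±2 intensity units) that the round-trip tests enforce.
* **Background $I_0$** defaults to (255, 255, 255); slides are standard
  brightfield with near-white background. `background: estimate` switches
  to the per-image 99th-percentile channel value for slides with a grey
  cast.
* **Negative concentrations are clamped to 0** — they are physical
  quantities, and negative values only arise from noise below the stain
  plane.
* All arithmetic is floating point; quantization to 8 bits happens once,
  at channel reconstruction, with round-half-away-from-zero.

## Zone scoring

The grade is a function of the pure-DAB intensity histogram alone. The
intensity axis is partitioned into four closed zones plus an excluded
range:

| intensity | 0–60 | 61–120 | 121–170 | 171–230 | 231–255 |
|---|---|---|---|---|---|
| meaning | 3+ | 2+ | 1+ | 0 | excluded |

Pixels above 230 are discarded as bright fatty tissue and empty glass,
which in breast sections contribute heavily in the 230–255 range and
carry no staining information. Two rules then produce the grade, in this
order:

1. **Dominance**: if one zone holds *strictly more than* 66% of the
   scoreable (non-excluded) pixels, the image takes that zone's grade
   directly. The denominator is scoreable pixels, not all pixels —
   excluded fat is declared uninformative, so it cannot dilute a
   dominant zone. Exactly 66% does not trigger the rule.
2. **Weighted formula**: otherwise the zone-weighted mean
   $(3n_3 + 2n_2 + 1n_1 + 0n_0)/(n_3+n_2+n_1+n_0)$ is computed and
   rounded half-up to the grade. The original publication shows its
   algebraic formula only as an unavailable figure; the zone-weighted
   mean is the simplest formula consistent with the surrounding
   procedure and is deliberately isolated behind `weighted_score()` so a
   different form can be swapped in. Half-up rounding (1.5 → 2+) favors
   detection sensitivity; `rounding: half_even` is available.

`stained_area()` reproduces the pathologist's area categories — negative
(< 10% stained), focal (10–20%), patchy (20–70%), diffused (≥ 70%) —
with "stained" meaning any positive-zone pixel (intensity ≤ 170 by
default). The printed area bins overlap ("20–70%", "more than 70–80%");
they are resolved as half-open bins with a single cut at 70% for
diffused. These manual-era categories predate the digital method, so the
170 threshold is a documented mapping choice, configurable as
`area_threshold`.

For heterogeneous sections, `average_grade()` implements the recommended
remedy of scoring several fields of view and averaging their weighted
scores before rounding; dominance is a per-image device and is not
applied to the aggregate.

## The synthetic image generator

No public image set accompanies the reference cohort, so validation runs on
seeded synthetic images (`render_ihc()`) that emulate the tissue classes
the scorer must separate: DAB-stained tumor regions targeted at a chosen
zone, lightly stained stroma (zone 0), hematoxylin-counterstained
nuclei, and bright background above the exclusion cutoff. Pixels are
assigned to regions as shuffled rectangular tiles — the histogram scorer
is geometry-blind, so simple shapes suffice — and concentrations are
drawn uniformly per region, forward-rendered through the same
Beer–Lambert model ($RGB = I_0 \cdot 10^{-S\kappa}$), quantized, and
perturbed with additive Gaussian channel noise.

Generator conditions (the defaults used by the test suite and the
acceptance script):

* **Zone calibration is computed, not hard-coded**: the DAB
  concentration range for a target zone is obtained by inverting
  $I = 255\cdot10^{-\kappa}$ over the zone's intensity interval shrunk
  by a 3-unit margin (and a floor of intensity 15 for the open-ended 3+
  zone), so the calibration stays correct under a different stain
  matrix, and 8-bit quantization cannot push a noise-free pixel across a
  zone boundary.
* **Hematoxylin counterstain concentration 0.05–0.4**: a light-to-
  moderate nuclear counterstain. Beyond roughly 0.5 the quantization
  cross-talk of unmixing alone can exceed the ±2 intensity-unit
  round-trip budget, which real ImageJ-style pipelines also inherit.
* **Noise sd = 2** grey levels per channel: typical sensor/compression
  jitter; grade recovery stays at or above 95% over 200 seeded images
  while still exercising zone-boundary robustness.
* **Single-grade layout** (`grade_region_spec()`): 72% tumor tissue in
  the target zone, 13% stroma, 15% background for positive grades (85%
  zone-0 tissue + 15% background for grade 0), making the tumor zone
  ~85% of scoreable pixels so the ground-truth grade follows from the
  dominance rule.
* The ground-truth grade is computed *analytically* from the realized
  tile areas via the same dominance/weighted rules, never by running the
  scorer on the image.

What the generator does **not** emulate: nucleus-level morphology,
texture, chromatic aberration, uneven illumination, or the low
tumor-to-stroma fields that drive most manual/automated disagreement in
real cohorts. Passing the synthetic recovery tests therefore shows the
scoring function is a correct implementation of its rules under its own
image model — not that it resolves the biological ambiguities of real
slides.

## Cohort statistics

`cohort_summary()` tabulates positivity (grade ≥ 1+, matching the
positive/negative dichotomy under which 1+ and 2+ count as positive) per
stratum, carrying exact percentages alongside half-up-rounded reporting
values. `percent_agreement()` and `cohens_kappa()` compare two graders
over the four ordinal categories; kappa is unweighted by default (the
published analysis does not state weighting) with linear weights as an
option. `chi_square_2x2()` is Pearson's test without the Yates
correction by default — standard practice when the original software is
unspecified — with `yates = TRUE` available. On the reference cohort's
ER-status table (32/4 vs 44/28) the uncorrected test gives
$\chi^2 = 8.88$, $p = 0.0029$ and the corrected one $p = 0.0058$; the
published analysis reports $p = 0.0033$, which matches neither variant exactly and
presumably reflects a different software default. The package reports
both and does not tune toward the published value. Two further printed
percentages (54% post-chemotherapy positivity; 81%/63% by menopause) are
arithmetically inconsistent with their own enumerated counts and are
reproduced only as counts.

## Problem sizes and determinism

The validation suite uses 48×48 to 64×64 pixel images (a histogram
scorer is resolution-independent, so small fields are fully
representative), 200 seeded images for recovery rates, 100 random
concentration fields for the round-trip bound, and a 108-sample
synthetic cohort mirroring the reference subtype layout. All randomness
passes through explicit integer seeds; `render_ihc()` and
`generate_cohort()` restore the caller's RNG state, and regenerating
with the same seed is bit-exact.

## Known limitations

* Whole-slide pyramidal formats, ≥3-stain unmixing and stain-vector
  estimation from the image are out of scope.
* The weighted formula is an explicit reconstruction (see above), not a
  transcription of the unpublished original.
* Scores on real slides with low tumor-to-stroma ratio are biased
  toward lower grades, as the published analysis observes; the provided remedy is
  `average_grade()` over multiple fields, not tissue segmentation.
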