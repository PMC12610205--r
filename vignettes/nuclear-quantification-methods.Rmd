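---
title: "Quantifying nuclear staining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear staining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucquant)
```

## The problem

Many regulatory proteins — nuclear receptors, stress kinases, transcription
factors — shuttle between cytoplasm and nucleus, and their *nuclear*
abundance is what matters biologically. On a stained micrograph the antigen
may be present at varying intensity in both compartments, so the question a
scorer must answer per cell is not "is there staining?" but "does the
staining occupy the nucleus?". Manual scoring of this is slow and shows
large interobserver variability. `nucquant` automates it: it segments
nuclei, segments antibody signal independently, and calls a nucleus
positive when the signal mask covers a sufficient fraction of the nuclear
area. Because positivity is defined by *coverage of the nucleus*, the call
is insensitive to cytoplasmic staining surrounding it.

## The pipeline

Each field of view is processed in three steps:

1. **Nucleus detection.** For H-DAB brightfield images the RGB field is
   first separated into haematoxylin and DAB channels by colour
   deconvolution (below). The nuclei channel is thresholded with one of 17
   automatic histogram algorithms, 8-connected components are labelled, and
   objects are gated by area (default 300–1200 px). For fluorescence the
   nuclei channel is thresholded directly (bright objects on a dark
   background). In *preprocessed* mode an externally produced mask or label
   image (e.g. from StarDist or Trainable WEKA) replaces internal
   segmentation entirely.
2. **Signal detection.** The signal channel (DAB pseudo-transmittance or
   the fluorescence signal image) is thresholded independently; only this
   threshold accepts a manual offset (`signal_offset`), mirroring the
   original tool's slider. Nucleus thresholding stays fully automatic.
3. **Overlap.** For each nucleus region $N_i$ with area $|N_i|$ and signal
   mask $S$, the coverage fraction is
   $c_i = |N_i \cap S| / |N_i|$, and the nucleus is positive iff
   $c_i \ge \tau$ with $\tau = 0.80$ by default. The field-level result is
   the percentage of positive nuclei.

An empty field (no nuclei surviving the gate) reports an *undefined*
percentage with a warning rather than 0 — "no cells" and "no positivity"
are different findings and batch summaries must not conflate them.

## Colour deconvolution

Brightfield staining attenuates light multiplicatively, so intensities are
converted to optical densities $OD = -\log_{10}(\max(I, 1)/255)$ per
channel (the clamp at 1 keeps OD finite at zero intensity while preserving
monotonicity). Stains mix additively in OD space: $OD = M^\top c$, where
the rows of $M$ are unit stain vectors and $c$ the stain concentrations.
The default $M$ is the standard H-DAB basis of Ruifrok & Johnston as
shipped with ImageJ/Fiji — haematoxylin $(0.650, 0.704, 0.286)$, DAB
$(0.268, 0.570, 0.776)$, residual their normalized cross product — and is
user-overridable. After solving for $c$ and clipping negatives, each stain
channel is re-exposed as 8-bit pseudo-transmittance
$\mathrm{round}(255 \cdot 10^{-c})$, in which darker = more stain. This
scale matters: the semiquantitative intensity cut-offs below are defined on
it. The same model run forward (`render_from_concentrations()`) is the
synthetic generator's renderer, which gives the package an exact
round-trip test: separate(render($c$)) recovers the 8-bit closed form
within ±2 gray levels across $c \in [0, 2]$.

DAB staining itself is not stoichiometric and does not follow Beer–Lambert
exactly, which is why intensity output for H-DAB is semiquantitative
(classes) rather than a continuous estimate; fluorescence intensity is
fully quantitative.

## Automatic thresholding

All 17 algorithms of the ImageJ/Fiji AutoThreshold suite are implemented
from their primary sources: Default (the platform's original iterative
intermeans), Huang, Huang2, Intermodes, IsoData, Li, MaxEntropy, Mean,
MinError, Minimum, Moments, Otsu, Percentile, RenyiEntropy, Shanbhag,
Triangle and Yen. Conventions that the literature leaves open are fixed as
follows, for determinism:

* ties inside iterative and criterion-maximizing algorithms break toward
  the **lower** threshold;
* a degenerate histogram (all pixels one value) returns that bin, with a
  warning, for every method — batch runs on empty fields must not die;
* `Huang2` applies Huang's fuzziness criterion with unrounded class means
  (the platform's second implementation differs from the first only in
  bin-level details);
* `Intermodes`/`Minimum` fall back to `Mean` with a warning when 10,000
  smoothing passes fail to produce a bimodal histogram (possible when all
  mass sits in the outermost bins, which can never form interior modes);
* thresholding polarity is explicit: `dark_object` selects $I \le t$
  (deconvoluted brightfield channels), `bright_object` selects $I \ge t$
  (fluorescence). The original publication does not state polarity; this
  choice is ours and is covered by nesting tests
  ($\mathrm{mask}(t) \subseteq \mathrm{mask}(t+1)$ for dark objects).
* a *constant* signal channel yields an empty signal mask (with a
  warning): composing the degenerate-histogram convention with
  bright-object polarity would otherwise select every pixel of an all-dark
  channel, turning "no signal anywhere" into "everything positive".

Otsu is verified in the test suite against an exhaustive between-class
variance search, and several methods agree with independent
implementations in the wider ecosystem where the variants coincide.

## Segmentation conventions

Connected components use **8-connectivity** (diagonal contact merges), the
particle-analysis default of the platform the method originates from, and
labels are assigned in raster-scan order of each component's first pixel so
labelling is reproducible. Holes inside nuclei (unstained nucleoli) are
filled by default before area measurement, so coverage is computed over
the full nuclear area; edge-touching objects are kept by default. Both are
configurable (`fill_holes`, `exclude_edges`). Touching nuclei are *not*
watershed-split: clumps exceed `max_area` and are discarded by the gate,
which is the described behaviour of the original method. The area gate
defaults to 300–1200 px, the published setting for the cell lines the
method was tuned on (measured at 200x magnification, 1920x1200 px
fields); it should be re-measured for other material.

## Positivity, intensity classes and scores

The coverage boundary is **inclusive**: $c_i = \tau$ counts as positive
("the positive signal area represented 80% of the nucleus" reads as
attainment). Intensity classes apply only to positive nuclei — a
non-positive nucleus is *negative* regardless of staining — and are based
on the mean gray value of the nucleus on the DAB pseudo-transmittance
channel:

| class    | mean gray value |
|----------|-----------------|
| strong   | $< 60$          |
| moderate | $[60, 120)$     |
| weak     | $\ge 120$       |

The field summary then reports
$\mathrm{histoscore} = 3\,p_s + 2\,p_m + 1\,p_w \in [0, 300]$ and the
overall intensity score
$4\,p_s + 3\,p_m + 2\,p_w + 1\,p_n \in [100, 400]$, where $p_s, p_m, p_w,
p_n$ are the class percentages. Since the percentages sum to 100 the two
scores are algebraically locked: overall = histoscore + 100 (asserted on
random compositions in the tests). The overall category uses
upper-inclusive intervals — negative $[100, 101]$, weak $(101, 201]$,
moderate $(201, 301]$, strong $(301, 400]$ — preserving the published
strict "> 301" for strong while making the categories a partition (the
printed ranges overlap at their endpoints). A 1% cut-off overrides the
score: a field with $\ge 99\%$ negative nuclei is categorized negative
outright.

For fluorescence, quantitative mode returns the per-nucleus mean gray
value on the signal channel, for all nuclei or positive nuclei only.

## Agreement statistics and threshold calibration

The coverage threshold $\tau$ is a calibrated quantity, not a constant of
nature. `calibrate_coverage_threshold()` re-analyzes a panel of fields at
each candidate $\tau$ (default sweep 0.1–1.0 in steps of 0.1) and compares
program scores with a human consensus (unweighted mean of the included
raters) using the intraclass correlation coefficient, two-way model,
absolute agreement, single measures:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with $MS_R$, $MS_C$, $MS_E$ the row, column and residual mean squares of
the $n \times k$ table. Absolute agreement (rather than consistency)
penalizes systematic offsets between program and raters, which is the
right property for a calibration target. Whether the original analysis
used single- or average-measures ICC is not printed; we default to single
measures and expose `type = "average"`
($\mathrm{ICC}(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)$). The
sweep returns the full ICC curve and the argmax threshold, ties resolved
toward the lower threshold for determinism. ICC > 0.75 is labelled good
and > 0.9 excellent reliability (strict inequalities). Supporting
statistics (`pair_stats()`) give the mean difference, its SD, the t-based
95% CI, and Pearson's r; r is returned as `NA` when either vector has zero
variance rather than silently taking a limit.

## The synthetic generator

Because the original micrographs and rater data are not redistributable,
the package carries a seeded generator whose fields have *exact* ground
truth. Nuclei are non-overlapping disks (rejection-sampled centres,
pairwise margin 2 px, capped at 10,000 attempts); each disk's signal
occupies a contiguous angular sector of exactly
$\mathrm{round}(c \cdot |N|)$ pixels, selected by sorting disk pixels by
polar angle (ties by radius, then raster order). A sector, not scattered
pixels, mimics the geometry of partial nuclear staining while keeping the
pixel count exactly countable. H-DAB fields are composed through the
forward deconvolution model; fluorescence pairs set disks to
$\mathrm{round}(255 \cdot c_{hema})$ and sectors to
$\mathrm{round}(255 \cdot c_{dab})$ on black. Defaults: 300×400 px
fields, radii 10–18 px (areas ≈ 320–1000 px, inside the default particle
gate), haematoxylin 0.7 OD, DAB 0.8 OD, no noise. Optional Gaussian noise
is seeded and re-quantized to 8-bit; the noisy test condition uses an SD
of 8 gray levels (≈ 3% of the 8-bit range, camera-like). Simulated rater
panels score each field at its true percent positive ($\tau = 0.8$) plus
independent Gaussian noise (default SD 5 points, 5 raters — the size of
the included human panel), clipped to [0, 100].

What the generator does **not** emulate: tissue texture, uneven
illumination, stain gradients within a nucleus, touching/overlapping
nuclei, non-circular nuclear shapes, and chromatic noise correlations.
Passing the recovery tests therefore demonstrates correctness of the
*computational* pipeline — segmentation arithmetic, coverage counting,
classification boundaries — not robustness to histological artefacts;
threshold-algorithm choice on real material remains the user's
responsibility, as the original method also advises.

## Problem sizes and numerical choices

The test suite and the acceptance script run on 300×400 px fields with
8–20 nuclei per field, panels of 5–6 fields, 200-histogram oracle sweeps
and 3×3–5×4 ICC tables; these sizes exercise every code path while keeping
a full run in the low minutes on one CPU. Key numerical conventions:
16-bit inputs are rescaled by the full-range linear map (not per-image
min–max, so one scale holds across a batch); RGB→gray uses the unweighted
channel mean, the convention of the originating platform; coverage
fractions are exact rational counts; CSV output prints fractions with 4
decimals; all RNG use is seeded and generator calls restore the caller's
RNG state.

## Known limitations

* No watershed splitting: heavily confluent material loses clumped nuclei
  to the max-area gate, which biases sampling toward isolated cells.
* The stain matrix is assumed, not estimated; strongly non-standard
  staining protocols require supplying custom vectors.
* The 60/120 intensity cut-offs are only meaningful on the 8-bit DAB
  pseudo-transmittance scale produced by this deconvolution; applying
  semiquantitative mode to arbitrary channels is not supported.
* Agreement statistics assume complete tables (every rater scored every
  image).
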