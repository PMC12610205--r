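# nucquant

Single-cell quantification of **nuclear** antibody staining in microscopy
fields — for histologists, pathologists and cell biologists who need the
percentage of cells with a positive nucleus, independent of any
cytoplasmic staining, without manual scoring.

Many regulatory proteins (nuclear receptors such as PPARα, stress kinases
such as phospho-p38) shuttle between cytoplasm and nucleus, and their
nuclear abundance is the biologically meaningful readout. Manual scoring
of nuclear positivity is slow and notoriously variable between observers.
`nucquant` automates it for both H-DAB brightfield images and two-channel
fluorescence images, and also ingests externally produced nucleus masks
(StarDist, Trainable WEKA, Cellpose, ...).

## The method

For each field of view:

1. **Nuclei** are segmented: H-DAB images are separated into haematoxylin
   and DAB channels by colour deconvolution (Beer–Lambert optical
   densities, Ruifrok–Johnston H-DAB stain vectors), the nuclei channel is
   thresholded with one of the 17 classical histogram algorithms (Otsu,
   Li, Huang, MaxEntropy, Triangle, ...), and 8-connected components are
   gated by area (default 300–1200 px).
2. **Signal** is thresholded independently on the DAB or fluorescence
   channel (with an optional manual offset).
3. **Overlap** decides positivity: nucleus *i* with pixel set *Nᵢ* and
   signal mask *S* has coverage *cᵢ = |Nᵢ ∩ S| / |Nᵢ|*, and is positive
   iff *cᵢ ≥ τ* (default τ = 0.80, calibrated against human rater
   consensus and user-adjustable).

Optional intensity output: semiquantitative classes on the DAB channel
(strong: mean gray < 60, moderate: [60, 120), weak: ≥ 120, computed for
positive nuclei only), the histoscore
`3·%strong + 2·%moderate + 1·%weak` (0–300), an overall score
`4·%strong + 3·%moderate + 2·%weak + 1·%negative` (100–400) with a
field-level category (> 301 strong, 201–301 moderate, 101–201 weak, and a
1% cut-off: ≥ 99% negative nuclei force a negative call), and quantitative
per-nucleus mean intensities for fluorescence.

A calibration module sweeps τ over 0.1–1.0 and selects the value
maximizing the intraclass correlation (two-way, absolute agreement)
between program output and rater consensus; agreement helpers report ICC,
Pearson r, mean difference, SD and 95% CI.

## Worked example

The package ships a seeded generator of synthetic fields with exact
per-nucleus ground truth, so you can try the full pipeline without data:

```r
library(nucquant)

# 20 disk nuclei; 9 with 95% of their area covered by signal,
# 11 with 30% or 10% coverage
spec <- make_field_spec(seed = 42, n_nuclei = 20,
                        coverage = c(rep(0.95, 9), rep(c(0.3, 0.1), c(6, 5))))
field <- analyze_field(image = render_h_dab(spec)$image,
                       config = quant_config("h_dab",
                                             intensity_mode = "semiquantitative"))
field
#> Field analysis (h_dab mode)
#>   nuclei detected: 20
#>   positive nuclei: 9 (45.0%) at coverage >= 0.80
#>   classes: 45.0% strong / 0.0% moderate / 0.0% weak / 55.0% negative
#>   histoscore: 135.0; overall score 235.0 (moderate)

head(regions_table(field$regions), 3)
#>   label area mean_gray  coverage positive intensity_class
#> 1     1  746 190.14209 0.3002681    FALSE        negative
#> 2     2  450 233.40000 0.1000000    FALSE        negative
#> 3     3  794  49.88161 0.9496222     TRUE          strong
```

All 20 nuclei are recovered and the 45% positive fraction matches the
design exactly: the nine nuclei at 95% coverage clear the 80% threshold,
the rest do not. Per nucleus you get area (px), mean gray value on the
DAB pseudo-transmittance channel (dark = strongly stained: 49.9 for a
covered nucleus vs 233.4 for an unstained one), the measured coverage
fraction, and the positivity/intensity call. `plot(field)` draws the
colour-coded overlay; `write_nucleus_table()` / `write_overlay()` export
results.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/nucquant.R simulate --seed 1 --n-fields 20 --out fields/
Rscript inst/cli/nucquant.R batch --mode h-dab --input-dir fields/ \
        --intensity semi --out results/
Rscript inst/cli/nucquant.R calibrate --input-dir fields/ \
        --raters raters.csv --out calibration/
```

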