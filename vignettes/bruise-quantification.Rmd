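---
title: "Quantifying blueberry bruising from NIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blueberry bruising from NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsibruise)
```

## The problem

Blueberry bruising is subcutaneous: the skin stays intact while damaged
cells release free water and phenolic compounds oxidize. The standard
assessments are destructive and subjective — a grader slices each fruit
along its equator and scores the discolored share of the cut face, or an
instrument compresses the berry to read firmness. Both miss bruises that
sit away from the slice plane or the compression axis.

In the 950–1650 nm range, free water absorbs strongly near 980, 1200 and
1470 nm, so bruised tissue reflects less NIR light than healthy tissue and,
critically, its reflectance stays *flat* between 1470 and 1650 nm where
healthy tissue turns upward again. A hyperspectral camera therefore sees
bruises through the intact skin. `hsibruise` implements the full analysis
chain from raw camera cubes to a per-fruit **bruise ratio index** — the
fraction of a fruit's pixels classified as bruised — plus the reference
measurements (firmness, human assessment) and the statistical battery used
to compare them.

## Pipeline model

For a raw cube $S$, white reference $W$ and dark reference $D$ (digital
numbers on the camera's 12-bit scale), reflectance is the flat-field
correction

$$R = \frac{S - D}{W - D},$$

computed per pixel and band, which removes illumination non-uniformity and
per-pixel sensitivity differences. Segmentation thresholds the raw 1075 nm
band — where berry/background contrast peaks — then fills holes, removes
specks below `min_object_px`, and labels 8-connected components as berries.
The calyx end reflects little NIR light at all bands and mimics bruise
spectra, so a 5-pixel-radius closed disc at each component center is
excluded from classification.

Pixel spectra are normalized by dividing each spectrum by its own mean
(scale invariance removes multiplicative illumination differences between
acquisitions; SNV is available as an alternative — the choice matters
little once classes are separated by shape). A soft-margin RBF
support-vector classifier with library defaults (cost 1, kernel width
$1/B$ for $B$ bands, no tuning) assigns each berry pixel to
healthy/bruised. The per-berry bruise ratio index is

$$\mathrm{BRI} = \frac{\#\{\text{bruised pixels}\}}{\#\{\text{countable
fruit pixels}\}},$$

with calyx-excluded pixels removed from numerator *and* denominator
(removing them only from the numerator would bias small berries downward),
averaged over the stem- and calyx-side images when a tray is imaged twice.
A fruit is called bruised when the index strictly exceeds 0.2.

Reference firmness is the least-squares slope (N/mm) of the parallel-plate
force/deformation curve restricted to 0.5–2.5 mm, where such curves are
near-straight. Firmness prediction from per-berry mean spectra uses partial
least squares regression fitted by NIPALS on centered data; the component
count is chosen by 10-fold cross-validation minimizing RMSEP, capped at 20.
Mean spectra enter unnormalized: normalization is a classification device,
while the firmness literature regresses on reflectance.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| segmentation band | 1075 | nm | berry/background contrast maximum |
| threshold | 942 (alt. 737) | DN of 4095 | foreground strictly above level |
| `min_object_px` | 50 | px | speck removal after hole filling |
| calyx radius | 5 | px | exclusion disc at component center |
| SVM cost / width | 1, 1/141 | — | library defaults, deliberately untuned |
| CV folds / repeats | 10, 5 | — | accuracy mean; sd across re-randomized runs |
| bruise threshold | 0.2 | index | strict (`>`) bruised call |
| firmness window | 0.5–2.5 | mm | straight part of the curve |

The printed thresholds (737 and 942) are on the raw DN scale; whether the
original protocol applied them before or after flat-field correction is not
documented, so we threshold the raw DN band and apply the mask to the
reflectance cube (thresholding reflectance instead is configurable). The
threshold inequality is strict; with integer DN data the choice of `>`
versus `>=` moves the boundary by one gray level. The reported ± spread on
cross-validation accuracy is interpreted as the standard deviation across
repeated re-randomized fold assignments.

## The phantom generator

Real acquisitions of this kind are not publicly deposited, so the package
ships a synthetic phantom generator whose defaults state the study
conditions: trays of 25 disjoint near-circular berries (radius 16–20 px on
a 240×240 px scene — spheres project to discs and the physical sample
holders kept fruit apart), a dark background, a smooth multiplicative
illumination gradient captured by the white reference, additive Gaussian
sensor noise (sd 0.02 on the reflectance scale), and a dark 5-px calyx spot
at each berry center. Healthy/bruised reference spectra follow the
water-absorption physiology above; per-pixel spectra are convex mixtures of
the two with a mixture weight drawn per pixel, so the bruise region
contains genuinely ambiguous, partially-bruised pixels. Bruises are
one-sided caps of the berry disc, more severe on the stem side
(attenuation 0.6 on the calyx side). Per-fruit firmness is linear in the
true bruise fraction (2.4 − 1.5·fraction N/mm, noise sd 0.075), and the
simulated grader sees only the central slice row of the bruise mask plus
truncated Gaussian noise (sd 0.08) — deliberately blind to off-slice
bruises, reproducing the known failure mode of human assessment.

The mixture-weight distributions are the generator's class-separation dial.
They were calibrated once so that 10-fold cross-validation accuracy of the
default pipeline lands in the mid-90s (the regime the method is designed
for) while per-berry index errors stay small, and then frozen:
bruised-region weight ~ N(0.74, 0.23) clipped to [0.02, 1], healthy-region
weight ~ N(0.04, 0.14) clipped to [0, 0.6]. A consequence worth knowing:
a minority of bruise-region pixels are nearer the healthy reference than
the bruised one — by design, since fully separable classes would make every
downstream accuracy figure trivially 100%.

What the phantom does *not* emulate: specular glare and BRDF effects,
partial-volume mixing at berry boundaries, touching fruit (no watershed is
implemented), bruise development over storage time, and any real
cultivar-level spectral diversity. Passing phantom tests therefore
demonstrates that the algorithms are implemented correctly and are
well-behaved under controlled noise, not that the published real-fruit
accuracies are reproduced — those depend on data that are not available.

## Numerical and design choices

* **Indexing.** Rows/columns/bands are 1-based `(row, col, band)`, the R
  convention; ENVI interleave (BIL/BSQ/BIP) is handled only at the I/O
  boundary, and round trips are bit-exact for integer DN cubes.
* **Nearest-band lookup** rather than interpolation for named wavelengths
  (all referenced wavelengths are on-grid, so lookup is exact); ties break
  toward the lower band.
* **Connectivity** is 8-neighbor by default (4-neighbor available). The
  component "center" is the pixel centroid rounded to the nearest pixel.
  Berries are numbered in raster-scan order of their first pixel;
  cross-image correspondence uses nearest-center matching, which is robust
  to that numbering.
* **Calyx disc membership** is the closed disc (squared distance ≤ r²),
  clipped to the berry's own pixels: 81 lattice points at radius 5.
* **Balancing** keeps the minority class whole and subsamples the majority
  uniformly without replacement under a documented seed (default 17).
* **Degenerate inputs** fail loudly: empty ROIs, one-class libraries,
  constant responses, singular MANOVA scatter, all-identical ranks. One
  deliberate convention: comparing bruised-fruit counts that are identical
  in every replicate returns p = 1 rather than an error.
* **MANOVA dimensionality.** Testing all 141 bands needs more samples than
  variables per the Wilks/Rao machinery; rather than silently
  regularizing, the function refuses and offers band subsampling
  (`band_step`).
* **Post-hoc procedure.** The omnibus Kruskal–Wallis test is followed by
  Dunn-type two-sided comparisons on joint ranks with tie correction and
  Bonferroni adjustment; the compact letter display is assembled by greedy
  insertion over the non-significance graph, smallest mean rank first.
  (The original analysis cites an R package without naming its method;
  Dunn/Bonferroni is the conservative standard choice.)
* **PLSR.** NIPALS with deflation; at full rank it reproduces ordinary
  least squares, which the tests verify against a direct `lm()` oracle.
* **Seeds.** Every stochastic step draws from a stage-tagged stream derived
  from one master seed (`derive_seed`), so pipelines are reproducible
  end-to-end and reruns are byte-identical.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
scenes of 25 berries at 240×240 px (9 berries at 120×120 px where geometry
is incidental), training libraries capped at 600 spectra per class,
10-fold CV with 3 repeats, 300 berries for PLSR recovery, and 500 null
simulations for the type-I-error calibration of each test. These sizes were
chosen as the smallest at which the stochastic targets are stable across
seeds.

## Worked example

```{r example, eval = FALSE}
library(hsibruise)

res <- run_pipeline(pipeline_config(seed = 101))
head(res$report)
res$cv$mean_accuracy          # 10-fold CV accuracy of the pixel classifier
res$stats$kw$letters          # treatment groups sharing no letter differ
res$stats$linreg$r_squared    # bruise ratio index vs simulated grader
```

## Known limitations

The classifier is deliberately untuned (the published protocol fixed
library defaults); feature selection and parameter search are out of scope.
Bruise quantification is area-based — no volume estimate is attempted. The
two-side index assumes the same tray imaged twice with fruit in place;
there is no re-identification of shuffled fruit. And the statistical
equivalence results on phantoms say nothing about instrument-specific
artifacts (smile, keystone, stray light) that flat-field correction does
not remove.
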