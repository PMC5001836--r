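---
title: "screenpolish: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screenpolish: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenpolish)
```

## The assay and the statistic

screenpolish analyzes image-based RNAi screens that read out the nuclear
translocation of a fluorescent reporter — the motivating case is a
transcription factor (Nrf1/NFE2L1) that accumulates in the nucleus when the
proteasome is inhibited, so that knocking down a gene required for its
activation keeps the reporter cytoplasmic. The per-cell measurement is the
ratio of mean reporter intensity in a nuclear region of interest to the mean
intensity in a perinuclear ring:

* the nuclear ROI is the nuclear-stain (DAPI) mask eroded by 2 px;
* the cytoplasmic ROI is a 3 px wide ring around the stain mask, optionally
  offset by a 1 px gap (two conventions used for different cell lines, both
  supported via `gap_px`).

The well score is the median of the per-cell ratios (mean available via
config; commercial screening platforms do not document their aggregation
statistic, so the robust choice is the default). Wells with fewer than `min_cells = 20`
measurable cells are treated as missing.

## Plate normalization: median polish and B scores

Raw well scores on 384-well plates carry positional artifacts (row/column
gradients from evaporation, dispensing, incubator position). Each plate is
decomposed by Tukey's two-way median polish,

$$x_{rc} = \mu + \alpha_r + \beta_c + \varepsilon_{rc},$$

fitted by alternately sweeping row and column medians (rows first) and
folding effect medians into the grand effect. The residual
$\varepsilon_{rc}$ is the positionally corrected value, standardized into
the B score

$$B_{rc} = \frac{\varepsilon_{rc} - \mathrm{Median}}{\mathrm{MAD}},$$

with Median and MAD computed over the plate's *sample* wells only, so that
the deliberate separation of control wells cannot inflate the spread
estimate (screening platforms differ on this point; both choices are
exposed).
Two further interpretation choices are worth stating:

* The "measured value" entering the B-score formula is taken to be the
  polish residual, since the polish is applied before the standardization;
  a raw-value variant is available (`use_residuals = FALSE`).
* The MAD carries the 1.4826 normal-consistency factor by default
  (`mad_scale`), the convention in the B-score literature; published
  screens often omit whether they scale the MAD, so `mad_scale = 1` is
  equally supported and tested.

### Numerical behavior of the polish

`median_polish` iterates to `tol = 1e-12` on the maximum change of any
effect, capped at 100 sweeps. The tight default is deliberate: the L1 norm
of the residual matrix can plateau for several sweeps while the
decomposition is still moving, so looser stopping rules (including the
relative-L1 rule in `stats::medpolish`) can freeze the fit mid-trajectory.
The test suite checks agreement with an independent fixed-sweep brute-force
polish to 1e-9 on 1,000 random plates, and the reconstruction identity
$x = \mu + \alpha_r + \beta_c + \varepsilon$ is enforced exactly at every
non-missing well. Missing wells are ignored by all medians and carry no
residual; an all-missing row or column has its effect pinned at 0.

## Plate quality control

Assay robustness is summarized per plate by the Z′-factor computed from 12
negative-control and 12 positive-control wells,

$$Z' = 1 - \frac{3(s_{neg} + s_{pos})}{|\bar{x}_{neg} - \bar{x}_{pos}|},$$

with sample standard deviations. $Z' > 0.5$ is the usual acceptance bar for
an excellent assay window. "12 individual wells" is interpreted as 12 wells
per control class per plate (configurable); the statistic is undefined, and
flagged, when the control means coincide.

## The three-stage hit funnel

1. **Primary**: genes whose pooled-siRNA well has $B < -3.2$ (strict
   inequality, matching the printed cutoff), plus an explicit override list
   standing in for rescue by visual inspection of raw images.
2. **Secondary (deconvolution)**: each candidate is retested with the four
   individual siRNAs of its pool in two cell lines; an siRNA confirms when
   its well score falls below the midpoint between the retest plate's
   control means (a B-score cutoff is configurable). The pass rule keeps a
   gene when some cell line reaches `secondary_min_hits`. The phrase "more
   than two hits" is ambiguous between $\ge 2$ (common deconvolution
   practice, the default) and the literal $\ge 3$; both are implemented and
   tested, and neither is privileged as ground truth.
3. **Tertiary (bounce-back attenuation)**: inhibitor-induced fold change of
   a proteasome subunit transcript (PSMA3), referenced to GUSB, is computed
   by ΔΔCt with amplification efficiency exactly 2. A gene passes when
   knockdown attenuates the induction below `tertiary_max_ratio = 0.7`
   of the non-targeting control. Attenuation criteria are usually applied
   qualitatively in practice; 0.7 is this package's documented default, chosen as a
   conservative midpoint between "no attenuation" (1.0) and the strong
   attenuation (~0.2–0.3) expected of a true regulator, and it is exposed
   in the config.

Funnel monotonicity (final hits ⊆ secondary passes ⊆ primary hits) is
enforced structurally: stage-order violations are errors.

## The synthetic world

The generator states one fixed world rather than a tunable benchmark:

* **Well scores**: baseline nucleus:cytoplasm ratio 2.0 (induced,
  translocation intact); positive controls shifted by −1.2 to 0.8
  (translocation abolished); control noise SDs 0.08 and 0.06; sample noise
  SD 0.1; row/column gradients (0.02, 0.01) score units per well index;
  planted hits shift their well by −1.0. The control levels and SDs are
  the stated assay-window conditions; the gradient magnitudes produce a
  clearly visible artifact (up to ~0.3 score units corner to corner,
  i.e. 3σ of well noise) that the polish must remove.
* **Fields**: cells are rendered as a nuclear disk (radius 8 px) inside a
  cytoplasmic disk (outer radius 14 px), placed without overlap; the
  reporter carries intensity `true_ratio × cyto` in the nucleus and `cyto`
  in the annulus, so ground-truth masks recover `true_ratio` exactly at
  zero noise. Background applies outside cells. Noise is additive Gaussian
  (not Poisson): the downstream statistics are medians and ratios of means,
  so the noise family is not load-bearing, and the simpler model keeps
  every oracle analytic.
* **qPCR**: Ct tables are built backwards from the intended fold changes
  (base induction 4-fold, reference Ct 22, target baseline Ct 25, 3
  replicates), so ΔΔCt arithmetic recovers `base_induction × attenuation`
  exactly at zero noise.

What the generator does **not** emulate: realistic optics (PSF, chromatic
aberration, autofluorescence, uneven illumination), touching nuclei,
off-target siRNA structure, or gene–gene correlation. A green synthetic
test therefore establishes the correctness of the statistical machinery,
not the biological performance of any historical screen — raw genome-wide
screen images are rarely deposited, so reproducing a specific published
hit list is out of scope by construction.

## Degenerate inputs and tie-breaking

* Cells whose nuclear ROI erodes below `min_nuclear_px = 4` pixels, or
  whose ring has zero mean intensity, are flagged and excluded from well
  aggregation.
* Ring pixels contested by two cells go to the nearer nucleus; exact ties
  go to the lower label.
* A plate whose sample residuals have zero MAD, or fewer than 8 usable
  sample wells, is an error, not a silent NA.
* All randomness flows from one master seed through a documented splitting
  scheme (`split_seed`), keeping every derived seed in 32-bit range;
  regeneration of any plate, field or table is bit-identical.

## File formats

Tables are CSV/TSV with a `#`-prefixed provenance header (stage, config
hash, seed). Images are exchanged as plain-text 16-bit PGM (P2) rather
than TIFF: the supported toolchain has no TIFF codec available, PGM is
lossless for the integer-valued synthetic channels, and the in-memory
representation (a plain numeric matrix) is format-agnostic so a TIFF
reader can be slotted in without touching the analysis code.
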