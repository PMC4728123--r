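---
title: "Methods: single-molecule mobility, adhesion enrichment and colocalization"
author: "sptmobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule mobility, adhesion enrichment and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptmobility)
```

## The problem

Single-particle tracking PALM (sptPALM) of photoswitchable membrane
receptors yields tens of thousands of short molecular trajectories per
cell. This package implements the per-track analytics used to ask whether
a receptor's mobility depends on where it sits relative to focal
adhesions: diffusion coefficients from mean-squared-displacement (MSD)
curves, a confinement radius, a three-way mobility classification, track
density enrichment inside versus outside an adhesion mask, a
profile-based two-channel colocalization index, and a spectral-count
abundance screen for candidate interactors. A seeded synthetic-data
generator reproduces the statistical structure of each input so every
stage can be validated against known ground truth without microscope
data.

## Trajectory model and estimators

A trajectory is a sequence of $N$ positions $(x_i, y_i)$ in µm at frame
interval $\Delta t$. Only tracks with $5 \le N \le 20$ frames (0.5–2 s at
10 fps) are analyzed: shorter tracks cannot support the four-lag MSD
regression, longer ones are unlikely to be single fluorophores. Both
bounds are inclusive.

The MSD at lag $\tau = n\Delta t$ averages over all overlapping pairs:

$$\mathrm{MSD}(n\Delta t) = \frac{1}{N-n}\sum_{i=1}^{N-n}
  (x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2 .$$

The diffusion coefficient is one-fourth of the slope of the
least-squares line through the first four MSD points
($\mathrm{MSD}(\tau) = 4D\tau$ for 2D Brownian motion). The line is
fitted **with a free intercept**: static localization error $\sigma$
adds a constant $4\sigma^2$ to every lag, which the intercept absorbs
while leaving the slope — and hence $D$ — unbiased. For exactly linear
MSD curves the through-origin and free-intercept fits coincide, so the
definitional ratio $D = \text{slope}/4$ is unaffected by this choice. On
noisy short tracks the fitted slope can be negative; the estimate is
reported as computed, and clamped to zero only inside the classifier.

The radius of confinement $r_\mathrm{conf}$ is the radius of the exact
minimum enclosing circle of the track, computed with Welzl's
move-to-front algorithm (the test suite checks it against an exhaustive
pair/triple enumeration to $10^{-9}$ µm). It is not approximated by half
the maximum pairwise distance, which underestimates the radius for
obtuse point sets.

Classification uses strict thresholds, applied in order: **immobile** if
$r_\mathrm{conf} < 0.166$ µm (one camera pixel); otherwise **confined**
if $D < 0.2$ µm²/s; otherwise **free**.

`spt_fit()` packages this chain — filter, MSD, $D$, $r_\mathrm{conf}$,
class, optional adhesion-region label — into a classed object with
`print`, `summary`, `coef` and `plot` methods. `predict`/`residuals`
methods are not provided: the estimator is per-trajectory and
non-parametric, so there is no new-data prediction to make.

## Adhesion context

The adhesion mask is a binary pixel grid (nonzero = adhesion) with a
physical pixel size, 0.166 µm by default. Coordinates follow one
convention everywhere: 0-based pixels, (row, col) order in images, x in
µm along columns and y along rows, half-open pixel extents, so the point
$(x, y)$ falls in pixel $(\lfloor y/s \rfloor, \lfloor x/s \rfloor)$. A
track is *inside* only if every localization is in a mask-true pixel,
*outside* only if every localization is in a mask-false pixel; tracks
that straddle the boundary — or leave the imaged field entirely — are
*discarded* from quantitative analysis.

Enrichment is quantified within rectangular adhesion-rich regions of
interest, defined strictly as mask coverage $> 25\%$ of the ROI. Within
a qualifying ROI,

$$\text{enrichment ratio} =
  \frac{n_\text{inside}/A_\text{inside}}{n_\text{outside}/A_\text{outside}},$$

with areas in µm² measured inside the ROI only and each track counted
once, by the pixel of its first localization. Per-track (rather than
per-localization) counting matches a density expressed in tracks/µm²;
counting localizations would weight long immobile tracks more heavily.
A ROI with no outside tracks raises an error rather than reporting an
infinite ratio.

## Colocalization index

Two 8-bit intensity profiles sampled at the same points along a line
(bilinear interpolation, optionally after a 0.6-pixel Gaussian blur of
both channels) are compared pointwise. Each pair $(a_k, b_k)$ is a point
in the intensity plane; points above the identity line are reflected
across $y = x$, which preserves their distance from the line and folds
the cloud into $y \le x$. The index is the magnitude of the slope of the
through-origin least-squares line, $\sum x_k y_k / \sum x_k^2$.

The through-origin fit is a deliberate design choice. After reflection
every point satisfies $0 \le y \le x$, so this slope is bounded in
$[0, 1]$ and equals 1 exactly when the profiles are identical. A
free-intercept fit would assign slope magnitude 1 to perfectly
anti-correlated profiles, which contradicts the intended reading that a
larger slope means stronger colocalization; with the through-origin fit
the anti-correlated case scores 0. Ties ($a_k = b_k$) are left where
they are, profiles are compared by sample index with no registration,
and all-zero profile pairs are rejected as undefined rather than scored.

## Abundance screen

For each protein, the abundance index divides its peptide count by the
total counts in the sample and by the protein's molecular weight:
$\mathrm{AI} = c / (T \cdot \mathrm{MW})$. "Total protein content" is
read as total peptide counts — the only quantity available in a count
table; because some users may prefer a mass-weighted total, the
alternative $T = \sum_i c_i \mathrm{MW}_i$ is exposed as
`total_mode = "mass"`. The screen ranks proteins by the bait/mock ratio
of abundance indices, with a pseudocount (default 1) added to both raw
counts so mock-absent proteins get finite ratios; sample totals are left
at their raw values so that, at pseudocount 0, the ratio is exactly
invariant to rescaling either sample's depth. The candidate cutoff is a
user parameter (default 3): it is a screening convention, not a derived
constant.

## Statistical reporting

`summarize_group()` returns mean, SD and SEM; SD is the convention for
small numbers of independent measurements (colocalization slopes,
enrichment ratios across ROIs), SEM for very large per-track samples.
`compare_groups()` runs a one-way equal-variance ANOVA omnibus test
followed by all pairwise two-sided equal-variance Student's t-tests with
Bonferroni correction over the number of pairs (for two groups, a single
t-test with no correction). Significance is flagged at strict
$p < \alpha$ on the adjusted p-value, $\alpha = 0.01$ by default.
Two-sided equal-variance t-tests are the conservative default when
neither tail nor variance structure is specified. The suite verifies the
omnibus test empirically: over 10,000 null simulations (3 groups of 10),
the rejection rate at $\alpha = 0.01$ falls within $0.01 \pm 0.004$.

## What the synthetic data emulates — and what it does not

The generator reproduces the statistical structure the analysis relies
on, at the acquisition scale of the emulated experiment (10 fps, 0.166
µm pixels):

* **Trajectories.** Free diffusion has i.i.d. Gaussian increments of
  variance $2D\Delta t$ per axis. Confined motion uses the same steps
  inside a reflecting circular boundary — the simplest mechanism that
  strictly bounds $r_\mathrm{conf}$; the real mechanism (picket-fence
  obstacles, binding) is not modelled. Immobile molecules are fixed
  points. All modes add i.i.d. Gaussian localization noise, default
  $\sigma = 0.02$ µm — a free parameter typical of PALM and small
  against the pixel; it is not a measured instrument value. Track
  durations are drawn uniformly on [`frames_min`, `frames_max`]
  (default 5–20) so the duration filter has both survivors and
  casualties.
* **Masks.** Elliptical adhesion footprints rasterized by pixel-centre
  membership on the half-open grid.
* **Images.** Fill versus ring renders of the same ellipse geometry with
  Gaussian intensity noise, emulating a receptor that fills adhesions
  against one that rings them. No point-spread function, blinking or
  photobleaching is simulated; trajectories and images bypass the
  detection step entirely.
* **Peptide tables.** Mock counts are Poisson with mean
  $\text{depth} \cdot w_i$; bait counts use mean
  $\text{depth} \cdot w_i f_i$, so the expected bait/mock *count* ratio
  equals the programmed fold $f_i$ exactly. The abundance-*index* ratio
  additionally carries the factor $T_\text{mock}/T_\text{bait}$; in a
  realistic table (here 100 background proteins with a handful
  enriched) that factor is within a few percent of 1, which is why the
  recovery checks use a 100-protein background rather than a toy table
  of two proteins.

Passing tests on these inputs validates the estimators and bookkeeping,
not detection, tracking, or segmentation — those upstream steps are
consumed as files, and their artefacts (linking errors, mask
thresholding choices) are outside this package's scope.

All generators are pure functions of their specification and an integer
seed, restore the caller's RNG state, and return bit-identical output
for identical seeds.

## Numerical choices and degenerate inputs

* MSD requires $N \ge 2$; the $D$ fit requires 4 lags, guaranteed for
  duration-filtered tracks ($N \ge 5$).
* The minimum enclosing circle handles duplicated and collinear points;
  containment tests use a $10^{-12}$ relative tolerance.
* Classification recovery depends on track duration as well as on the
  population parameters: a confined molecule ($R = 0.3$ µm,
  $D = 0.05$ µm²/s) observed for only 5–8 frames has typically not yet
  explored its disc, so $r_\mathrm{conf}$ falls below the one-pixel
  threshold and the track is — correctly, given the information
  available — labelled immobile. Recovery checks therefore use
  full-length 20-frame (2 s) tracks, where the three programmed
  populations (immobile with 0.02 µm noise; confined $R = 0.3$,
  $D = 0.05$; free $D = 1.0$) are recovered at ≥ 90% (≈ 98% observed).
* Intensities are quantized to integers in 0–255 at every image-valued
  boundary (render, smooth, profile extraction); index computations then
  run in double precision.
* Degenerate requests error explicitly: zero-length profile lines,
  all-zero profiles, ROIs without both mask and non-mask pixels,
  enrichment with no outside tracks, empty value vectors, all-constant
  groups.

## Problem sizes used in the validation suite

The suite and the reproduction script were sized to be decisive yet
quick: 1000 random tracks for the oracle-equivalence checks, 500 tracks
for $D$ recovery, 450 for classification recovery, 2000-track fields
for enrichment (uniform null and programmed 3× contrast), 25 seed×line
replicates for the fill/ring colocalization ordering, 10,000 null
simulations for the type-I error calibration, and a depth of $10^5$
counts for the 4× abundance recovery. These sizes give Monte-Carlo
standard errors several times smaller than each check's tolerance.

## Known limitations

* No drift correction, state-switching (HMM) mobility models, or
  anomalous-diffusion exponents — the analysis assumes the three-class
  model throughout.
* Masks are inputs; the package does not segment adhesions from raw
  vinculin images.
* The colocalization metric is the bespoke reflection-slope index only;
  Pearson/Manders-style coefficients are intentionally out of scope.
* ROI placement is user input; the package checks the 25% rule but does
  not propose regions.
* The screen operates on protein-level counts; spectrum-level
  processing, FDR estimation and protein inference belong to the
  upstream search engine.
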