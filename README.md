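# sptmobility

Analytics for single-particle-tracking PALM (sptPALM) studies of membrane
receptor organization at focal adhesions. The package takes per-molecule
trajectory tables (as exported by an external localization/tracking step),
binary adhesion masks and two-channel TIRF images, and answers three
questions a cell biologist asks of such data:

1. **How mobile is each molecule?** Per-track mean-squared displacement,
   diffusion coefficient, confinement radius, and a three-way mobility
   class (immobile / confined / free).
2. **Does the receptor concentrate at adhesions, and does its mobility
   change there?** Track-density enrichment ratios and mobility fractions
   inside versus outside an adhesion mask.
3. **Does one receptor colocalize with an adhesion marker?** A bounded
   profile-based colocalization index, plus a spectral-count abundance
   screen for candidate interactors from affinity-purification mass
   spectrometry.

A seeded synthetic-data generator (trajectories, masks, two-channel
images, peptide-count tables) provides ground truth for every stage, so
the whole pipeline is testable without microscope data.

## The estimators

For a track of $N$ positions $(x_i, y_i)$ (µm) at frame interval
$\Delta t$ (10 fps by default), with $5 \le N \le 20$ frames retained:

$$\mathrm{MSD}(n\Delta t) = \frac{1}{N-n}\sum_{i=1}^{N-n}
  (x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2, \qquad
  D = \tfrac{1}{4}\,\mathrm{slope}\big[\mathrm{MSD}(\tau_1..\tau_4)\big]$$

$r_\mathrm{conf}$ is the radius of the exact minimum enclosing circle of
the track (Welzl's algorithm). A track is **immobile** if
$r_\mathrm{conf} < 0.166$ µm (one pixel), else **confined** if
$D < 0.2$ µm²/s, else **free**.

The enrichment ratio inside an adhesion-rich region of interest (mask
coverage > 25%) is the track density (tracks/µm²) over mask pixels
divided by the density over non-mask pixels. The colocalization index
folds paired 8-bit profile intensities across the identity line and
reports the through-origin regression slope $\sum x y / \sum x^2 \in
[0,1]$ (1 = identical profiles). The abundance index is
$c/(T\cdot\mathrm{MW})$ — peptide count over sample total counts and
molecular weight — and candidate interactors are ranked by the bait/mock
index ratio.

## Worked example

Simulate a field with an immobile population seeded inside elliptical
adhesions and confined + free populations outside, then fit:

```r
library(sptmobility)

spec <- mask_spec(c(40, 40), list(
  list(center = c(12, 12), semi_axes = c(10, 7), angle = 0.3),
  list(center = c(28, 28), semi_axes = c(10, 7), angle = -0.5)))
field <- simulate_field(spec, list(
  population_spec("immobile", count = 120, placement = "inside_mask"),
  population_spec("confined", D = 0.05, confinement_radius = 0.3,
                  count = 40, placement = "outside_mask"),
  population_spec("free", D = 1.0, count = 120,
                  placement = "outside_mask")), seed = 11)

fit <- spt_fit(field$tracks, mask = field$mask)
summary(fit)
#> Tracks: 280 retained of 280 input
#>
#> By mobility class (D in um^2/s):
#>  mobility   n fraction   mean_D    sem_D
#>  immobile 130   0.4643 0.001106 0.000576
#>  confined  45   0.1607 0.048661 0.008855
#>      free 105   0.3750 1.174617 0.092933
#>
#> By adhesion region:
#>   region   n f_immobile f_confined f_free     mean_D     sem_D
#>   inside 120     1.0000     0.0000 0.0000 -2.537e-05 5.064e-05
#>  outside  52     0.1731     0.5577 0.2692  2.525e-01 5.912e-02
```

The per-class means recover the programmed diffusion coefficients
(0 / 0.05 / 1.0 µm²/s), and the region breakdown shows the programmed
contrast: everything inside adhesions is immobile, the outside mixture is
mobile. (Free tracks that wander across the mask boundary or out of the
field are discarded from region statistics; a near-zero mean D can come
out marginally negative because the four-lag slope is noise-limited for
static tracks.)

```r
enrichment_ratio(fit$tracks, as.character(fit$table$region),
                 field$mask, roi(0, 0, 40, 40))
#> enrichment ratio 6.122 (inside 9.942 tracks/um^2 [n=120],
#>                         outside 1.624 tracks/um^2 [n=52])
```

Two-channel colocalization on rendered images — channel B either fills
the same ellipses as channel A or only rings them:

```r
lines <- data.frame(x0 = c(2, 18), y0 = c(12, 28),
                    x1 = c(22, 38), y1 = c(12, 28), n_samples = 50L)
ring <- render_two_channel_image(spec, render_spec("fill", noise_sigma = 5),
                                 render_spec("ring", noise_sigma = 5),
                                 seed = 11)
colocalization_profile_set(ring$A, ring$B, lines)$slope
#> [1] 0.2132288 0.2366016
fillb <- render_two_channel_image(spec, render_spec("fill", noise_sigma = 5),
                                  render_spec("fill", noise_sigma = 5),
                                  seed = 12)
colocalization_profile_set(fillb$A, fillb$B, lines)$slope
#> [1] 0.9840398 0.9841478
```

A receptor ringing the adhesions scores ~0.2; one filling them scores
~0.98 — the index separates the two geometries cleanly.

A command-line front end over the same functions ships at
`inst/cli/sptmobility.R` (subcommands `simulate`, `tracks`, `coloc`,
`screen`, `run`), and `run_pipeline()` drives everything from one YAML
config.

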