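# fluorowell

Simulation and end-to-end quantification of **single-cell microwell
fluorospot assays**.

Self-seeding microwell chips trap thousands of individual cells — one per
well, each well with a pore in its bottom — and capture the protein each
cell secretes on an antibody-coated membrane pressed against the chip.
Replacing the membrane every 24 h while stimulating (R1881) and then
inhibiting (enzalutamide / abiraterone) secretion yields, per cell, a
three-point secretion time series plus live/dead viability: the raw material
for classifying drug-sensitive, low-producing and drug-resistant cancer
cells. The published chips' raw images are not public, so this package pairs
the analysis pipeline with a forward simulator whose presets encode the
published cohort numbers — every algorithm is scored on whether it recovers
known ground truth from rendered images.

It is aimed at people building or validating image-analysis pipelines for
microwell/fluorospot secretion assays, and at anyone who needs a
ground-truthed synthetic benchmark for per-well spot quantification.

## What it computes

For a chip of `n` wells at pitch `p`, with membrane spot intensities `I` and
a calibration series of known areal densities `rho` (pg/um^2):

* **Calibration**: least-squares fit of the saturating response
  `I(rho) = I_bg + I_max * rho / (rho_half + rho)`, inverted in closed form;
  spot mass is `rho_hat x ROI area`, and the per-cell rate is
  `mass / n_cells / (duration / 24 h)` in pg/cell/day.
* **Detection**: per-well cell counts from Gaussian-blob detection with a
  local annulus threshold (mean + 4 SD) and an area-based touching-cell
  split; viability from the calcein / ethidium-homodimer channel pair.
* **Registration**: the rigid transform (dx, dy, theta) mapping each
  membrane into the chip frame, found by inlier-count grid search over spot
  centroids and polished by a closed-form rigid fit.
* **Dynamics**: per-well rate series over t0/t1/t2, classified as
  sensitive / insensitive-low / resistant / nonviable by stimulation fold
  (>= 1.5) and inhibition drop (>= 30%).
* **Statistics**: exact tie-corrected Wilcoxon signed-rank (n <= 25; normal
  approximation beyond), Welch's t for viability, boxplot-convention
  summaries, and the assay's significance stars.

## Worked example

Simulate a 20 x 20-well chip with the LNCaP basal preset and recover the
secretion rates end to end (the mini chip needs the empty-well floor and
spot minimum lowered from their full-chip defaults):

```r
library(fluorowell)

geom <- chip_geometry(n_rows = 20, n_cols = 20, active_area_mm = c(2, 2),
                      tile_grid = c(2, 2))
run <- run_pipeline(tempfile("fw"), geometry = geom,
                    population = "lncap-basal", phases = "t0", seed = 42,
                    min_bg_wells = 5, min_spots = 20)

table(run$loading$n_cells_detected)
#>   0   1   2   3
#>   7 369  12  12

run$alignments$t0
#> <fw_transform> dx 14.47 um, dy -18.85 um, theta 0.232 deg
#>   (residual 0.21 um, 96 inliers)

run$calibration
#> <fw_calibration> I(rho) = 500.8 + 40002.1 rho/(0.02001 + rho),
#>   valid rho in [0, 0.075] pg/um^2

q <- run$quantified$t0
mean(q$rate_pg_per_cell_day[q$above_background & q$n_cells == 1])
#> [1] 6.074931   # preset truth: 6.1 pg/cell/day
```

Reading the output: 369/400 wells hold a single detected cell (the preset
seeds ~91%); the membrane was mounted ~15 um off and 0.23 degrees rotated,
and registration recovered that to sub-pixel accuracy from the spots alone;
the fitted calibration matches the forward model it was rendered with; and
the mean recovered basal rate over above-background single-cell wells lands
within 0.5% of the simulated 6.1 pg/cell/day.

`plot_occupancy()`, `plot_secretion()`, `plot_timeseries()` and
`autoplot()` on the calibration object give the standard figures;
`tidy()`/`glance()` return broom-style tables for fitted objects. A thin
command-line wrapper over the same functions lives at
`inst/scripts/fluorowell.R` (subcommands `simulate`, `stitch`, `detect`,
`register`, `quantify`, `dynamics`, `report`, `run`).

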