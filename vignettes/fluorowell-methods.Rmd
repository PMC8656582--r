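---
title: "Methods: simulating and quantifying single-cell microwell fluorospot assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying single-cell microwell fluorospot assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorowell)
```

## The assay being modelled

Self-seeding microwell chips hold thousands of single cells, one per well,
each well with a pore in its bottom. An antibody-coated PVDF membrane pressed
against the chip captures the protein each cell secretes (here: PSA from
prostate cancer cells) directly beneath its well. Swapping the membrane every
24 h yields a per-cell secretion *time series*: a baseline phase (t0), an
androgen-stimulated phase (t1, R1881), and an anti-androgen phase (t2,
enzalutamide or abiraterone). Fluorescence imaging of the chip (calcein for
live cells, ethidium homodimer for dead cells) and of each labelled membrane,
plus a calibration membrane spotted with known protein amounts, turn spot
intensities into absolute per-cell secretion rates in pg/cell/day.

`fluorowell` implements both sides of this experiment:

* a **forward simulator** that generates ground-truth cells (occupancy,
  secretion rates, drug-response phenotypes, viability) and renders every
  image the assay produces, and
* an **analysis pipeline** (cell detection → membrane registration →
  calibration inversion → time-series classification → cohort statistics)
  that must recover the simulated truth from the images alone.

Because the original chips' raw images are not public, recovery of known
simulation parameters is the package's accuracy currency: presets pin the
simulator to the published cohort numbers, and the pipeline is tested on
whether it reproduces them end to end.

## Chip geometry

The published chip holds 6400 wells on an 8 × 8 mm active area. The grid
layout is not public; we fix 80 × 80 wells at 100 µm pitch — the only
square factorisation consistent with a square active area and single-cell
well dimensions — and flag it as a reconstruction. Coordinates are
micrometres from the chip's top-left corner, well ids row-major and 0-based,
well (0,0) centred at (pitch/2, pitch/2). The default pixel size is
2.5 µm/px, rendering a full chip at 3200 × 3200 px in a 10 × 10 tile mosaic;
the real instrument's 20× optics are irrelevant to the algorithms and would
only cost memory. Each well's membrane spot is measured over a disc ROI of
radius 35 µm, chosen to capture diffusion-broadened spots while keeping
neighbouring ROIs disjoint at 100 µm pitch.

## Population model and presets

Each well receives 0–3 cells i.i.d. from the occupancy distribution; the
default is the published loading histogram (92% one cell, 4% two, 3% three,
2% empty — printed values sum to 101% and are renormalised). Per cell:

* **Secretor status**: Bernoulli with the preset's baseline secreting
  fraction. Non-secretors get a residual 0.001 pg/day — effectively nothing,
  below any detection limit.
* **Basal rate**: lognormal with arithmetic mean and CV set by the preset
  (LNCaP 6.1 pg/cell/day, CV 4.5/6.1; VCaP 3.7, CV 1.9/3.7). The lognormal
  family is our choice: the reported distributions are long-tailed and
  positive — many low producers plus a heavy tail of highly active cells —
  but no distribution family is named.
* **Phenotype**: sensitive / insensitive-low / resistant with fractions
  0.91 / 0.085 / 0.005, inside the published ranges (93–89%, 6–11%, <1%).
  Stimulation multiplies the t1 rate of sensitive *and* resistant secretors
  by 2.0, so the population mean per-cell increase is ~90% while ~10% of
  cells are unaltered — the published mixture arithmetic. Inhibition
  multiplies the t2 rate of sensitive cells by 0.15 (a sharp drop; no number
  is printed).
* **Viability**: marginal viable fractions at each phase end
  (0.88, 0.78, then 0.24/0.39 for the LNCaP enzalutamide/abiraterone arms);
  survival is a per-cell Bernoulli chain with conditional probability
  `v[p]/v[p-1]`, and dead cells secrete zero from their phase of death.

Two deliberately different LNCaP baselines exist because the publication
reports both without reconciling them: the *basal* preset (secreting fraction
0.95, matching the reported more-than-90% of single cells secreting above
background) and the *time-course* preset (secreting fraction 0.53, the
reported baseline secreting fraction after 24 h). The *paired* preset
reproduces the one- vs two-cell comparison (4.8 vs 7.5 pg/cell/day): since
the single-mean population model cannot express occupancy-dependent rates,
it carries an optional `rate_mean_by_count` override.

Within a phase, secretion is constant-rate: captured mass = rate ×
duration/24 h. Intra-phase kinetics are not modelled.

## Rendering model

Cells are isotropic Gaussian blobs (σ = 6 µm, peak 800 counts above
background) at fixed jittered positions (|offset| < pitch/4). Cells sharing
a well are placed on a ring (radius 20–22 µm, random rotation, 1 µm jitter):
at this PSF genuinely touching cells are unresolvable, so the simulator
keeps multi-cell wells *solvable* while the detector's area-split rule covers
the occasionally merged components. This is the main idealisation of the
renderer — real two-cell wells can be harder than simulated ones, so
occupancy-accuracy results here bound the algorithm, not the instrument.

Membrane spots are Gaussians (σ = 20 µm) at the well's pore position mapped
through the membrane's mounting transform (a rigid shift of up to ±30 µm and
rotation up to ±0.3° drawn per membrane, or injected explicitly). The spot is
scaled so that the mean intensity over the measurement ROI equals the forward
calibration response at areal density mass/ROI-area. That makes rendering and
calibration inversion exact inverses up to noise and 16-bit quantisation —
the property the round-trip tests assert at 1–2% — and conserves the
rate→mass→rate chain without modelling diffusion physics.

The forward response is a saturating hyperbola above camera background,
ΔI(ρ) = I~max~·ρ/(ρ~half~+ρ) with defaults I~max~ = 40000 counts,
ρ~half~ = 0.02 pg/µm². Noise is Poisson shot noise on expected counts plus
Gaussian read noise (SD 30) on a constant background (500), rounded and
clipped to 16 bits. All defaults were chosen once so that detection is
non-trivial but solvable at desk scale, and every one is a config argument.

The calibration membrane renders one uniform disc per standard density; the
default series is the published dilution arithmetic — 1 µL drops of
0–300 µg/mL over ~4 × 10⁶ µm², i.e. 0 to 0.075 pg/µm².

## Analysis pipeline

**Cell detection.** Gaussian smoothing (σ = 3 µm), per-well threshold at
annulus-background mean + 4 SD, connected components inside the well ROI,
minimum area 25% of the nominal cell footprint (800 µm²), and components
above 1.8× nominal counted as ⌈area/nominal⌉ touching cells. The SD estimate
is floored at 2.2% of the annulus mean: this guards against a degenerate
threshold on noise-free input while keeping counts exactly invariant under
global intensity scaling (both properties are tested). How the original
study discriminated two-cell wells from large single cells is not described;
the area rule is our stand-in.

**Registration.** Membranes are mounted by hand, so each is displaced by an
unknown small rigid transform. Spot centroids are detected with a robust
lower-quantile background threshold (dense chips leave fewer than half the
pixels as background near spots, so the 25th/45th percentiles estimate the
background level and SD uncontaminated). A coarse-then-fine grid search over
(dx, dy, θ) maximises the number of centroids landing within pitch/4 of a
well centre — inlier counting rather than least squares, so missing spots
(non-secretors) and merged spots cannot drag the optimum — and a closed-form
rigid fit on the inlier matches polishes the answer. Every well then gets a
measurement ROI at its transformed pore position, spot or not, because
background estimation and below-background calls need empty and silent wells.

**Quantification.** The calibration curve is fitted by Levenberg–Marquardt;
the hyperbola admits an exact closed-form inverse, used to map each ROI mean
intensity to areal density and mass. Empty-well background statistics (≥50
wells with no detected cell, the assay's rule) set the detection limit:
above background means ROI mean > background mean + 3 SD, the conventional
limit-of-detection choice. Intensities at or below the fitted background
floor to mass 0 (rates are physical quantities, never negative); intensities
at the curve ceiling are censored at the top of the valid range. The fixed
ROI stands in for a per-spot segmented area: segmentation is unstable
for faint spots, and fixed-ROI readout is exactly mass-consistent under the
Gaussian spot model.

One selection rule matters when comparing per-cell rates across occupancy
groups: a cell that died before the capture window secretes nothing but, if
it is still counted in the well, deflates the well's per-cell rate. Rate
comparisons between one- and two-cell wells therefore restrict to wells
whose full detected complement is alive (loading count equals the live count
at t0) — the natural reading of a comparison between wells *containing* one
versus two cells.

**Dynamics and classification.** Per-well series over the three phases are
classified: nonviable (dead by t2); insensitive/low (below background at t0
and t1, or stimulation fold < 1.5); sensitive (fold ≥ 1.5 and ≥30% drop
after inhibition); resistant (fold ≥ 1.5, drop < 30%); otherwise
unclassified. The original grouping of secretion patterns is qualitative, so
the 1.5×/30% cut-offs are our formalisation: they sit between the preset
effect sizes (2.0×, 85% drop) and null (1.0×, 0%) and are exposed as
configuration. The cohort stimulation statistic is the mean of per-well
percent changes t0→t1 over wells viable at both phases and above background
at t0; the alternative reading — a fold change of means — is deliberately
not what we compute, and we state our choice because either is defensible.

**Statistics.** Paired comparisons use the Wilcoxon signed-rank test with
zero differences discarded and midranks for ties; for n ≤ 25 the null
distribution is computed exactly by a generating-function convolution over
the (doubled) midranks — identical to enumerating all 2ⁿ sign assignments —
and beyond that by the tie-corrected, continuity-corrected normal
approximation. Viability comparisons use Welch's t — whether the original
analysis pooled variances is unknown, and unequal variances are the safer
assumption. Quartiles are linear
interpolation between order statistics (type 7). Stars follow the assay's
convention: * p < 0.05, ** p < 0.001, *** p < 0.0001.

## Numerical and degenerate-input choices

* All randomness flows from one master seed through named substreams
  (`substream_seed`), so any stage re-runs reproducibly on its own and
  identical configuration + seed gives byte-identical TIFF/CSV output.
* Tiles abut exactly; no stage-overlap stitching. TIFFs are uncompressed
  16-bit grayscale and round-trip losslessly.
* A calibration fit is refused with fewer than 4 distinct standards
  (including 0), non-monotone standard means beyond noise, or non-positive
  fitted parameters.
* Fewer than 50 detectable membrane spots is an explicit
  insufficient-signal error; a registration RMS residual above pitch/4 is
  flagged low-confidence rather than silently accepted.
* Fewer than 50 empty wells is an explicit error; the floor can be lowered
  deliberately (logged) for small chips.
* `summary_stats` of a single value reports SD 0 with `sd_defined = FALSE`;
  all-zero paired differences and zero-variance t-tests are errors, not
  numbers.

## Problem sizes

Full chips (6400 wells, 3200² px) simulate in ~30 s and analyze in ~45 s per
phase on one CPU; the acceptance script runs all of its recoveries at this
full scale. The test suite exercises the same pipelines on 40 × 40 to
60 × 60-well chips, where every cohort quantity it asserts has sampling error
comfortably below the tolerance being checked; unit tests use 4–20-well-wide
chips.

## What passing does and does not show

The simulator reproduces the *statistical* structure of the assay: occupancy,
lognormal heterogeneity, phenotype mixtures, survival chains, spot placement,
mounting offsets, shot/read noise, saturation. It does not model diffusion
through the pore, membrane texture, optical PSF detail, cell morphology,
proliferation (cell counts are static after seeding), within-phase secretion
kinetics, or cells drifting between phases. Recovery results therefore
validate the analysis algorithms against a faithful-but-idealised forward
model — they do not certify performance on any particular instrument's
images.
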