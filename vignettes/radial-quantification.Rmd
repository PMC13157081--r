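---
title: "Radial quantification of aggregate infiltration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial quantification of aggregate infiltration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialorg)
```

## The measurement model

The assay quantifies where, along the surface-to-center axis, a
fluorescently labelled aggregate species sits inside a 2D organoid
cryosection. The analysis rests on three assumptions:

* a single middle cryosection is representative of the organoid, so the
  analysis is strictly 2D (z-stacks are rejected rather than projected);
* the cell-marker channel delineates the tissue: everything inside its
  thresholded outline is organoid, everything outside is background;
* fluorescence intensity is proportional to the amount of labelled
  protein, so the intensity sum over a set of pixels (the ImageJ-style
  "integrated density", IntDen) is a mass proxy.

Depth is the exact Euclidean distance from a tissue pixel to the nearest
background pixel, computed on the segmented mask. The maximum depth $R$
is the organoid's surface-to-center distance ("radius" — for an
elliptical or lobed section this is the depth of the most interior
point, not half of any particular diameter). Two complementary readouts
are derived:

* **Shell profile.** Tissue is partitioned into concentric bands of
  fixed width $w$ (default 25 px), and each band's IntDen is expressed
  as a percentage of the whole-organoid IntDen. Per-organoid
  normalization removes differences in total uptake; percentages sum to
  100 by construction, which the tests verify to $10^{-6}$.
* **Region summary.** Each pixel is assigned by its *relative* depth
  $f = d/R$ to one of five regions, R1 $= f \in [0, 0.2)$ through
  R5 $= f \in [0.8, 1]$. Because $f$ is relative to the organoid's own
  radius, regions are size-invariant and comparable across organoids.

The two coordinate systems are deliberately decoupled: region
membership always uses the organoid's own radius, while the plotting
coordinate of a shell (its `relative_position`) divides the shell
mid-depth by the radius of the *largest* organoid in the comparison
group (`rescale_to_largest()`), so that profiles of differently sized
organoids share one axis without distorting their regional statistics.

## Numerical conventions

* **Binning.** Shell index is $\min(\lfloor d/w \rfloor + 1, K)$ with
  $K = \lceil R/w \rceil$; bands are half-open $[(i-1)w, iw)$ with the
  innermost band truncated and closed at $R$. Since the distance
  transform assigns depth $\ge 1$ to every mask pixel, the band
  $(0, w)$ is shell 1 and every mask pixel carries exactly one label.
  Region bands are likewise half-open with $f = 1$ (the deepest pixel)
  assigned to R5. All assignments are verified in the tests against an
  independent per-pixel interval binning and, for the depth map itself,
  against an exhaustive nearest-background search on small random
  shapes.
* **Segmentation.** The marker channel is rescaled to unit range before
  Gaussian smoothing ($\sigma$ = 2 px) and Otsu thresholding, which
  makes the mask exactly invariant under affine intensity changes
  (offset and gain) — a useful property when acquisitions differ only
  in camera offset. Closing (disk radius 3 px), largest 8-connected
  component, and hole filling follow. The original macro's threshold
  settings are not recoverable, so these deterministic defaults are
  exposed as parameters (`smoothing_sigma_px`, `closing_radius_px`,
  `min_area_px`).
* **IntDen.** Plain double-precision sums, no background subtraction by
  default (matching how such macros typically operate); an optional
  constant-offset subtraction is available via `background_offset`.
* **Zero signal.** An organoid whose aggregate channel sums to zero
  inside the mask has no defined percentage profile; it is excluded
  with a "no signal" error rather than recorded as zeros.
* **The 25-pixel shell width** is read as a depth-band thickness in
  geometric pixels (the natural reading of a distance-map band) and is
  a parameter everywhere it appears.

## Statistics

Region percentages from $n$ organoids per timepoint enter a balanced
two-way ANOVA (region × timepoint with interaction). Per-region
comparisons between the two timepoints use the pooled residual mean
square of the full model with its residual degrees of freedom — the
behaviour of GraphPad's "multiple comparisons between time points
within each row" — with Šidák adjustment over the five regions,
$p_{adj} = 1 - (1-p)^5$. Stars follow the ladder `*` < 0.05,
`**` < 0.01, `***` < 0.005, `****` < 0.0001. Normality pre-screening
uses Shapiro-Wilk ($n \ge 3$) and the D'Agostino-Pearson omnibus
($K^2$, $n \ge 8$; reported as unavailable below that); the omnibus is
implemented from the standard skewness/kurtosis transforms and verified
against an independent reference implementation in the tests.

Two deliberate approximations:

* Comparisons of scalar readouts against a control group
  (`one_way_vs_control()`) use Šidák-adjusted pooled-variance $t$
  tests in place of exact Dunnett quantiles; this is slightly
  conservative and is documented on the function.
* Region percentages are compositional (they sum to 100 within an
  organoid) but are analyzed untransformed, as is conventional for this
  assay; `region_time_anova(..., logit = TRUE)` offers a logit
  transform for sensitivity analyses.

**Calibration.** The test suite simulates null datasets (both
timepoints drawn from the same Dirichlet composition, $n = 6$ per cell
as in the assay's design, 2000 replicates) and checks that the
family-wise fraction of replicates with any starred region stays near
the nominal 5%. The calibration null uses the *exchangeable*
composition (all regions 20%, concentration 300, giving organoid-level
region SDs of ~2 percentage points) so that every region has the same
sampling variance: this isolates the error-rate property of the
Šidák/pooled-MS procedure itself. A caveat worth knowing: under a
realistic uneven composition (e.g. the uniform-disk profile
36/28/20/12/4) region variances differ several-fold, and per-region
tests built on the pooled residual MS become anti-conservative for the
high-variance regions and conservative for the low-variance ones. This
is a property of the pooled-error design the assay prescribes, not of
this implementation; the logit option mitigates it.

## TUNEL counting

Nuclei are segmented from the DAPI channel (smoothing, Otsu, watershed
on the distance transform to split touching nuclei, minimum-area
filter). A nucleus is TUNEL-positive when its *mean* TUNEL intensity —
robust to single hot pixels, unlike the maximum — exceeds a threshold.
By default the threshold is Otsu's split of the per-nucleus mean
distribution, guarded by a 2× fold-change requirement between the two
classes: a field containing no genuine positives then yields zero calls
instead of splitting its noise. Passing an absolute `threshold`
disables the guard and makes every call independent of all other
nuclei. The watershed neighbourhood is sized at a quarter of
`min_separation_px`; with the default (8 px) the tests confirm that two
nuclei overlapping by 30% of their radius are split while
well-separated nuclei are neither split nor merged.

## The synthetic generator

`generate_section()` emulates the features of the real data that the
pipeline actually consumes:

* roughly circular sections — an ellipse (axis ratio `ellipticity`)
  with optional low-order Fourier boundary perturbation (modes 3–8,
  total relative amplitude `boundary_roughness`), which keeps the
  outline simply connected;
* a textured cell-marker channel filling the tissue (band-limited
  noise, correlation length `marker_texture_scale` = 15 px);
* an aggregate channel following one of five radial models: `uniform`,
  `crust(δ)` (all signal within δ of the surface), `exponential(λ)`
  (intensity $\propto e^{-d/\lambda}$), `channels` (straight radial
  corridors with Gaussian cross-section, mimicking the corridor-like
  infiltration route), and `punctate` (Gaussian clumps at random
  angles and depths, mimicking clustered deposits);
* noise per the standard fluorescence approximation — Poisson shot
  noise on the expected count plus Gaussian read noise — with defaults
  amplitude 1000 counts, background 2 counts, read noise SD 2. The low
  background reflects a background-subtracted acquisition in which the
  aggregate channel is nearly dark outside labelled deposits; it also
  keeps the unsubtracted background from contaminating profile
  percentages by more than a fraction of a point at the default
  amplitude.

Each generated section carries its ground truth: the noiseless signal
raster, the true mask, and expected shell/region percentages obtained
by per-pixel binning of the noiseless field (code kept separate from
the measurement path). For perfect disks with uniform, crust or
exponential models, `expected_profile()` additionally provides closed
forms from the annulus integral
$\int_a^b (R-d)\, f(d)\, \mathrm{d}d$, which the tests cross-check
against supersampled numeric integration. The closed forms also power
the monotonicity check (expected R1 occupancy strictly decreases as λ
grows) and the λ estimator's disk approximation.

`fit_penetration()` estimates λ by least squares between measured and
model-predicted shell percentages. When the organoid's depth map is
supplied, the prediction uses the actual per-pixel depth distribution
with the same binning rule as the measurement, which removes the
discretization bias of the idealized disk (the distance transform
assigns boundary pixels depth 1, so continuous-disk integrals are
offset by about half a pixel — negligible for large λ, visible for
λ ≈ 10 px).

What the generator does **not** emulate: 3D structure, ventricles and
rosettes, uneven illumination, optical blur, or any transport dynamics
(time course experiments are represented purely by different profile
parameters). Passing tests therefore demonstrate correctness of the
measurement chain on images with known truth, not robustness to every
artifact of real microscopy.

## Problem sizes used in validation

The shipped tests exercise radius-300 px organoids in 640×640 fields
for the analytic-disk, crust and λ-recovery checks (λ ∈ {10, 20, 40,
80}, ten noisy replicates each, recovery within 10%); fifty random
specs across all five models at radii 60–100 px for conservation; 2000
simulated null datasets for ANOVA calibration; and TUNEL fixtures with
20 and 100 nuclei at positive fractions 0, 0.25 and 0.5 (exact count
recovery at amplitude ratios ≥ 4, nucleus recall/precision ≥ 0.95).
`scripts/acceptance.R` re-runs the same battery from scratch with
user-supplied seeds.

## Known limitations

* Strictly 2D and single-section; no accommodation for sections
  touching the image border (depth would be measured to the cut edge).
* No manual mask curation path beyond supplying an external mask to
  `compute_depth_map()`.
* The Dunnett approximation and the pooled-variance caveat above.
* `write_section()` writes integer TIFFs only (8/16-bit); 32-bit float
  TIFFs are read but not written.
* The channel and punctate models are qualitative emulations; no claim
  is made that their parameters correspond to biophysical transport
  quantities.
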