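# radialorg

Radial shell quantification of fibrillar protein infiltration in organoid
sections.

## The problem

Cerebral organoids exposed to fluorescently labelled fibrils of
aggregation-prone proteins (α-synuclein, amyloid-β, tau) internalize the
aggregates and let them spread inward over weeks. Asking *how deep* the
label has penetrated requires a quantification that is robust to
organoids of different sizes and different total uptake. `radialorg`
implements the standard depth-map approach for 2D cryosections:

1. **Tissue mask** — the cell-marker channel (e.g. vimentin) is smoothed,
   Otsu-thresholded, morphologically closed, reduced to its largest
   8-connected component, and hole-filled (`segment_organoid()`).
2. **Depth map** — for every tissue pixel the exact Euclidean distance
   `d(p)` to the nearest background pixel (`compute_depth_map()`); the
   maximum depth `R` is the organoid's surface-to-center "radius".
3. **Shell profile** — the tissue is partitioned into concentric depth
   shells of width `w` (25 px by default),
   `shell(p) = min(floor(d(p)/w) + 1, ceil(R/w))`, and the integrated
   density (IntDen, the plain intensity sum) of the aggregate channel is
   accumulated per shell and normalized to the organoid total:
   `percent_i = 100 · IntDen_i / IntDen_total` (`build_shells()`,
   `measure_profile()`). Per-organoid normalization makes organoids with
   different uptake comparable.
4. **Regions** — each pixel is binned by its *relative* depth
   `f = d(p)/R` into five regions, R1 = outermost 20% of the
   surface-to-center distance through R5 = innermost 20%
   (`summarize_regions()`). Region membership always uses the organoid's
   **own** radius; for plotting, profiles of a comparison group are
   re-referenced to the **largest** organoid of the group
   (`rescale_to_largest()`).
5. **Statistics** — D'Agostino-Pearson and Shapiro-Wilk pre-tests
   (`normality_tests()`), balanced region × timepoint two-way ANOVA with
   Šidák-corrected per-region comparisons between timepoints
   (`region_time_anova()`, `p_adj = 1 − (1 − p)^5`), and one-way ANOVA
   with comparisons against a control group (`one_way_vs_control()`).
6. **Apoptosis** — DAPI nuclei are segmented with a watershed split
   (`segment_nuclei()`) and TUNEL-positive nuclei counted against the
   total (`count_tunel()`).
7. **Synthetic data** — `synthetic_spec()` / `generate_section()`
   generate organoid sections with configurable radial signal models
   (uniform, surface crust, exponential penetration gradient, radial
   channels, punctate clusters) under Poisson + Gaussian noise, together
   with the exact expected noiseless profile, so the entire pipeline is
   testable without microscopy data. `fit_penetration()` estimates the
   exponential decay length λ from a measured profile.

## Worked example

```r
library(radialorg)

## a synthetic section: exponential penetration, decay length 40 px
spec <- synthetic_spec(radius_px = 150, field_px = c(360, 360),
                       model = model_exponential(40), seed = 42)
gen <- generate_section(spec, meta = experiment_meta("org01", "aSYN", "direct", 1))

## full pipeline: segmentation -> depth map -> shells -> regions
q <- quantify_section(gen$section, min_area_px = 5000)
q$regions
#> <region_summary> organoid 'org01' (radius 149.2 px)
#>    R1    R2    R3    R4    R5
#> 64.41 24.32  8.36  2.46  0.45

fit_penetration(q$profile, q$depth)
#> <penetration_fit> lambda = 40.39 px (per-pixel depth, radius 149.2 px, SSE 0.00028)
```

64% of the label sits in the outermost fifth of the tissue and the
fitted decay length recovers the generating value (40.4 vs 40 px).
Comparing two timepoints (six organoids each, a near-total-crust
composition at week 1 against a partly penetrated one at week 4):

```r
d <- simulate_region_dataset(6, mean_percents   = c(96, 2, 1, 0.7, 0.3),
                             mean_percents_2 = c(45, 25, 15, 10, 5), seed = 1)
region_time_anova(d)$comparisons[, c("region", "mean_t1", "mean_t2", "p_adj", "stars")]
#>  region mean_t1 mean_t2     p_adj stars
#>      R1 95.6199  45.860 0.000e+00  ****
#>      R2  2.2642  24.822 0.000e+00  ****
#>      R3  1.1467  15.323 0.000e+00  ****
#>      R4  0.7805   9.586 0.000e+00  ****
#>      R5  0.1888   4.408 1.945e-07  ****
```

TUNEL counting on a generated fixture with 25% apoptotic nuclei:

```r
fx <- generate_tunel_fixture(100, positive_fraction = 0.25, amplitude_ratio = 8, seed = 3)
count_tunel(segment_nuclei(fx$section$channels$nuclei), fx$section$channels$tunel)
#> <tunel_result> 25 / 100 nuclei TUNEL-positive (25.0%), threshold 54.5
```

A thin command-line front end over the same functions lives at
`inst/cli/radialorg.R` (subcommands `segment`, `profile`, `regions`,
`tunel`, `simulate`).

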