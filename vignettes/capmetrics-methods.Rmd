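---
title: "Methods: microcapsule characterization with capmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microcapsule characterization with capmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmetrics)
```

`capmetrics` characterizes spray-dried microcapsule powders: particle
sizing from SEM-style micrographs, the standard powder quality-control
equations, external-standard HPLC quantification, and Tukey-based
homogeneous grouping. This vignette explains the models and procedures,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The imaging model

An SEM micrograph of a spray-dried powder shows bright, roughly
spherical granules on a darker background, with an instrument databar
along the bottom edge and a scale bar of known physical length. The
sizing pipeline makes three assumptions:

1. particles are convex and approximately circular in projection, so the
   diameter of the *minimum enclosing circle* (MEC) of a particle's
   contour estimates its true diameter even when a minor arc is hidden
   behind a neighbor — the visible arc still pins down the circle;
2. particles intersecting the image boundary are truncated and would
   bias the distribution downward, so they are excluded outright;
3. the scale bar calibrates the whole frame
   (`um_per_px = scalebar_um / scalebar_px`, default 20/229
   ≈ 0.0873 µm/px).

The stages are `crop_databar()` (default 65 rows — the pipeline removes
the strip regardless of its content), `normalize_contrast()` (affine
min–max to 0–255; a constant image maps to zeros with a warning),
`segment_instances()`, `exclude_border_particles()` (an instance is a
border instance iff it owns at least one pixel in the outermost
rows/columns of the content region), `measure_particles()` and
`summarize_sizes()`.

### Segmentation backend

Instance segmentation is an injectable contract: any
`function(image_matrix, config) -> integer label matrix` can be used, so
a learned model can replace the default without touching the rest of the
pipeline. The default classical backend is

Otsu threshold → hole filling → Euclidean distance transform → seed
detection → seeded watershed.

Seeds are distance-map maxima; maxima closer than
`base_diameter_px / 2` (default 15 px for the 30 px expected particle
diameter) merge into one seed, which keeps a single particle from
splitting while still separating touching neighbors with distinct
distance peaks. We use seed-based region growing (`EBImage::propagate`)
rather than tolerance-based watershed because explicit seeds with a
minimum separation make the split criterion transparent and keep every
label a single connected region. Foreground components that receive no
seed (slivers near the resolution limit) keep their own label and are
then subject to the `min_area_px` filter (default 9 px), which removes
sub-resolution specks. Heavily fused agglomerates that produce a single
distance peak legitimately remain unsplit; no attempt is made to
resolve them.

### Geometry and conventions

The MEC is computed on the outer boundary pixels of each instance (the
result is identical to using all pixels, at far lower cost) with the
exact randomized-incremental algorithm; the shuffle is driven by an
internal fixed-seed generator so a given contour always yields the same
circle, bit for bit. Coordinates are 1-based `(row, col)` with pixel
centers at integer positions — the R convention. `diameter_px` is twice
the MEC radius over pixel centers; at the default calibration one pixel
is worth about 0.09 µm, or roughly 2 % of a 4 µm particle, which is the
resolution limit of any per-particle claim.

Size descriptors use the sample SD (n − 1), linear-interpolation
percentiles for D10/D50/D90 (the convention of R's default quantile
type), and a histogram with 0.5 µm bins anchored at 0.

## The synthetic-data generator

`simulate_micrograph()` renders shaded disks (linear radial falloff,
brighter center — a coarse mimic of secondary-electron contrast on
spheres) with diameters drawn from a log-normal distribution
parameterized by its median (default 3.7 µm) and log-SD (default 0.45),
the unimodal right-skewed shape with a long tail of larger granules that
spray-dried populations show. Placement is rejection sampling under a
pairwise overlap constraint (`max_overlap_fraction` of the smaller
disk's area; lens-area formula). When the constraint is *disjoint*
(`max_overlap_fraction = 0`), a `min_gap_px` margin (default 2 px) is
additionally enforced so that disjoint disks remain separable at pixel
resolution — two circles tangent in continuous coordinates can share
adjacent pixels and fuse into one connected component, which would make
"disjoint" ground truth unverifiable in the rendered image. Gaussian
intensity noise is added, and a uniform databar strip with a white scale
bar of exactly `scalebar_px` pixels is appended.

The truth table records each disk's center, diameter, and whether it
touches the border, where "touches" is defined through pixel coverage
(the disk owns a pixel center in the outermost rows/columns iff its
extent reaches within 1 px of them) so that truth flags and the
pipeline's border exclusion are commensurable.

What the generator does **not** emulate: electron-optics texture,
charging artifacts, depth-dependent focus, agglomerate morphology beyond
pairwise overlap, and databar text glyphs. Passing recovery tests on
synthetic images therefore demonstrates that the measurement chain is
unbiased for well-separated convex particles at known scale — not that
any particular segmentation backend handles real SEM texture; that is
exactly the part the backend contract leaves replaceable.

Recovery is validated on three seeded 2048 × 2048 micrographs with 380
particles each (≥ 300 interior): recovered mean and D50 agree with
ground truth to well within 5 % (observed ≤ 0.2 %), and the excluded
label set equals the truth's border set exactly. The 2048 px frame is
our choice: at the 20 µm/229 px calibration, several hundred disjoint
4 µm particles need that much area at realistic packing.

## Powder quality control

The calculators are direct implementations of the standard equations
(moisture, solubility with blank correction, encapsulation efficiency,
bulk and tapped density, Carr's Index, Hausner Ratio), with the
physically implied guard rails as errors: dried mass above initial mass,
surface oil above total oil, a tapping series whose last two readings
still differ by ≥ 1 % (the convergence rule), non-positive volumes. Two
exact identities are maintained and tested:
`HR = 1/(1 − CI/100)` and `EE + surface/total × 100 = 100`.

Reporting follows the bench convention: each analytical replicate is
passed through the formula and the per-replicate values are averaged
(`replicate_summary()`). For nonlinear quantities (EE, CI, HR) this
differs from evaluating the formula at mean inputs; the per-replicate
path is canonical here because published tables report means of
replicate determinations. Blank correction in the solubility assay is
applied to the aliquot residue *before* the dispersion/aliquot factor —
the physically coherent order, since the blank measures non-volatile
residue in the aliquot.

The formulation mass balance takes a recipe (oil, emulsifier, and
wall-material solutions with their solid fractions) and returns the dry
solids, the feed solids fraction, and `m_oil`, the oil mass fraction of
the dry matrix. For the study recipes (20 g oil, 0.4 g emulsifier, two
133 g solutions at 15 % solids) this gives 60.3 g dry solids, 21.05 %
feed solids and `m_oil ≈ 0.3317`, and the lipid-core concentration of a
lipophilic analyte follows as `c_core = c_powder / m_oil` — valid under
the assumption that the analyte partitions entirely into the oil phase.

## HPLC quantification

`fit_calibration()` is ordinary unweighted least squares (the published
line is a plain linear equation, so no 1/x weighting is applied), with
R² as the squared correlation and the response-factor RSD
(`RF = area/amount`, the standard convention) as a linearity
diagnostic. Detection limits derive from baseline noise through the
slope at the usual S/N thresholds, `LOD = 3σ/slope` and
`LOQ = 10σ/slope`, which fixes `LOQ/LOD = 10/3` before rounding.
Inversion floors negative amounts at zero and assigns exactly one
censoring flag per injection (`below_lod`, `between_lod_loq`,
`quantified`, or `extrapolated` above the calibrated range).

The injection volume is not part of the chromatogram and must be
supplied (`sample_prep()`, default 10 µL); powder concentrations scale
inversely with it, so it is a required, recorded configuration value
rather than a hidden constant. The default sample prep (0.2 g powder
reconstituted in 2 mL) converts an injected amount to µg/g powder as
`amount × recon_vol / (inj_vol × sample_mass)`.

## Statistics

Group comparisons accept either raw replicates or printed
mean/SD/n summaries as first-class input — published tables expose only
the latter, and the summary path is algebraically identical to the raw
decomposition when the raw data match the summaries
(`MS_w = Σ(n_i−1)s_i²/Σ(n_i−1)`; between-group SS from the means).
Tukey HSD uses the studentized-range distribution with the Tukey–Kramer
standard error for unequal n; at k = 2 it reduces exactly to the pooled
two-sample t-test. Shapiro–Wilk (per group) and Levene's test
(mean-centered, the classical variant) are advisory: they are reported,
never used to block the ANOVA, matching how such gates are used in
bench reports.

The compact letter display uses insert-and-absorb: start with one letter
covering all groups, split it on each significant pair, absorb subsets,
then order the letter sets by the largest member mean so that "a" marks
the top group. The output satisfies the contract that two groups share
a letter iff their difference is not significant, verified exhaustively
in tests for k ≤ 10. On the packaged study summaries this reproduces
the published superscripts: five moisture groups with the control alone
on "a" and three formulations sharing "e", and a single significant
encapsulation-efficiency pair.

For particle-diameter comparisons across formulations the package
treats each particle as an observation (unequal group sizes,
Tukey–Kramer); image-level means would be the conservative alternative
and can be fed through the same summary interface.

## Numerical choices and limitations

* Report tables round half-up at 2 decimals (`format_mean_sd()`);
  internal computation is double precision throughout.
* The MEC tolerance is relative (1e-7); degenerate inputs (collinear or
  duplicated points) fall back to the widest diametral pair.
* Tukey p-values come from `ptukey`, whose quantile accuracy is far
  below the 1e-6 we require of it.
* Problem sizes in the shipped analysis are chosen for a desk-scale
  rerun: 1024² demo micrographs with ~120 particles each and three
  2048² recovery frames; all seeds are explicit arguments.
* The family-wise error of Tukey at the study design (9 groups, n = 3)
  is checked by simulation (1000 seeded replicates) to lie near the
  nominal 0.05.
* Published per-formulation particle counts cannot be reproduced without
  the original micrographs; the package's claim is parameter *recovery*
  on ground-truthed synthetic data, which is the strongest statement
  available without the raw images.
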