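---
title: "Methods: TIL densities and a CD3/CD8 immunoscore from IHC digital pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIL densities and a CD3/CD8 immunoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tilscore` implements a two-stage analysis of tumor-infiltrating
T lymphocytes (TILs) in chromogenic immunohistochemistry (IHC):

1. an **image stage** that turns H-DAB-stained tiles plus tumor/necrosis
   annotations into per-patient densities of CD3+, CD8+ and CD45RO+ cells
   (cells/mm²), and
2. a **cohort stage** that derives survival-optimised high/low cutpoints
   for each marker, assigns a four-level CD3/CD8 immunoscore, and
   quantifies its prognostic value with Kaplan–Meier curves, log-rank
   tests and Cox proportional-hazards models.

The motivating application is neuroblastoma, a paediatric tumor with low
immune infiltration, where the density of infiltrating T cells carries
prognostic information beyond stage (INSS), risk group (COG), *MYCN*
status and age. Because the cohorts such analyses run on are not freely
redistributable, the package ships synthetic generators for both stages —
image tiles with exact cellular ground truth, and patient cohorts with
planted hazard structure — so every claim the package makes is testable
end to end.

## Image stage

### Optical density and stain separation

Chromogen amounts are additive in optical density (OD), not in intensity.
Each 8-bit RGB pixel is transformed per channel with the Beer–Lambert
relation

$$\mathrm{OD}_c = -\log_{10}\frac{I_c + 1}{I_0}, \qquad I_0 = 255,$$

the +1 keeping OD finite at 0. The OD vector of each pixel is then
unmixed by colour deconvolution: with unit stain vectors for
haematoxylin $(0.650, 0.704, 0.286)$ and DAB $(0.269, 0.568, 0.779)$
(the standard H-DAB pair) and a residual vector orthogonal to both, the
per-pixel system $\mathrm{od} = c^\top M$ is solved for the concentration
vector $c$. Negative concentrations are clipped to zero — they arise only
from noise, and stain amounts are physical. The stain vectors used by any
particular scanner/stain lot are overridable in `run_config()`;
automatic stain-vector estimation (Macenko-style) is out of scope.

### Nucleus segmentation and compartments

Nuclei are segmented from the haematoxylin concentration plane with a
classical chain: Otsu threshold (with an absolute floor of OD 0.15 so
empty glass is never segmented), hole filling, Euclidean distance
transform, watershed splitting of touching objects, and an area filter of
8–120 µm² (lymphocyte through tumor-cell nuclei at ×200, i.e. ~0.5 µm per
pixel). The published pipeline this emulates used a trained neural
segmenter; no weights exist to ship, and everything downstream depends
only on the *labelled-mask contract*, so any externally produced mask can
be imported via `read_label_mask()` (16-bit TIFF) and used unchanged.

Membranous markers are scored against a perinuclear ring: the background
within 2 µm (Euclidean distance, the cell-expansion convention of QuPath
and `skimage.segmentation.expand_labels`) of each nucleus, minus all
nucleus pixels, with contested pixels assigned to the nearest nucleus
centroid. The original ring width is unpublished; 2 µm is a declared,
configurable default approximating a membrane/cytoplasm rim.

### Positivity and densities

A pixel is DAB-positive when its DAB concentration strictly exceeds a
cutoff (default OD 0.3; `calibrate_dab_cutoff()` instead sets it at the
99th percentile of pooled control-slide DAB when control tiles are
available, mirroring calibration against negative controls). A **cell**
is positive when the DAB-positive area overlaps at least 5% of its
scoring compartment — the nucleus for CD3/CD8, the ring for CD45RO. The
5% floor makes the call robust to single-pixel bleed; set it near zero
for an any-overlap rule.

The region of interest (ROI) is annotated tumor minus annotated necrosis,
read from QuPath-dialect GeoJSON
(`properties.classification.name` ∈ {"Tumor", "Necrosis"}) and rasterized
by pixel-centre membership with half-open spans. Cells belong to the ROI
by centroid. These two conventions make densities exactly additive under
tiling: splitting a slide into quadrants and pooling counts/areas
reproduces the whole-slide density bit for bit, which the tests assert.
Density is positive cells per mm² of ROI; one region set per patient is
assumed (whether the original analysis averaged multiple blocks per
patient is unstated).

## Cohort stage

### Survival-optimised cutpoints

For each marker the high/low cutoff is the maximally selected rank
statistic on overall survival: candidate cutoffs are midpoints between
consecutive distinct order statistics leaving at least
`ceil(minprop * n)` patients (default `minprop = 0.1`) on each side; each
candidate is scored by the absolute standardized two-group log-rank
statistic; the maximiser wins, ties going to the smallest cutoff.
"High" means strictly greater than the cutoff. Cutoffs are derived on
overall survival (OS) and reused for event-free survival (EFS). Because
the cutoff is *selected* to maximise separation, the associated statistic
is strongly inflated relative to N(0,1) — a property test demonstrates
the inflation — so the package reports it for ranking only and computes
no selection-corrected p-value (none is reported in the analyses this
mirrors; a Hothorn–Lausen correction is a possible extension).

The immunoscore is the pair of CD3/CD8 binary scores mapped to
CD3+CD8+, CD3+CD8−, CD3−CD8+, CD3−CD8− (reference first). CD45RO is
deliberately excluded: it shows no EFS association in this setting.

### Survival analytics

All outcome analytics are computed from first principles, with the
`survival` package serving as an independent cross-check in the test
suite only:

* **Kaplan–Meier**: product-limit estimator with Greenwood variance and,
  by default, 95% intervals on the $\log(-\log S)$ scale (bounded in
  [0, 1]; a linear-scale option exists). Step evaluation is
  right-continuous; evaluation beyond follow-up carries the last value
  forward with a truncation flag.
* **Log-rank**: observed-minus-expected with hypergeometric variance
  summed over event times; the k-group statistic inverts the
  (k−1)-dimensional covariance block; df = k−1.
* **Cox proportional hazards**: Newton–Raphson maximisation of the
  partial likelihood with Efron (default) or Breslow tie handling —
  both shipped because the mirrored analyses used both R and Stata,
  whose defaults differ. Convergence at max |score| < 1e-9 or
  ΔlogPL < 1e-10, with step halving; a monotone likelihood (perfect
  separation) raises an error naming the runaway term. Wald standard
  errors come from the inverse observed information; hazard ratios are
  reported as exp(β) with 95% CIs, matching the HR (CI) presentation
  convention. No multiple-testing correction is applied anywhere.
* **Model building**: every candidate factor is screened univariably;
  factors with block-Wald p < 0.05 enter the multivariable model;
  backward selection repeatedly removes the non-forced factor with the
  largest block-Wald p ≥ 0.05. Categorical factors move as whole dummy
  blocks (a COG risk factor keeps or loses both its dummies together).
  The pre-selection (full) model is always reported alongside the
  selected one, since adjusted tables conventionally print all adjusters.
* **Associations** between categorical variables use the χ² test
  (Yates correction only for 2×2) switching to Fisher's exact test for
  2×2 tables with any expected count below 5.

## Synthetic generators

### Image tiles

`generate_ihc_image()` paints elliptical nuclei (radius 2–4 µm,
eccentricity ≤ 1.15) at haematoxylin OD 0.75 on a near-white background
(RGB 244, 242, 245 with Gaussian noise σ = 3), placing centroids by
rejection sampling with a minimum spacing of 2.5× the maximum radius —
the regime in which the classical watershed is validated; a lower
spacing factor provides a touching-cells stress mode. Positive cells
(exactly `round(n_cells × positive_fraction)` of them) carry DAB OD 0.6
either over the nucleus ("nuclear", CD3/CD8-like) or as a 1 µm
perinuclear rim ("membranous", CD45RO-like). The painted rim is kept
narrower than the 2 µm scoring annulus deliberately: a membrane stain is
physically thin, and a wider rim can graze a neighbouring cell's annulus
at minimum spacing, which would corrupt the generator's ground-truth
contract (≥95% sensitivity and precision for the default pipeline).
Chromogens are painted along the same stain vectors the deconvolution
assumes, so unmixing is exact up to rounding and noise. What the
generator does *not* emulate: tissue texture, scanner-specific noise,
stain variation between slides, overlapping/clumped cells, nucleus shape
variety beyond ellipses. Passing end-to-end tests therefore validate the
geometry and calling logic of the pipeline, not its robustness to
real-tissue artefacts — real data additionally need stain-vector and
cutoff calibration.

### Cohorts

`generate_cohort()` simulates patients with the covariate mix of the
244-patient neuroblastoma cohort the package's defaults describe
(`nb_cohort_characteristics()`: 46.7% aged <18 months, 57.4% male, 67.2%
advanced INSS, 44.3/25.4/30.3% COG high/intermediate/low, 13.5% *MYCN*
amplified among known, with unknown-category rows renormalised away).
Marker densities are log-normal around the published medians (CD3 156,
CD8 90, CD45RO 14 cells/mm²) with log-SDs (0.9, 0.8, 1.45) chosen so the
simulated upper range matches the published maxima (2100, 864, 949), and
5% zero-inflation emulating the 0/mm² range minima. The log-normal shape
is an assumption — only medians and ranges are published.

Immunoscore group membership is drawn first (defaults 0.45, 0.12, 0.08,
0.35 — group prevalences are not published; these imply marginal low-CD3
and low-CD8 prevalences of 0.43 and 0.47, consistent with roughly
40–50% "low" calls that survival-optimised cutpoints typically produce)
and densities are then drawn from the matching side of each marker's
true cutoff, so the generating cutoffs and groups are exact ground
truth. A mild, centred log-odds tilt (default 0.5) correlates adverse
clinical categories with the CD3−CD8− group without moving the marginal
frequencies, providing realistic confounding for the multivariable
recovery checks.

Survival times are exponential under proportional hazards,
$T_i \sim \mathrm{Exp}(\lambda_0 e^{x_i^\top\beta})$ — the simplest
PH-consistent generator — with independent OS and EFS draws, administrative
censoring uniform on 12–84 months (staggered accrual over a 7-year
window), and the default coefficient set taken from the published
multivariable model (OS: age ≥18 months HR 3.00, *MYCN* nonamplified
0.64, early INSS 0.68, COG intermediate/low 0.48/0.14, immunoscore
CD3+CD8−/CD3−CD8+/CD3−CD8− 2.50/1.07/6.04; analogously for EFS). The
baseline rate is calibrated by root finding either to a marginal
survival target (default: 3-year OS 77.1%, EFS 63.0%) or to an expected
event fraction under the censoring distribution.

## Numerical and design notes

* Pixel coordinates are 0-based with pixel centres at half-integers;
  polygons live in pixel units; rasterization is half-open — the source
  of exact tiling additivity.
* `mpp` (microns per pixel) defaults to 0.5, typical of ×200 scans, and
  must be set for real data; all physical parameters (areas, ring width)
  are specified in microns and converted through `mpp`.
* Watershed seed ties break toward the lowest label; rings resolve
  contested pixels by nearest nucleus centroid.
* Cutpoint ties resolve to the smallest cutoff; equal-to-cutoff densities
  are "low".
* Degenerate inputs fail loudly rather than silently: empty ROI, zero
  events, all-identical densities, zero-variance covariates and zero
  censoring windows are errors.
* Simulation sizes in the test suite (244-patient cohorts, a few hundred
  replicate seeds, 512² px tiles with ≤100 cells, bias checks at
  n = 2000 over 10 seeds) were chosen to make Monte Carlo error small
  relative to the tolerances asserted while keeping the default test run
  fast.
* When averaging hazard-*ratio* estimates across replicate cohorts, the
  mean exceeds the generating HR by roughly $e^{\mathrm{Var}(\hat\beta)/2}$
  (Jensen) plus the small-sample bias of strong effects at n = 244 —
  about +3% for the univariable and +7% for the eight-parameter
  multivariable design. Recovery checks therefore use a ±10% band, which
  accommodates the bias without hiding gross errors.

## Known limitations

* The classical segmenter assumes mostly non-touching nuclei; heavily
  clumped tissue needs an external segmenter (imported via the mask
  contract).
* The DAB cutoff and stain vectors are defaults, not calibrated truths;
  real studies should calibrate both.
* Hot-spot / invasive-margin spatial scoring and multiplex
  colocalization are out of scope; slides are scored as a whole.
* The Cox machinery covers right-censored single-event data; competing
  risks, time-varying covariates and proportionality diagnostics are not
  implemented.
* EFS and OS are simulated independently per patient, which ignores that
  death is part of the EFS composite; adequate for parameter-recovery
  purposes, not for joint-outcome modelling.
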