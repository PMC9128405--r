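# tilscore

Tumor-infiltrating lymphocyte (TIL) densities and a CD3/CD8 immunoscore
from brightfield IHC digital pathology, with the survival analytics to
evaluate their prognostic value.

## What it does, and for whom

In many solid tumors — including neuroblastoma, the paediatric cancer
this package's defaults describe — the density of infiltrating T cells
(CD3+ total, CD8+ cytotoxic, CD45RO+ memory) carries prognostic
information beyond clinical stage and genomic risk markers. `tilscore`
is for researchers who have H-DAB IHC slides and outcome data and want a
reproducible, fully testable path from pixels to hazard ratios:

1. **Image stage** — colour deconvolution of RGB tiles into
   haematoxylin/DAB optical-density planes (Ruifrok–Johnston), classical
   nucleus segmentation (Otsu + watershed; external masks importable),
   positivity calling by compartment overlap (nucleus for CD3/CD8,
   perinuclear ring for CD45RO), and densities in cells/mm² over the
   annotated tumor-minus-necrosis region (QuPath GeoJSON).
2. **Cohort stage** — per-marker high/low cutpoints by maximally
   selected rank statistics (the largest standardized log-rank statistic
   over admissible splits, minimum group proportion 0.1), a four-level
   CD3/CD8 immunoscore (CD3±CD8±), Kaplan–Meier curves with Greenwood
   intervals, k-group log-rank tests, and Cox proportional-hazards
   models — univariable screening at p < 0.05 followed by multivariable
   backward selection with the immunoscore forced — reporting hazard
   ratios `exp(β)` with Wald 95% CIs.

The core model: given covariates $x$, the hazard is
$\lambda(t \mid x) = \lambda_0(t)\,e^{x^\top\beta}$, fitted by
Newton–Raphson maximisation of the partial likelihood (Efron or Breslow
ties). The Kaplan–Meier estimator
$\hat S(t) = \prod_{t_i \le t}(1 - d_i/n_i)$ carries Greenwood variance
$\hat S^2 \sum d_i / (n_i(n_i - d_i))$. All of this is implemented from
the formulas inside the package and cross-checked against the
`survival` package in the test suite.

Because cohorts of this kind are not redistributable, the package also
ships **synthetic generators**: H-DAB tiles with exact cellular ground
truth, and patient cohorts with published covariate frequencies,
log-normal marker densities and exponential proportional-hazards
outcomes — so the whole pipeline is validated end to end in code.

## Worked example

Simulate a 244-patient cohort with the default (published) covariate mix
and hazard structure, then run the full cohort analysis:

```r
library(tilscore)

co  <- generate_cohort(cohort_sim_params(seed = 42))
rep <- run_cohort_stage(co, quiet = TRUE)
print(rep)
#> Cohort analysis report: 244 patients
#>
#> Cutpoints (cells/mm2, OS-optimised):
#>   CD3        133.4  (|z| = 5.30)
#>   CD8        84.75  (|z| = 7.11)
#>   CD45RO     14.35  (|z| = 2.03)
#>
#> Immunoscore groups:
#>
#> CD3+CD8+ CD3+CD8- CD3-CD8+ CD3-CD8-
#>      104       29       21       90
#>
#> 3-year OS  78.1% (72.0-83.0)
#> 3-year EFS 62.3% (55.6-68.3)
#>
#> Immunoscore log-rank (OS): chisq = 56.37, df = 3, p = 3.5e-12
#> Multivariable OS (vs CD3+CD8+):
#>   CD3+CD8-   HR  5.08 (1.89-13.68) p = 0.00129
#>   CD3-CD8+   HR  1.29 (0.27-6.23) p = 0.75
#>   CD3-CD8-   HR 10.20 (4.57-22.78) p = 1.45e-08
#>
#> Immunoscore log-rank (EFS): chisq = 45.63, df = 3, p = 6.78e-10
#> Multivariable EFS (vs CD3+CD8+):
#>   CD3+CD8-   HR  1.37 (0.70-2.66) p = 0.358
#>   CD3-CD8+   HR  0.90 (0.40-2.04) p = 0.804
#>   CD3-CD8-   HR  3.94 (2.52-6.17) p = 2.12e-09
```

Reading the output: the maxstat cutpoints land near the generator's true
density cutoffs (~133 and ~85 cells/mm² for CD3/CD8); patients low in
both markers (CD3−CD8−) carry a strongly elevated adjusted risk of death
and of any event, while the marginal 3-year survival matches the
cohort-level rates the simulation was calibrated to (77.1% OS, 63.0%
EFS). The adjusted CD3−CD8− hazard ratio overshoots its generating value
(6.04) in this single replicate — single-cohort estimates of strong
effects are noisy and, selected cutpoints being survival-optimised,
somewhat optimistic; the acceptance script below averages away the
replicate noise.

The image stage works the same way from tiles:

```r
p   <- ihc_sim_params(n_cells = 60, positive_fraction = 0.4, seed = 1)
sim <- generate_ihc_image(p)
ann <- list(tumor = list(sim$truth$tumor_polygon), necrosis = list())
quantify_tile(sim$image, ann, marker = "CD3", run_config())$density
#>   patient_id marker positive_count roi_area_mm2  density
#> 1       <NA>    CD3             24     0.065536 366.2109
```

`run_image_stage()` batches tiles via a manifest and writes per-cell and
per-patient CSVs; `run_cohort_stage()` accepts the resulting density
table (or any CSV in the 15-column cohort schema) and writes cutpoints
JSON, the scored cohort, KM curves and Cox tables.

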