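# xparr

Quantitative grayscale texture analysis for dentin–pulp regions of
interest (ROIs) on dental radiographs, aimed at one diagnostic question:
can pixel-level texture indices computed from an ordinary panoramic
radiograph flag the ribbon-like **C-shaped root canal** that normally
requires cone-beam CT to confirm?

## The model

For an 8-bit ROI with gray levels *B<sub>ij</sub>* and row maxima
*A<sub>i</sub>* = max<sub>j</sub> *B<sub>ij</sub>*, each pixel gets a
transmittance depth value

```
R_ij = [ log((A_i − B_ij)² + 1) · sin(π/2 · B_ij / A_i) ]²
```

(natural log; rows with *A<sub>i</sub>* = 0 are defined as zero). The map
is summarized into three per-ROI indices, recorded under native-resolution
and digitally magnified viewing conditions:

* **Xpar** — mean of all *R<sub>ij</sub>* (average depth variation per pixel);
* **Power Xpar** — scaled power mean `scale · (mean R_ij^p)^(1/p)`
  (defaults p = 2, scale = 10), amplifying focal deep structure;
* **Pixel Count** — ROI area, which inflates under digital zoom without
  adding anatomy.

Around the indices the package provides: a synthetic dentin–pulp phantom
and cohort generator (no external data needed anywhere), digital zoom by
nearest/bilinear/bicubic interpolation with a documented pixel-center
convention, Sobel gradient maps, minimal grayscale DICOM/PNG/TIFF input,
Mann–Whitney and Wilcoxon tests with rank-biserial effect sizes, Spearman
correlation, ROC analysis with Youden-optimal thresholds, multivariable
logistic models with odds ratios and likelihood-ratio tests, and a-priori
sample-size design via the noncentral t distribution. `run_study()` chains
the whole analysis and exports the report tables; a thin CLI
(`inst/cli/xpar_study.R`) wraps it with `simulate` / `measure` /
`analyze` / `report` subcommands.

## Worked example

```r
library(xparr)

# one synthetic C-shaped dentin-pulp ROI
ph <- make_tooth_phantom(phantom_params(canal_shape = "c_shaped"), rng_seed = 7)
texture_metrics(ph$image)
#> <texture_metrics> [non_zoomed] Xpar 15.137, Power Xpar 192.475 (p = 2, scale = 10), Pixel Count 2000

# the full study on the default 43-tooth cohort (22 C-shaped / 21 control)
rep <- run_study(study_config(cohort = cohort_spec(seed = 1), seed = 1))
rep
#> <study_report> 43 teeth (seed 1)
#>   tables: descriptives (64 rows), zoom comparison (12), logistic (3 models), ROC (12 strata)
#>   best ROC stratum: 1023x593 power_xpar non_zoomed, AUC 0.867

subset(rep$roc, resolution_group == "1023x593" & condition == "non_zoomed")[,
  c("metric", "auc", "threshold", "sensitivity", "specificity", "youden_j")]
#>         metric       auc  threshold sensitivity specificity youden_j
#> 10        xpar 0.7333333   11.75459        0.75         0.8     0.55
#> 11  power_xpar 0.8666667  171.01138        0.75         1.0     0.75
#> 12 pixel_count 0.5916667 2175.00000        0.25         1.0     0.25
```

Reading the output: Power Xpar is the strongest discriminator in the
high-resolution stratum — teeth scoring at or above the Youden-optimal
threshold are called C-shaped with sensitivity 0.75 at perfect
specificity, and the AUC of 0.87 is the probability that a random
C-shaped tooth outscores a random control. The same ordering (Power Xpar
» Xpar » Pixel Count) holds in every stratum once a real effect is
present, while zeroing the generator's effect knobs drives all AUCs to
chance — both properties are enforced by the test suite.

Sample-size design behind the 43-tooth cohort:

```r
sample_size_two_group_t(power_spec(effect_d = 0.90, alpha = 0.05, target_power = 0.80))
#> $n_per_group 21   $n_total 42   $achieved_power 0.8121
```

## Layout

```
R/                   implementation (imaging, depth map, phantom/cohort,
                     diagnostics, pipeline)
inst/cli/            command-line front end
scripts/acceptance.R design-quantity reproduction script
tests/testthat/      unit, property and acceptance tests
vignettes/           methods vignette (model, generator, design choices)
```

See `vignettes/xpar-methods.Rmd` for the model's assumptions, the
phantom's scope and limits, and every numerical convention the package
commits to.
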