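# octsubband

Quantification of the faint hyperreflective **sub-band posterior to the
external limiting membrane (ELM)** in high-resolution OCT of the outer
retina.

## The problem

On clinical OCT (5–7 µm axial resolution) the myoid zone — between the ELM
and the ellipsoid zone (EZ) — looks uniformly dark. A high-resolution
spectral-domain prototype (~2.7 µm axial PSF FWHM) with fusion of six
repeated volume scans resolves a faint reflective sub-band a few
micrometres posterior to the ELM, attributed to the photoreceptor myoid,
whose salience increases with age. This package is for image-analysis and
vision-science researchers who want a tested, reproducible implementation
of the quantitative side of that observation:

* a **parametric simulator** of flattened outer-retina OCT volumes
  (Gaussian bands, PSF blur, fused multiplicative speckle, foveal
  geometry, vessel shadows) standing in for non-public patient data;
* the **A-scan statistic**: the sub-band/ELM peak-intensity ratio in
  linear scale,

  `ratio (%) = 100 · I_subband / I_ELM`,

  with sub-pixel parabolic peak interpolation, a gap (hyporeflective
  separation) criterion, a fixed 4.9 µm fallback offset when no distinct
  peak exists, and a ±5 A-scan shadow-substitution rule;
* **B-scan visibility grading** emulated end to end (automated proxy with
  a 60% ratio threshold, simulated graders, 2-of-3 majority vote,
  adjudication);
* the **statistics battery**: Kruskal–Wallis, Spearman (t approximation),
  uncorrected Pearson χ², Cramér's V `V = sqrt(χ² / (n · min(r−1, c−1)))`,
  two-sided Fisher's exact test by hypergeometric enumeration, Cohen's κ,
  and a per-group/location cohort report with pooled summaries.

See `vignettes/octsubband-methods.Rmd` for the model, parameter rationale
and limitations.

## Worked example

Calibrate an eye to a 77% measured ratio, render a volume, locate the
fovea and measure the six distance points:

```r
library(octsubband)
grid  <- grid_spec(n_ascans_y = 5L)      # 500-column strip, 0.89 um axial
model <- outer_retina_model()            # 2.7 um PSF, 6-volume fusion
fovea <- foveal_geometry()

frac <- calibrate_reflectivity(77, model, grid)
#> 0.7691  — intrinsic amplitude fraction measuring as 77% (the PSF tails
#>           and noise floor inflate the smaller peak, so frac < 0.77)

ph  <- eye_phenotype("example", age_years = 57, laterality = "OD",
                     subband_rel_reflectivity = setNames(rep(frac, 6),
                                                         LOCATIONS))
vol <- render_volume(model, ph, fovea, grid, seed = 7)
fc  <- locate_fovea(vol)
#> foveal centre: column 250, B-scan 1, ELM height 65.0 um
measure_eye(vol, fc)[, c("location", "ratio_pct", "axial_offset_um")]
#>   location ratio_pct axial_offset_um
#> 1       2N      83.6            4.80
#> 2       1N      78.6            5.10
#> 3     0.5N     74.5            5.12
#> 4     0.5T     69.0            4.71
#> 5       1T      82.8            4.86
#> 6       2T      82.5            4.76
```

The measured ratios scatter around the 77% design with the ~5-point
standard deviation implied by the fused speckle, and the measured
ELM-to-sub-band offsets recover the designed 4.9 µm within half an axial
pixel. A full simulated cohort with Table-style statistics:

```r
res <- measure_cohort(cohort_design(seed = 1),
                      grid = grid_spec(n_ascans_y = 25L))   # 44 eyes, ~40 s
rep <- summarize_cohort(res$measurements, res$gradings,
                        res$manifest[, c("eye_id", "age_years", "age_group")])
print(rep)   # group means/SDs, Kruskal-Wallis, Spearman, chi2 / Cramer's V,
             # pooled means and visible fractions, grader kappas
```

## Pipeline and CLI

`run_pipeline(default_config(seed), out_dir)` executes
simulate → prep → measure → grade → stats, writing per-eye 32-bit float
TIFF stacks (+ JSON sidecars), measurement/grading CSVs, a Table-style
report CSV and a report JSON. The same stages are exposed as a CLI:

```sh
Rscript -e 'octsubband::oct_cli()' run --seed 1 --out out/
Rscript -e 'octsubband::oct_cli()' simulate --config cfg.yaml --out vols/
# (an installed launcher also lives at inst/cli/retsubband)
```

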