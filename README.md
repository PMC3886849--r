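# gliaquant

Unbiased quantification of perinatal white-matter injury (WMI) from glial
immunofluorescence, embedded in a fully seeded simulation of a fetal sheep
hypoxia–ischemia (H-I) study.

## The problem

In preterm WMI the injury spectrum is dominated by *diffuse* astrogliosis and
microgliosis rather than frank necrosis, so ordinal H&E necrosis scales
(0 = none … 4 = 76–100% necrotic) miss most of the injury range. A
continuous, selection-free alternative is the **stained-area fraction**: the
proportion of a white-matter region of interest (ROI) whose pixels are
labeled by GFAP (astrocytes) or Iba1 (microglia) immunofluorescence.
`gliaquant` is for image-analysis and perinatal-physiology researchers who
want that estimator, a ground-truth test bed for it, and the statistics that
link injury severity to hemodynamic/metabolic state.

## The estimator

For an ROI with `N` pixels, build the pixel-intensity histogram `c(v)` (one
bin per integer intensity level). Fluorescence background is the dominant,
approximately symmetric low-intensity mode, so:

1. locate the background peak `v*` as the count-weighted centroid of the
   three highest-frequency bins of the background mode (the maximal-mass run
   of three consecutive bins; ties toward lower intensity);
2. integrate the histogram on the background side of the peak,
   `B⁻ = Σ_{v < v*} c(v)`;
3. reflect: the background population is `B = 2·B⁻ + c(v*)` (the mode bin is
   counted once), clamped at `N`;
4. the labeled area fraction is `f̂ = max(0, (N − B) / N)`.

Per animal, `f̂` is averaged over triplicate sections. No threshold is ever
chosen by eye and no lesion is selected, which is what makes the index
unbiased.

The surrounding pipeline simulates the study that motivates the estimator: a
17-fetus H-I cohort with twin controls, four physiology epochs (baseline,
hypoxia, hypoxia–ischemia, recovery), a latent injury severity driven by the
occlusion-epoch blood glucose, oxygen content (CaO₂) and cephalic blood
pressure, lognormal marker links, synthetic section images with exact
ground truth, and a zero-inflated ordinal necrosis score.

## Worked example

```r
library(gliaquant)

# quantify one synthetic section with known 40% stained fraction
img <- generate_section_image(image_spec(true_fraction = 0.40, seed = 1))
r <- labeled_area_fraction(img)
sprintf("estimated fraction: %.4f (peak %.2f, background %d of %d px)",
        r$fraction, r$peak_intensity, r$background_count, sum(img$roi_mask))
#> "estimated fraction: 0.4016 (peak 30.01, background 156877 of 262144 px)"

# simulate one cohort and inspect it
ch <- generate_cohort(cohort_config(seed = 1))
ch
#> glia_cohort: 17 H-I + 17 control animals
#>   GFAP fraction  H-I 0.288  control 0.202
#>   Iba1 fraction  H-I 0.368  control 0.165
#>   pathology score 0 in 14/17 H-I animals

# week-adjusted association of occlusion-epoch lactate with CaO2
hi <- ch$epochs[ch$epochs$epoch == "hypoxia_ischemia", ]
adjusted_linear_assoc(hi$lactate, hi$CaO2, hi$survival_week,
                      predictor = "lactate", outcome = "CaO2")
#> CaO2 ~ lactate: slope -4.191 (se 0.32), t = -13.09, p = 3.03e-09,
#>   r2 = 0.925, n = 17 (adjusted for survival_week)
```

A single 17-animal cohort is intentionally noisy (the r² above is one draw);
the calibrated structure appears as replicate means. Averaging the
week-adjusted r² profile over 50 seeded cohorts:

```r
prof <- sapply(1:50, function(i) {
  pr <- multi_predictor_profile(generate_cohort(cohort_config(seed = child_seed(7, i))))
  setNames(pr$r2, paste(pr$outcome, pr$predictor, sep = "~"))
})
round(rowMeans(prof), 3)
#>      GFAP~BP    GFAP~CaO2 GFAP~glucose GFAP~lactate      Iba1~BP
#>        0.135        0.180        0.454        0.195        0.103
#>    Iba1~CaO2 Iba1~glucose Iba1~lactate
#>        0.078        0.281        0.095
```

Blood glucose is the strongest predictor of GFAP-measured injury; at 200
replicates the GFAP profile converges to ≈ 0.50 / 0.21 / 0.15 for
glucose / CaO₂ / BP.

The full pipeline (cohort → images → quantification → pathology →
associations → report) runs with one call, or from a shell via the thin CLI:

```r
run_pipeline(pipeline_config(seed = 42), out_dir = "run42")
```

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gliaquant.R", package="gliaquant"))') \
    all --config inst/extdata/example-config.yaml --out run42
```

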