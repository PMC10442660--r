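# nirhsi

Pixel-wise delineation of gastric-cancer extent on resected specimens from
near-infrared hyperspectral images (NIR-HSI), including tumor regions that
are *unexposed* — covered by normal mucosa and invisible under white light.
The package is aimed at researchers in biomedical optical imaging who want
a tested, reproducible reference implementation of this analysis protocol,
runnable end to end on synthetic specimens when clinical recordings are
unavailable.

## The method

A hyperspectral cube records a spectrum (1000–2350 nm, 6.3 nm steps) at
every pixel. The pipeline:

1. **Calibration.** Reflectance against white-standard and dark-noise
   frames, `R = (Ir − Id)/(Iw − Id)`, then absorbance `A = −log10 R`.
2. **Preprocessing.** Bands above 1400 nm dropped (64 bands remain);
   standard normal variate (SNV) per pixel, `Z = (x − x̄)/sd(x)`; pixels
   excluded as highlights (`R(1300 nm) > 0.70`), shadows (`< 0.10`),
   necrosis, within a 5-pixel Chebyshev margin of the pathologist's
   boundary lines, or outside the pathologically evaluated area.
3. **Classification.** Two-class soft-margin SVM (tumor vs normal, C = 1)
   with RBF kernel `K(xi, xj) = exp(−‖xi − xj‖²/σ²)`, bandwidth from the
   median heuristic `σ² = median{‖xi − xj‖² : i < j}`; 200 training pixels
   per class per specimen; leave-one-specimen-out cross-validation (each
   fold trains on 9 × 400 = 3600 spectra from the other specimens).
4. **Evaluation.** Per-specimen TP/FN/FP/TN inside the evaluated area;
   specificity `TN/(FP+TN)`, sensitivity `TP/(TP+FN)`, accuracy
   `(TP+TN)/total`, cohort means ± population SD; sensitivity stratified
   by exposed/unexposed region; tumor-thickness ranges of identified (TP)
   and unidentified (FN) areas.

A synthetic specimen generator (two-layer Beer–Lambert mixing: tumor
signal saturating with tumor thickness, attenuated exponentially by
covering mucosa) provides cohorts with known ground truth; see the
methods vignette (`vignettes/nirhsi-methods.Rmd`) for the model, parameter
defaults and their rationale.

## Worked example

Recompute published per-specimen metrics from confusion counts, using the
bundled reference tallies:

```r
library(nirhsi)
metrics(as_confusion_counts(10952, 1804, 1075, 17886, specimen_id = "d"))
#>  specimen_id stratum    tp   fn   fp    tn specificity sensitivity accuracy
#>            d     all 10952 1804 1075 17886    94.33047    85.85764 90.92285

ref <- reference_confusion_counts()
rows <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i)
  metrics(as_confusion_counts(ref$tp[i], ref$fn[i], ref$fp[i], ref$tn[i]))))
summarize_cohort(rows)
#> <cohort_summary> 10 specimens
#>   specificity   74.8 +/- 19.3  (n=10)
#>   sensitivity   77.2 +/- 18.7  (n=10)
#>   accuracy      79.7 +/-  8.9  (n=10)
```

Specimen (d) classifies 94.3% of its normal pixels and 85.9% of its tumor
pixels correctly; across the ten reference specimens the mean specificity,
sensitivity and accuracy are 74.8%, 77.2% and 79.7%.

Run the whole pipeline on a synthetic cohort:

```r
res <- run_all(pipeline_config(seed = 1))
res
#> <pipeline_result> 10 specimens, seed 1
#> <cohort_summary> 10 specimens
#>   specificity   97.9 +/-  2.1  (n=10)
#>   sensitivity   93.5 +/-  6.9  (n=10)
#>   accuracy      96.4 +/-  2.5  (n=10)
#>   region sensitivity: exposed 100.0, unexposed 85.1
```

On the default synthetic cohort every exposed tumor pixel thick enough to
survive the boundary margin is recovered, while the unexposed rim — where
covering mucosa attenuates the tumor signature — loses about 15% of its
pixels, the same qualitative asymmetry the protocol was designed to probe.
`detection_transition()` measures the thinnest detectable tumor for a
trained model (≈1.5 mm at the defaults).

Or from the shell:

```sh
Rscript scripts/run_pipeline.R --n 10 --seed 1 --out report/
```

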