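# vesselmrf

Modality-agnostic segmentation of blood vessels from 3D angiographic
volumes (MRA, CTA). Classical statistical vessel segmentation fits a
mixture model to the raw-intensity histogram, which ties every pipeline to
one modality and anatomy. `vesselmrf` first standardizes the data with a
multi-scale Hessian vesselness filter, after which one *fixed* mixture —
two Exponential components for the suppressed background, one Gaussian for
the vessel lobe — fits the filtered histogram for any input. Voxels are
then labelled by MAP classification refined with a 3D Markov random field
prior solved by iterated conditional modes (ICM).

The package is aimed at researchers in vascular image analysis who need a
self-contained, reproducible segmentation baseline: it ships a simulator
for tubular validation phantoms with layered Gaussian noise, overlap
metrics (segmentation error ratio, Dice similarity coefficient), NIfTI and
MetaImage I/O, and a command-line front end.

## The method in brief

1. **Vesselness filtering.** At scales σ (voxels) the σ²-normalized
   Hessian eigenvalues `|h1| ≤ |h2| ≤ |h3|` give, for bright tubes
   (`h2, h3 < 0`),

   ```
   v0 = (1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2c²))
   R_A = |h2|/|h3|,  R_B = |h1|/√|h2·h3|,  S = ‖H‖_F
   ```

   and 0 wherever `h2 > 0` or `h3 > 0`; the multi-scale response is the
   pointwise maximum. Defaults: α = β = 0.5, c = half the maximum Hessian
   norm of the volume.

2. **Fixed mixture via peak-seeded K-means + EM.** The filtered data,
   enlarged back to the original intensity range, is fitted with
   `f(x) = w_E1 λ1 e^(−λ1 x) + w_E2 λ2 e^(−λ2 x) + w_G N(x; μ_G, σ_G²)`.
   Histogram peaks (or an `I_max`/mid/`I_min` cold start) seed a 1D
   K-means; EM with closed-form M-steps refines all seven parameters.

3. **MAP–MRF labeling.** Vessel iff
   `w_G f_G(x) > w_E1 f_E1(x) + w_E2 f_E2(x)`, then ICM sweeps under an
   isotropic 26-neighbour Potts prior (strength `beta_sr`, default 1) until
   the labeling stabilizes.

## Worked example

Simulate the single-tube validation phantom (128³ voxels, tube intensity
810, three layered Gaussian noises), segment it, and score against the
known ground truth:

```r
library(vesselmrf)

spec <- phantom_presets(seed = 1)$phantom_I
ph   <- build_phantom(spec)        # $volume (vol3d) + $truth (labels)
res  <- segment(ph$volume)         # full pipeline with default config
res
#> <vessel_segmentation> 128x128x128 voxels, 18467 labeled vessel (0.881%)
#>   c = 164; EM 15 iter (converged); ICM 2 sweep(s)

score(res$labels, ph$truth)
#> <seg_scores> 2097152 voxels
#>   over-segmented:  221
#>   under-segmented: 330
#>   error ratio: 0.0263%
#>   DSC: 98.51%
```

`error ratio` is the percentage of misclassified voxels
(`(N_over + N_under) / N_total`); `DSC` is the Dice overlap
`2|S_g ∩ S_m| / (|S_g| + |S_m|)` with the ground-truth tube. The fitted
mixture, EM log-likelihood trace and ICM diagnostics are in `res$report`;
`plot_mixture_fit(res$histogram, do.call(mixture_model, res$report$mixture))`
draws the histogram with the three component curves.

Real volumes go through the same call: `segment(read_volume("tof.nii.gz"))`,
or from a shell via the bundled CLI:

```sh
Rscript inst/cli/vesselmrf segment --input tof.nii.gz \
    --output labels.nii.gz --report report.json --plot fit.png
Rscript inst/cli/vesselmrf phantom --preset phantom_II --seed 0 \
    --volume p2.nii.gz --truth p2_truth.nii.gz
Rscript inst/cli/vesselmrf score --pred labels.nii.gz --truth p2_truth.nii.gz
```

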