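---
title: "Statistical vessel segmentation of angiographic volumes: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical vessel segmentation of angiographic volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmrf)
```

## The problem and the model

Angiographic volumes (time-of-flight MRA, contrast CTA, and related
modalities) show blood vessels as bright tubular structures on a noisy,
modality-dependent background. Statistical segmentation methods classically
fit a mixture model to the raw-intensity histogram, but every modality and
anatomy needs its own mixture family, which makes such pipelines brittle.
`vesselmrf` instead standardizes the data first: a multi-scale Hessian
vesselness filter maps any input volume onto a common statistical shape —
a large mass of suppressed background at and near zero response, and a lobe
of enhanced vessel voxels at high response. One *fixed* mixture then fits
the filtered histogram regardless of where the volume came from, and a
Markov random field prior cleans up the voxelwise decision.

The pipeline has three stages.

**1. Vessel enhancement.** At each scale $\sigma$ the volume is convolved
with Gaussian-derivative kernels to obtain the Hessian, multiplied by
$\sigma^2$ ($\gamma = 2$ normalization) so responses are comparable across
scales, and eigen-decomposed into $h_1, h_2, h_3$ ordered by magnitude.
Bright tubes have $|h_1| \ll |h_2| \approx |h_3|$ with $h_2, h_3 < 0$. The
response is

$$v_0 = \begin{cases}
0 & h_2 > 0 \text{ or } h_3 > 0,\\[2pt]
\left(1 - e^{-R_A^2 / 2\alpha^2}\right) e^{-R_B^2 / 2\beta^2}
\left(1 - e^{-S^2 / 2c^2}\right) & \text{otherwise,}
\end{cases}$$

with $R_A = |h_2|/|h_3|$ (line vs. plate), $R_B = |h_1| / \sqrt{|h_2 h_3|}$
(blob deviation), and $S = \lVert H \rVert_F$ (structureness). The
multi-scale response is the pointwise maximum over the scale set — the
standard fusion for this filter family, which the single-scale formula
leaves open.

**2. Fixed mixture on the filtered histogram.** After enlarging the
filtered range back to the original intensity range, the histogram is fit
with

$$f(x) = w_{E1}\,\lambda_1 e^{-\lambda_1 x} + w_{E2}\,\lambda_2 e^{-\lambda_2 x}
       + w_G\, \mathcal N(x;\, \mu_G, \sigma_G^2),$$

two Exponential components for the low and middle background regions and a
Gaussian for the vessel lobe. Initialization is peak-seeded: histogram
peaks found by a smoothed local-extremum rule seed a 1D K-means when at
least three exist, otherwise the centroids start at
$(I_{\max}, (I_{\max}+I_{\min})/2, I_{\min})$. Clusters are re-sorted
ascending and mapped lowest $\to E_1$, middle $\to E_2$, highest $\to$
Gaussian; EM with closed-form M-steps then refines all seven parameters.

**3. MAP–MRF labeling.** The spatially blind MAP rule labels voxel $j$ as
vessel iff $w_G f_G(x_j) > w_{E1} f_{E1}(x_j) + w_{E2} f_{E2}(x_j)$ (ties
to background). An isotropic Potts/Ising prior on the 26-neighbour cube
then couples neighbours: iterated conditional modes sweeps the volume in
raster order, assigning vessel iff
$f_G(y)\,e^{-U(V)} > \frac{w_{E1} f_{E1}(y) + w_{E2} f_{E2}(y)}{w_{E1}+w_{E2}}\,e^{-U(B)}$,
where $U(\ell) = \beta_{sr} \times (\text{neighbours labelled} \neq \ell)$.
Agreement lowers energy, so the prior smooths: isolated misclassified
voxels flip once $26\,\beta_{sr}$ exceeds their log-likelihood gap.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha`, `beta` | 0.5 | — | sensitivity of $R_A$, $R_B$; 0.5 is the usual compromise preferring lines over plates/blobs |
| `c` | `"auto"` | intensity | structureness sensitivity; auto = half the maximum Hessian Frobenius norm over all voxels and scales, a single per-volume constant tied to the grey-scale range |
| `scales` | 0.5, 1–4 by 0.5 | voxels | Gaussian-derivative scales; see below |
| `n_bins` | 1024 | — | histogram resolution over the rescaled range |
| `smoothing_window` | 11 | bins | moving-average width before peak detection |
| `min_prominence` | 0.01 | fraction | required peak prominence relative to the tallest smoothed count |
| `em$tol`, `em$max_iter` | 1e-6, 500 | — | relative log-likelihood stop, iteration cap |
| `em$mode` | `"histogram"` | — | bin-weighted EM (default) or exact per-voxel EM |
| `beta_sr` | 1.0 | — | MRF interaction strength; 0 disables spatial coupling |
| `max_icm_iter`, `convergence_frac` | 20, 1e-4 | — | ICM sweep cap and changed-label stopping fraction |

All processing happens in voxel index space: voxel spacing is recorded and
passed through I/O untouched, but scales are in voxels and anisotropic
volumes are not resampled. For strongly anisotropic data, resample before
segmenting or read the scale set as in-plane voxels.

## Design choices where the design was open

**Scale set.** Scales 1–4 voxels cover the calibres of the vessels and
phantom tubes this package targets. The set additionally includes a
0.5-voxel scale, for two reasons. First, thin vessels (radius near 1.5
voxels) are localized much more sharply by a sub-voxel scale. Second — and
less obviously — the mixture model *needs* the background to respond a
little: with no scale below 1 voxel, Gaussian smoothing suppresses
background texture so completely that the filtered histogram collapses into
a single spike at zero plus the vessel lobe, with nothing in between. The
middle Exponential component then has no background mass to model and
drifts upward into the vessel lobe, which destroys the classification (on
the multi-tube validation phantom the Dice coefficient fell from the
mid-90s to ~72 without the fine scale). The 0.5-voxel scale lets noise
texture populate the low/middle histogram regions the two Exponentials are
built to describe.

**Peak prominence.** The published initialization takes "the first three
peak values" of the smoothed histogram. With 1024 bins, Poisson counting
noise puts hundreds of tiny local maxima on the flanks of the background
lobe; the literal rule would seed all three K-means centroids inside the
background. A peak therefore only counts if its topographic prominence
reaches 1% of the tallest smoothed count. All qualitative behaviours are
preserved (well-separated modes are found, monotone histograms yield none),
and `min_prominence = 0` restores the literal rule. In practice the
filtered histograms of the validation phantoms have fewer than three
prominent peaks, so initialization falls back to the
$(I_{\max}, \text{mid}, I_{\min})$ cold start, which is robust.

**Range restoration.** The filtered volume is enlarged so its top response
matches `max(original)` while zero stays fixed at zero, rather than mapped
affinely onto `[min(original), max(original)]`. The Exponential components
have support anchored at $x = 0$; if the original minimum is far above zero
(one validation phantom has min ≈ 99), an affine map would shift the
suppressed-background spike to that minimum, where no Exponential can model
it, and EM degenerates. Keeping zero fixed preserves the model's structural
assumption for any input range.

**Two independent rates.** The mixture density is written with a single
$\lambda$ symbol for both Exponentials, but the EM updates index them
separately, and the fitted curves for real data show two distinct slopes;
the package therefore carries independent $\lambda_1, \lambda_2$.

**Cluster-to-component mapping.** The cold start lists centroids in
descending order ($I_{\max}$ first) while the EM seeding maps cluster 1 to
$E_1$. Read literally, that would seed an Exponential on the vessel lobe.
Clusters are re-sorted ascending by centroid before mapping, so the
steepest Exponential always models the lowest-intensity region.

**Potts sign convention.** Writing the pair potential as 1 for *equal*
neighbour labels inside $e^{-U}$ would penalize agreement — the opposite of
smoothing. The package uses the standard convention (energy counts
*disagreeing* neighbours), matching the prior's stated purpose of cleaning
up misclassification.

**ICM objective.** "Sum over voxels of the log of the chosen side" counts
every pairwise interaction twice and is not guaranteed monotone under
single-site updates. The asserted trace is the joint pseudo-posterior
$\sum_s \log f(x_s) - \tfrac12 \sum_s U(x_s)$ (each pair once), which ICM
provably never decreases; every run checks this.

**Degenerate inputs.** A constant (or all-zero) volume has no Hessian
structure: `c = "auto"` fails with a parameter error at the filtering stage
(a noise floor of $10^{-10} \times \max|x|$ absorbs discrete-kernel
residue). With an explicit `c` the same input survives filtering and fails
at K-means with a degenerate-data error — either way a stage-tagged error,
never a crash. Ties in both decision rules go to background (conservative
vessel calls); Gaussian-component collapse ($\sigma_G$ below $10^{-6}$ of
the data range) raises a diagnostic error rather than continuing with a
degenerate density; a constant filtered field cannot be rescaled and
returns the original minimum with a warning.

## The phantom simulator

The simulator reproduces the published validation conditions: tubes with
smoothly varying diameter rasterized from spline centerlines, plus layered
Gaussian background noise. Each background voxel draws one component from
the $(\mu, \sigma^2, \omega)$ list by its proportion and then an intensity
from it — a mixture partition, matching the triple notation — and every
intensity is clipped at zero. Tube voxels get the target intensity plus
$\mathcal N(0, 15^2)$ jitter (the published targets are "stochastic" around
810/650 without a stated spread; 15 keeps the vessel lobe narrow). The
printed proportions of Phantom I sum to 1.04 and of Phantom II to 0.8; both
are renormalized to a proper partition with a warning.

Preset geometry: the published tube curves are unrecoverable from the
figures, so Phantom I is one helix-like arc through the $128^3$ volume with
radius growing 4 → 6 voxels (truth ≈ 0.9% of the volume, consistent with
what the published error/DSC pair implies about the truth size), and
Phantom II is a 3×3 grid of straight and gently curved tubes with radii
spanning 1.5–6 voxels in a $240^3$ volume. Validation is via overlap
metrics, not voxel-exact geometry.

What the phantoms deliberately do **not** emulate: partial-volume blending
at tube boundaries (truth stays exact), bias fields, Rician noise, vessel
branching, and contrast falloff along the vessel. Passing the phantom
bounds therefore demonstrates that the statistical machinery recovers
hard-edged tubes under layered Gaussian noise; it does not by itself
establish clinical performance, where those unmodelled effects matter.

## Numerical choices

* Gaussian-derivative kernels are sampled at radius $4\sigma$ with discrete
  moment corrections (order 0 sums to one, order 1 maps a ramp to slope
  one, order 2 maps $x^2/2$ to one), so Hessians of polynomials are exact
  to machine precision. Borders use mirror padding, which avoids spurious
  edge responses that would pollute the background histogram.
* Eigenvalues of the symmetric 3×3 Hessian come from the trigonometric
  closed form with clamping of the acos argument; degenerate (isotropic)
  matrices short-circuit.
* EM runs on the 1024-bin histogram by default (each bin centre weighted by
  its count); per-voxel EM is available and agrees within 1% at these bin
  widths. The observed-data log-likelihood is checked non-decreasing at
  every iteration (relative tolerance $10^{-8}$).
* K-means is a weighted 1D Lloyd iteration with centroids kept sorted;
  empty clusters retain their centroid.
* ICM updates labels in place in raster order; border voxels use the
  truncated neighbourhood rather than padded labels, which avoids biasing
  the borders toward either class.

## Problem sizes and runtime

The validation runs use the full published volumes: $128^3$ (~2.1M voxels)
and $240^3$ (~13.8M voxels), each over three seeds in the test suite. On
one CPU core a $128^3$ phantom segments in ~15 s and a $240^3$ phantom in
~2 min, dominated by the separable convolutions of the filtering stage.
Component-level tests use 48³ miniatures of the same construction, which
run the whole pipeline in under a second.

## Known limitations

* Bright-on-dark vessels only; dark-vessel (e.g. black-blood) data is out
  of scope.
* Scales are isotropic in voxel units; strongly anisotropic acquisitions
  should be resampled first.
* The mixture assumes the filtered background dominates the low/middle
  intensities. Volumes that are essentially all vessel (or all background)
  degenerate — the pipeline reports a stage-tagged error rather than a
  segmentation.
* ICM is a greedy optimizer: it refines the MAP labeling locally and can
  keep large contiguous misclassifications that a global solver might fix.
* `c = "auto"` keys on the single largest Hessian norm in the volume, so a
  lone very sharp, very bright structure raises `c` for everything and can
  dim the response of faint vessels.
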