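---
title: "Brightness-histogram viability quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brightness-histogram viability quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viabquant)
```

## The measurement model

Live/Dead (SYTO9 + propidium iodide) staining yields, per stained sample,
one to four green-marker frames (viable cells) and one to four red-marker
frames (non-viable cells), captured separately on a confocal microscope.
The frames show clustered fluorescent spots on a dark background; individual
bacteria are not resolvable, and the stain is binary — a cell is marked
alive or dead with no intermediate gradation — so a dimly lit pixel carries
the same biological meaning as a bright one. `viabquant` therefore does not
segment or count objects. It quantifies the *amount of bright signal
relative to dark background* and treats the green/red quotient of that
quantity as the viable/non-viable cell ratio.

The estimator chain for one frame is:

1. $V(p) = \max(R(p), G(p), B(p))$ per pixel, kept as 8-bit integers. The
   channel maximum is used precisely because it ignores how colours are
   perceived: a red spot and a green spot of equal intensity get equal $V$,
   which a perceptual luma (e.g. $0.299R + 0.587G + 0.114B$) would not give.
   Alternative luminance definitions are deliberately out of scope.
2. The occurrence histogram $h(v)$, $v = 0..255$, of $V$, normalized by the
   dark-pixel count: $\tilde h(v) = h(v)/h(0)$. This makes the histogram
   invariant to how much of the field of view is occupied: duplicating a
   frame side by side doubles both $h(v)$ and $h(0)$ and changes nothing
   downstream, which is the property that lets frames of different bacterial
   density be compared.
3. A scalar feature. Default `max_binned`: partition $v = 1..255$ into
   `n_bins = 127` contiguous bins, sum $\tilde h$ within each bin, take the
   maximum. Variant `sum_all`: $\sum_{v=1}^{255} \tilde h(v)$.
4. Per sample and time point, features are averaged per marker (arithmetic
   mean over the 1–4 frames) and the ratio of means is reported.

## Interpretation of the 127-bin feature

Two details of step 3 are interpretive choices, fixed and documented here:

* **The $v = 0$ level is excluded from binning.** $\tilde h(0) \equiv 1$ by
  construction and the dark level dominates every frame; a bin containing it
  would always win the maximum with a constant, information-free value. The
  zero level is the normalizer, not signal, so the 127 bins cover the 255
  *nonzero* levels.
* **Bin edges are floor-based:** bin $b$ (0-based) covers
  $v \in [1 + \lfloor 255b/n \rfloor,\; 1 + \lfloor 255(b+1)/n \rfloor - 1]$.
  Any contiguous equal-as-possible partition would do; this one is fixed so
  results are bit-reproducible. Ties in the maximum are immaterial because
  only the value, never the bin index, is used.

The bin count is exposed as a parameter (`n_bins`), with the limiting cases
`n_bins = 1` (identical to `sum_all`) and `n_bins = 255` (largest single
normalized entry). The test suite checks that rankings of simulated samples
under 63, 127 and 255 bins and under `sum_all` agree with Spearman
$\rho \ge 0.9$, so the default is a robustness choice, not a sensitive
tuning knob.

## Aggregation and ratio conventions

Green and red frames of a sample are *unpaired* captures, so the ratio is
formed between marker-level aggregates, not averaged over frame pairs.
Mean-of-features (rather than feature-of-pooled-histograms) is used so each
frame contributes equally regardless of its dark-area fraction. The ratio is
undefined — and reported as an error, "no detectable dead-cell signal" —
when the red aggregate is zero; an all-dark green set with a nonzero red set
legitimately yields ratio 0. Swapping the two marker sets maps every ratio
$r \mapsto 1/r$ exactly, which the tests assert to $10^{-12}$.

Frame selection ("brightest, best focus") is operationalized as an advisory
deterministic score, `quality_score()` = mean($V/255$) × Tenengrad gradient
energy (mean squared Sobel gradient of $V/255$). It ranks candidate frames
for reporting; manifest-listed frames are never silently dropped.

## Input contract and degenerate cases

* Only lossless 8-bit RGB TIFF/PNG are read. JPEG is rejected because
  compression noise scatters true-zero background pixels into low nonzero
  levels, corrupting $h(0)$, the anchor of the whole normalization.
  Non-8-bit files raise an explicit unsupported-depth error — silent
  rescaling would change the histogram support. RGBA alpha is discarded
  with a warning.
* A frame with *no* dark pixel has no normalization anchor and raises an
  error: conforming confocal frames always contain dark background, so this
  signals a non-conforming input rather than something to patch silently.
* The marker is taken from the manifest, never inferred from pixels; an
  advisory check warns when the declared marker's colour plane carries less
  total intensity than the opposite plane.
* Manifest groups (sample × time × marker) must hold 1–4 frames, matching
  how stained-sample datasets are assembled.

## The synthetic-image generator

`simulate_pair()` renders a Thomas-type cluster process: cluster centers
uniform over the frame, cells assigned to clusters multinomially, positions
offset by an isotropic Gaussian (`cluster_spread`), each cell drawn as an
additive Gaussian spot (`spot_sigma`) whose peak comes from a normal
distribution clipped to $[1, 255]$, then background, optional Gaussian
noise, clipping to $[0, 255]$ and 8-bit quantization. Green and red scenes
are independent draws, matching the unpaired acquisition model. Defaults,
chosen once for plausibility against described confocal image character
(sparse bright clusters, large dark areas, 1024×1024 frames):

| parameter | default | meaning |
|---|---|---|
| `width`, `height` | 1024 px | native confocal frame size |
| `n_clusters` | 25 | cluster centers per frame |
| `cluster_spread` | 15 px | SD of cell offsets around centers |
| `spot_sigma` | 2.5 px | per-cell Gaussian spot width |
| `peak_mean`, `peak_sd` | 180, 40 | peak brightness distribution (8-bit) |
| `background_level` | 0 | dark confocal background |
| `noise_sd` | 0 | additive noise (8-bit scale) |

`noise_sd` defaults to 0 because exported confocal frames have essentially
exact-zero background between clusters; the dark-pixel normalizer presumes
that. Nonzero noise is available for stress tests, with the caveat that
dense sub-quantization noise populates the lowest brightness levels and, at
high amplitude, competes with signal in the lowest bins. No point-spread
physics, z-stacks or spectral bleed-through are modelled: passing recovery
tests shows the estimator tracks planted brightness-mass ratios under the
stated cluster model, not that it is robust to optical artifacts absent
from the model. There is also no absolute calibration — the physical frame
area does not fix a per-cell pixel size, so `spot_sigma` is plausible, not
calibrated, and ratios are relative, never percent-viability.

`simulate_panel()` builds ladders of planted ratios at constant total cell
count: `n_live = round(total * r / (1 + r))`. At high planted ratios the
brighter frame has fewer dark pixels than its partner, which inflates the
estimated ratio multiplicatively; the estimator is therefore validated as a
monotone *ranking* estimator (Spearman $\rho \ge 0.9$ against planted
ratios; mean estimate within $[0.8, 1.25]$ at the planted-equal split), not
as an unbiased absolute estimator at extreme splits.

## Validation problem sizes

Simulation scales used by the test suite and the acceptance script were
fixed as follows: oracle checks on 100 random 64×64 frames and 100 sparse
16×16 toy frames; recovery and robustness on a panel of 5 planted ratios
{0.25, 0.5, 1, 2, 4} × 3 replicates at 256×256 px and 400 cells per pair —
256×256 keeps per-frame cell density in the realistic sparse regime while
the whole panel (30 frames) simulates and quantifies in seconds; PCA oracle
checks on 6×9 matrices (six reactors, nine variables, the shape of a real
reactor campaign).

## The integration stage

The nine reactor variables (TOC removal, CH4, CO2, ecotoxicity, EST, GST,
CAT, ROS, non-viable fraction) arrive in heterogeneous units, so each is
z-scored (mean 0, SD 1, $n-1$ denominator; a constant column is an error
naming the column) and the PCA is the eigendecomposition of their
correlation matrix, computed via SVD of the standardized matrix. Full-rank
eigenvalues sum to 9, variance fractions sum to 1, and a deterministic sign
convention — the largest-magnitude element of each loading column is made
positive — removes the arbitrary axis orientation so repeated runs are
identical. Biplot arrows are loadings scaled by $\sqrt{\lambda_j}$
(correlation-scaled); reactor groupings are left to the reader, supported
only by score-space Euclidean distances (`score_distances()`), since any
ellipse drawing is interpretive.

`simulate_reactor_metrics()` plants a two-factor structure mirroring the
observed variable groupings (TOC/CH4/EST vs Ecotox/Nonviable on factor 1;
CO2/ROS vs CAT/GST on factor 2). With squared loadings 0.9225 and 0.35 the
planted correlation matrix has leading eigenvalues exactly
$1 + 4(0.9225) = 4.69$ and $1 + 3(0.35) = 2.05$ — a two-component share of
74.9% of the 9 variables. In the default `exact` mode, factor scores and
residuals are orthogonalized and rescaled so the *sample* covariance equals
the planted covariance and recovery is deterministic; `exact = FALSE` gives
ordinary noisy draws for sampling-variability studies.

```{r pca-demo}
m <- simulate_reactor_metrics(n_reactors = 24, seed = 3)
reactor_pca(m, k = 2)
```

## Known limitations

* The brightness-mass estimator conflates cell count with cell brightness:
  a sample whose cells stain brighter scores higher at equal count. Within
  one stained experiment this is the intended behaviour (binary stain, all
  bright pixels count), but ratios are not comparable across staining
  protocols or detector gains.
* Saturation (clipping at 255) compresses the feature in extremely bright,
  dense frames; the simulator reproduces this regime and warns when fewer
  than 1% of pixels remain dark.
* The PCA stage requires a complete matrix; no imputation is provided.
* Proprietary microscope containers (LSM/LIF/CZI) are not read; export to
  TIFF first.
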