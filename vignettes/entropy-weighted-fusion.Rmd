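---
title: "Entropy-weighted ensemble fusion of volumetric segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted ensemble fusion of volumetric segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrofuse)
```

## The problem

Automated mitochondria segmentation in FIB-SEM (focused ion beam scanning
electron microscopy) volumes is usually run with more than one network —
typically an object-detection-style model and a voxelwise semantic model —
because the two families fail differently. Detection-style models
occasionally miss a whole organelle (a detection false negative: an entire
connected component absent from the output); semantic models tend to err at
object boundaries. `entrofuse` implements the post-processing stage that
combines such predictions: it weights each model by the Shannon entropy of
its calibration metric profile and fuses the prediction volumes voxelwise,
so a structure found by only one model can still survive into the final
mask.

The package deliberately contains no training or inference code. Its inputs
are prediction volumes (binary masks or per-voxel scores in $[0,1]$) and
expert-annotated label volumes, read from multi-page TIFF stacks,
directories of 2D slices, or HDF5 datasets.

## The method

For an ensemble of $n$ models, each model $j$ is first evaluated on a
*calibration* pair (its prediction of a labelled volume) with an ordered
panel of $L$ similarity metrics, giving a metric vector
$\mathbf{m}_j = (m_{j1}, \dots, m_{jL})$, all entries in $[0,1]$. The
default panel is the seven-metric set
`JI_F, JI_B, m_IoU, DSC, accuracy, precision, recall`.

The vector is normalized to a probability distribution and scored with
Shannon entropy:

$$p_{ji} = \frac{m_{ji}}{\sum_l m_{jl}}, \qquad
  H_j = -\sum_i p_{ji} \log_2 p_{ji},$$

with $0 \log 0 = 0$. Under the default **normalized** convention $H_j$ is
divided by $\log_2 L$ so it lies in $[0,1]$; a **raw_bits** mode returns
the literal entropy in bits. Weights follow the entropy weight method —
lower entropy, i.e. a more discriminating profile, earns more weight:

$$w_j = \frac{1 - H_j}{\sum_k (1 - H_k)},$$

renormalized to sum to one (an identity whenever the $w_j$ already do,
which is always the case in exact arithmetic; with two models the
renormalization is literally the identity). The fused score volume is the
voxelwise convex combination

$$P(v) = \sum_j w_j\, m_j(v),$$

binarized at an inclusive threshold ($P \ge t$, default $t = 0.5$).

### Why the conventions matter

* **The probability normalization** $p_i = m_i / \sum_l m_l$ is the
  standard entropy-weight-method construction and makes $H$ invariant to
  rescaling the whole panel. The alternative of treating each metric value
  directly as a probability is not scale-invariant and can produce
  $\sum p \ne 1$.
* **Normalized vs raw bits.** With $L > 2$ a near-uniform metric vector has
  $H > 1$ bit, so the literal weight numerator $1 - H$ goes negative and
  Eq-style weights lose monotonicity (a smaller entropy can then earn a
  *smaller* weight because the denominator is negative). Dividing by
  $\log_2 L$ keeps $H \in [0,1]$ and $1 - H \ge 0$, preserving both
  non-negativity and monotonicity. `raw_bits` is retained for completeness
  and is protected by the degeneracy fallback below.
* **Degeneracy.** When $|\sum_k (1 - H_k)| \le \varepsilon$ (default
  $\varepsilon = 10^{-9}$) the weights are undefined; the ensemble falls
  back to uniform weights and the result is flagged `degenerate`. With two
  models this occurs exactly when both profiles are maximally uniform.
* **Inclusive threshold at 0.5.** With two near-equal weights, a voxel
  predicted by only one model receives a fused score of about one half.
  The inclusive rule $P \ge 0.5$ keeps such voxels, which is precisely the
  mechanism that repairs single-model whole-object misses; an exclusive
  rule would discard them.

### A property worth knowing: the weights track dispersion, not quality

The entropy of a *similarity* metric vector measures how uniform the
profile is, not how good the model is. A perfect model scores 1.0 on every
metric — a perfectly uniform profile, hence **maximal** entropy and the
*smallest* weight; a badly broken model with a spread-out profile (some
metrics near 0, others near 1) gets a *larger* weight. The package computes
this honestly and the test suite asserts the actual ordering. Two practical
consequences:

1. Entropy weighting is informative when the ensemble members are of
   broadly comparable quality, which is the regime the method is intended
   for (all its published uses fuse two strong networks). With comparable
   calibration profiles the weights land near $1/n$ and fusion behaves like
   slightly tilted averaging.
2. If one calibration profile is pathological (e.g. an all-zero
   prediction), its weight can exceed that of a much better model. Inspect
   the weight report (`write_weight_report()`, or the logged entropies in
   `cmd_fuse()`) before trusting a fused result.

For the same reason fusion is not guaranteed to beat the best single model
under asymmetric systematic bias — e.g. one member that under-segments
fused with one that over-segments. The acceptance script includes exactly
such a scenario and reports the fused panel next to the best individual
one, whichever way the comparison falls.

## Evaluation metrics

All scalar metrics derive from one `confusion_counts()` core that
accumulates TP/FP/FN/TN as exact integer tallies (no floating summation of
indicators), so counts are bit-exact at any volume size:

* `pixel_accuracy` $= (tp+tn)/\text{total}$, `error_rate`
  $= (fp+fn)/\text{total}$; their sum is exactly 1.
* `jaccard` foreground $tp/(tp+fp+fn)$ and background $tn/(tn+fp+fn)$;
  `dice` $= 2tp/(2tp+fp+fn)$, satisfying $DSC = 2J/(1+J)$.
* `mean_iou` averages the two class IoUs. The default `global` mode uses
  whole-volume counts. Published per-dataset tables are ambiguous about the
  aggregation level (printed means do not always equal the average of the
  printed class IoUs), so a `per_slice` mode is provided to explore the
  alternative: each z-slice contributes the mean of its *defined* class
  IoUs, and a class whose slicewise union is empty is excluded from that
  slice — this keeps slices without any mitochondria well-defined.
* `auroc` uses the tie-corrected rank (Mann–Whitney) formulation: the
  probability a random positive voxel outscores a random negative one,
  ties counted half. It is exact and threshold-free; for binary scores it
  reduces to $(TPR + TNR)/2$.
* **Empty-set convention:** any similarity metric with a zero denominator
  (e.g. precision of an empty prediction, foreground IoU when both volumes
  are empty) scores 1.

## Preprocessing

The intensity preprocessing mirrors the standard EM pipeline: slicewise
CLAHE followed by a small Gaussian blur. Both operate on 2D z-slices —
their natural parameters (an $8 \times 8$ tile grid, a $3 \times 3$
kernel) are 2D constructs.

* **CLAHE**: clip limit 2, $8 \times 8$ tiles by default, delegated to
  `EBImage::clahe`. The equalizer works in single precision, so outputs are
  clamped back onto the input slice's range; a constant slice (flat
  histogram) passes through unchanged.
* **Gaussian blur**: $3 \times 3$ kernel. Only the kernel size is
  conventionally specified, so sigma follows the common
  derive-from-kernel-size rule $\sigma = 0.3\,((k-1)/2 - 1) + 0.8$, i.e.
  $\sigma = 0.8$ for $k = 3$, fixed and documented. Borders use reflect
  padding, avoiding dark rims at slice edges. The kernel is normalized, so
  constant slices are invariant and the operation commutes with intensity
  scaling.
* **Alignment hook**: the slice-alignment step that sometimes follows is
  left as a pass-through hook (`align` argument of `preprocess_volume()`);
  no registration is estimated because no transform model or reference is
  specified for it.

## The synthetic phantom generator

`generate_ground_truth()` emulates the morphology that matters for fusion
mechanics: disjoint oval (axis-aligned ellipsoid) and tube-like (dilated
persistent-random-walk centerline) components, mirroring the oval and
tubular mitochondria shapes seen in EM volumes. Objects are separated by a
minimum gap so the 26-connected component count equals `n_objects` exactly
— connectivity is 26 (face, edge, corner), the standard choice for
volumetric object counting. `degrade()` layers the observed failure modes
of real pipelines: whole-component drops (detection misses), boundary
erosion/dilation (under/over-segmentation), spherical false-positive blobs
kept off the true foreground (so FP/FN bookkeeping in tests stays
unambiguous), and i.i.d. voxel flips. `scenario_complementary_fn()` builds
the canonical repair case: two otherwise-perfect predictions missing
disjoint whole objects, whose union is the truth.

Every generator is a pure function of its spec: a private RNG stream is
derived from `(seed, operation name)` and the caller's RNG state is left
untouched, so results are reproducible independent of call order.

What the phantoms do **not** emulate: electron-microscopy textures and
intensities (masks are binary; preprocessing tests use uniform-noise
intensity volumes), anisotropic voxels, touching or nested organelles, and
spatially correlated noise. Passing tests therefore demonstrate the
correctness of the fusion/metric machinery, not segmentation performance
on real EM data — headline scores on real datasets depend on trained
networks that are out of scope here.

## Numerical choices

* Confusion counts are exact integers; all metric ratios are single
  divisions of exact counts, which is what makes identities like
  `accuracy + error_rate == 1` hold bit-exactly in the tests.
* Fused scores are snapped onto the voxelwise $[\min_j m_j, \max_j m_j]$
  envelope after accumulation, so convexity and the set relations
  (intersection $\subseteq$ fused mask $\subseteq$ union for binary
  inputs, any $t \in (0,1]$) hold exactly despite round-off — e.g. voxels
  where every model agrees fuse to exactly the agreed value.
* Masks are stored on disk as 8-bit $\{0, 255\}$; any two-valued volume
  $\{a, b\}$, $a<b$, read as a mask maps $a \to 0$, $b \to 1$, since
  public datasets code labels as 0/255 or 0/1 interchangeably. Score
  volumes are written as 32-bit float TIFF or native-precision HDF5.
* Volumes are carried in `(z, y, x)` axis order (R's native 1-based
  indexing), matching slice-stack acquisition; slice directories are
  ordered by numeric-aware natural sort so `s10` follows `s2` and zero
  padding is neutral.

## Problem sizes in the test suite

The suite validates the metric core against a voxel-by-voxel enumeration
oracle on 500 random volumes up to $16^3$ and AUROC against the all-pairs
oracle up to $8^3$; the complementary-miss repair is replayed over 100
phantom seeds at $16 \times 32 \times 32$ with 4 objects; drop-probability
monotonicity uses 200 seeds at each of two probability levels. These sizes
were chosen so the full suite exercises every contract in a few minutes on
a single CPU while keeping the oracle comparisons exhaustive.

## Known limitations

* Weights are global per model — one scalar per model per ensemble — as
  the method defines them; no per-slice or per-voxel weighting.
* Single foreground class; multi-class fusion is out of scope.
* The calibration/target split is the caller's contract: the package does
  not prescribe which labelled data the metric vectors come from, and
  weight quality depends on that choice.
* No boundary-distance metrics (Hausdorff, surface Dice) and no
  instance-level detection metrics.
* DICOM/NIfTI input, anisotropic resampling and out-of-core volumes are
  not supported.
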