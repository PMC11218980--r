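---
title: "Methods: enhancement operators, relative-position attention, and the phantom benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancement operators, relative-position attention, and the phantom benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrivit)
```

`mrivit` implements a complete four-class brain-tumor MRI slice
classification pipeline: a three-operator image-enhancement stage used both
for preprocessing and for dataset augmentation, a modified ViT-B/16
classifier whose attention carries clipped two-dimensional relative position
encodings and whose feed-forward blocks have an inner residual shortcut, the
dataset-handling conventions (augmentation doubling, stratified 80/20
split), and the evaluation suite (confusion-matrix metrics, PR curves,
normal-approximation accuracy intervals). A seeded phantom generator makes
every stage testable without clinical data. This vignette records the
models, the tunable parameters, and the numerical and design choices.

## The enhancement operators

MRI slices commonly suffer low contrast, smooth brightness gradients and
noise. The pipeline chains three classical operators; their composition is
also the augmentation operator that doubles the dataset.

**Homomorphic filtering** models a pixel as illumination times reflectance,
$f(x,y) = i(x,y)\,r(x,y)$. Taking logarithms turns the product into a sum,
so a frequency-domain gain can suppress the slowly varying illumination
while amplifying detail. The transfer function is the Gaussian high-emphasis
form
$$H(u,v) = (\gamma_H-\gamma_L)\left\{1 - e^{-c\,D^2(u,v)/D_0^2}\right\} + \gamma_L,$$
with defaults $\gamma_H = 1.5$, $\gamma_L = 0.5$, $c = 1$, $D_0 = 40$;
$D(u,v)$ is the distance from the centered spectrum origin, measured in
index units. At $D = 0$ the gain is exactly $\gamma_L$; it rises
monotonically towards $\gamma_H$. The implementation applies $H$ to the
transform of the whole log-image (the illumination and reflectance spectra
are not separable in practice), adds a log guard $\varepsilon = 10^{-3}$
(zero pixels are ubiquitous in MRI background), exponentiates and rescales
to $[0, 255]$.

One numerical choice deserves a note: exponentiation after filtering
produces rare extreme pixels, and a plain min--max stretch would let those
outliers compress the bulk of the histogram into a handful of gray levels,
*reducing* the detail the operator is meant to enhance. `homomorphic_filter()`
therefore clips 0.5% per tail (the `clip_quantile` argument; 0 restores the
plain min--max stretch) before the linear stretch.

**CLAHE** equalizes contrast locally. The image is divided into
`tile_rows x tile_cols` sub-blocks (default 8 x 8); each block's 256-bin
histogram is limited at
$\mathrm{CL} = s_L \cdot S / n_\mathrm{bins}$ (clip factor $s_L = 2$ by
default, $S$ the tile pixel count); mass above the limit is removed and
spread uniformly over all bins; because the uniform share can push bins back
over the limit, the clip--redistribute cycle repeats until the residual
excess drops below `redistribution_tol` (0.5 counts). The printed
redistribution formula in the source description of this scheme is
internally inconsistent, so the standard iterative cycle is used; it
conserves the total count exactly, which the tests assert to $10^{-9}$.
Each pixel is finally mapped through a bilinear blend of the four
surrounding tiles' cumulative mappings, which are monotone by construction.

**Unsharp masking** adds back an amplified high-frequency residual:
`img + amount * (img - gaussian_blur(img, blur_sigma))`, clamped to
$[0, 255]$; defaults `blur_sigma = 1`, `amount = 1` (no kernel is prescribed
by the method description; a Gaussian low-pass is the conventional choice).

**Information entropy** scores enhancement: the Shannon entropy (bits) of
the 256-bin gray-level histogram, in $[0, 8]$. The package asserts the
*direction* of the published evaluation — over 20 seeded low-contrast
phantoms the combined HF → CLAHE → UM output has higher mean entropy than
the input — not its absolute values, which depend on the clinical images.

## The classifier

The backbone is ViT-B/16: a 224 x 224 input is cut into 16 x 16 patches
(a 14 x 14 grid), each flattened and linearly projected to 768 channels; a
learnable class token is prepended; 12 pre-norm encoder blocks with 12 heads
follow; the class token's final state feeds the head. Two modifications
define the variant:

**Clipped 2-D relative position encoding.** Plain self-attention is
permutation-invariant. Here, every ordered token pair $(i, j)$ is assigned a
bucket from its clipped spatial offset,
$$\mathrm{bucket}(i,j) = (\mathrm{clip}(\Delta r, k) + k)(2k+1) +
  (\mathrm{clip}(\Delta c, k) + k),$$
with $\mathrm{clip}(\delta, k) = \max(-k, \min(k, \delta))$ and one extra
bucket reserved for any pair involving the class token — $(2k+1)^2 + 1$
buckets total, shared across heads, with per-head learnable content: a
scalar logit bias $b$ and three `head_dim` vectors $p^Q, p^K, p^V$ per
bucket. The logit and output become
$$e_{ij} = \frac{(q_i + p^Q)(k_j + p^K)^\top + b}{\sqrt{d_z}},\qquad
  z_i = \sum_j \alpha_{ij}(v_j + p^V),$$
with $d_z$ the per-head channel count. Three choices here were genuinely
open:

* The printed clip function ($\max(k, \min(k, \delta))$) is constantly $k$;
  the standard clamp above is what "retaining only the relative positional
  information within a certain range" requires.
* The published description mentions scaling by sequence length in prose
  while its equations write $\sqrt{d_z}$; the per-head dimension is used,
  matching universal transformer practice.
* Absolute position embeddings are removed by default (`use_abs_pos`
  restores them): the relative encoding is presented as *the* position
  mechanism, and keeping both would confound the reduction test below.

Zero-initialized tables make the untrained network *exactly* a plain ViT:
the test suite asserts that with zero tables the vectorized attention
matches an independent plain scaled-dot-product implementation to $10^{-6}$,
and that with arbitrary tables it matches a literal double-loop evaluation
of the defining equations. Bucket ids depend only on offsets, so the
encoding is translation-invariant by construction (asserted by brute force).

**Residual feed-forward block.** The MLP sub-layer is
`Linear(d -> 4d) -> GELU -> Dropout -> Linear(4d -> d) -> Dropout` with an
*inner* shortcut, $F(x) + x$, additional to the encoder-level residual
around the sub-layer. At zero inner weights the block is the identity and
its Jacobian is the identity matrix (checked by finite differences).

**Head.** The class-token vector is adaptively average-pooled to
`pooled_dim` channels (default 256; the source names the pooling but not its
size), then Linear → tanh → Linear to 4 unnormalized scores; softmax lives
in the loss. Pooling with `pooled_dim = embed_dim` is the identity.

**Initialization.** Transformer projections use truncated-normal
(sd 0.02); relative tables start at zero (the plain-ViT reduction point is
the initial condition); the two head layers use Glorot-style
$\mathrm{sd} = 1/\sqrt{\mathrm{fan~in}}$. The last choice matters: two
stacked sd-0.02 layers would scale the gradient reaching the backbone by
$\sim 4\times10^{-4}$ and visibly stall the first half of a 30-epoch budget.

## Dataset handling

`build_manifest()` scans a class-folder tree (`glioma/`, `meningioma/`,
`pituitary/`, `no_tumor/`) into a tibble of records.
`augment_manifest()` adds exactly one combined-enhanced copy per original
— the published counts double from 7,023 to 14,046, which is consistent
with one combined HF+CLAHE+UM copy rather than one copy per operator.
`stratified_split()` shuffles each class with a seed and assigns
round-half-up(0.8 n) records to training; round-half-up is the only
rounding rule that reproduces both published fractional cases
(2593.6 → 2594 and 2811.2 → 2811). The split runs *after* augmentation over
all records, so an original and its enhanced twin can land in different
folds. This mirrors the published order of operations but is a genuine
leakage risk on real data: an enhanced twin in the test set is correlated
with a training original, so test accuracy there should be read as
optimistic. `load_batch()` resizes bilinearly to the model size, scales to
$[0,1]$ and standardizes with mean 0.5 / sd 0.5.

## Training and evaluation

`vit_train()` uses the published recipe — Adam, learning rate 0.001, batch
size 8, 30 epochs, categorical cross-entropy (the loss is not named in the
source; cross-entropy is the universal choice for softmax classification) —
records train/test accuracy and loss per epoch, and returns the
highest-test-accuracy checkpoint. Two trainer choices are ours: a global
gradient-norm ceiling of 1 per step (without it the loss shows recurrent
divergence spikes at batch size 8) and dropout/drop-path rates of 0.1 in
the full configuration but 0 in the desk-scale one (unit tests need
determinism, and a 39k-parameter model needs no stochastic regularization).

Metrics follow the one-vs-rest definitions: per-class accuracy
$100\,N_t^{(i)}/N^{(i)}$; precision $TP/(TP+FP)$ (the printed formula with
$TN$ in the numerator is specificity, inconsistent with its own name and
use, and is treated as a typo); recall $TP/(TP+FN)$; F1 the harmonic mean;
macro averages are unweighted class means (the averaging convention is not
named in the source; macro is the standard for a 4-class report). Undefined
ratios are reported as missing, never as zero. The accuracy interval is the
normal approximation $\pm 1.96\sqrt{\mathrm{acc}(100-\mathrm{acc})/n}$,
clamped to $[0, 100]$. One documented discrepancy: the published per-class
error counts imply an overall accuracy of $(2809-238)/2809 \approx 91.53\%$,
while the printed total is 91.36%; the package computes the former identity
and leaves the inconsistency to the reader.

## The phantom benchmark

`generate_phantom()` renders a seeded, deterministic head phantom:
elliptical "head" on a dark background; smooth tissue texture confined to a
low-contrast window (default [90, 150]); a multiplicative illumination
gradient (default ±30%) so the illumination–reflectance model has something
to remove; additive Gaussian noise (default sd 6 gray levels); and a
class-dependent lesion — an irregular superior blob (glioma), a bright rim
with dark core near the cortex (meningioma), a compact bright midline disc
low in the head (pituitary), or nothing (no_tumor). The geometry is invented
purely to make the four classes separable; no radiological realism is
claimed, and passing the phantom benchmark says nothing about clinical
accuracy — it validates the pipeline's mechanics (data flow, optimization,
metrics), not the medical claim.

The desk-scale study uses `vit_config_tiny()` — 64 x 64 inputs, 8 x 8
patches, width 32, 2 blocks, 4 heads, clip bound 3, pooling width 32 —
trained on 200 phantoms (50 per class, stratified 80/20) with the published
optimizer settings. Under a fixed seed this reaches ≥ 90% held-out accuracy
in a few CPU-minutes, and the trained model's class-token attention
concentrates on lesioned tissue (its top-quartile patch mass exceeds both
the uniform baseline and the untrained model's). Problem sizes throughout
the tests (image sizes 16–128, token counts ≤ 65, 200-image training sets)
were chosen as the smallest that still exercise every code path
meaningfully.

## Known limitations

* The full-size configuration (~92M parameters) is provided and counted but
  not trained here; the published clinical accuracies (Tables of the source
  study) require the external CE-MRI collection and GPU-scale training and
  are out of scope.
* Enhancement operates on single-channel images; RGB inputs are converted
  to luminance. DICOM/NIfTI volumes are out of scope.
* The augment-then-split order is faithful to the source but leaks
  correlated images across folds; a grouped split (twins share a fold) can
  be had by splitting before augmentation.
* PR curves sweep *scores*; with few distinct score values the curve is
  coarse.
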