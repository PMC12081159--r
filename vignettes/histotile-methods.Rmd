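---
title: "Methods: reliability-guided filtering and memory-cell tile classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability-guided filtering and memory-cell tile classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotile)
```

# Overview

`histotile` is a toolkit for tile-based analysis of prostate histopathology
images. It chains four stages:

1. **Reliability-guided restoration.** A degraded (low-resolution, noisy)
   image is upsampled and its pixels partitioned into *reliable* and
   *unreliable* by local max–min contrast; the unreliable pixels are then
   re-estimated by an ordered, confidence-weighted filter that propagates
   information inward from the reliable set.
2. **Correlogram descriptors.** The image is quantized into $m$ colors and
   summarized by its color histogram, correlogram and autocorrelogram —
   probabilities that particular colors co-occur at exact chessboard
   distances.
3. **Nonlocal patch-manifold spectrum.** All $s \times s$ patches of the
   luminance channel are treated as points in $\mathbb{R}^{s^2}$; a Gaussian
   diffusion kernel on this point cloud defines a graph Laplacian whose
   eigenbasis serves as a data-adaptive frequency basis ("graph
   frequencies") for contrast adjustment and for energy features.
4. **Memory-cell classification.** Per-tile feature vectors
   (autocorrelogram + low graph-frequency energies) are classified by an
   immune-inspired nearest-prototype scheme with a data-derived novelty
   threshold, and evaluated with confusion metrics and rank-statistic AUC.

Clinical prostate histopathology collections are rarely shareable, so the
package ships a seeded generator of tissue-like images; every stage of the
method is exercised and tested against that generator without any download.

# Restoration by ordered confidence propagation

## Reliability partition

The working scalar raster $D$ is the luminance (Rec. 601 weights) of the
guidance image $I$. A pixel is unreliable when
$\max_{W(x)} D - \min_{W(x)} D > \tau$ over the $(2r+1)^2$ window centered
on it. Windows are clipped at the border rather than padded, so no
fabricated values enter the decision. Defaults are $r = 1$ (the smallest
symmetric window) and $\tau = 0.1$ on the $[0,1]$ scale; both are exposed
because the right contrast threshold depends on stain intensity.

One-pixel ridges and other fine details legitimately produce large local
contrast. A first-order central-difference filter therefore restores to
reliable any pixel across which a directional derivative changes sign (a
zero crossing); refinement never demotes a reliable pixel.

## Propagation order and directions

Unreliable pixels are processed in increasing chessboard (8-neighbor)
distance $T$ to the nearest reliable pixel, computed by breadth-first
search; iteration $t$ processes exactly $\{x : T(x) = t\}$, so pixels
filtered at step $t$ are available to step $t+1$ and the filter terminates
after $\max T$ iterations with every pixel assigned. The propagation
direction $\nabla T$ is the unit central-difference gradient of $T$; where
it vanishes, the direction toward the nearest reliable pixel is used (ties
resolved in raster-scan order of the donors), which keeps the scheme fully
deterministic.

## Confidence and weights

Each pixel carries a confidence pair, one slot per propagation direction
$\pm\nabla T(x)$; reliable pixels hold $[1, 0]$. For an unreliable pixel,
each slot is the normalized, consistency-weighted average of the
already-processed 8-neighbors' aligned slots, decayed by one factor of
$a \in [0, 1)$ per propagation step:

$$C(x; \nabla_x) = \frac{a}{K_C} \sum_{y \in W(x)} B(x,y)\, G(x,y)\,
C(y; \nabla_y), \qquad K_C = \sum_{y \in W(x)} B(x,y)\, G(x,y).$$

$B(x,y) = \exp(-\gamma_I \lVert I_x - I_y \rVert^2)\,
\exp(-\gamma_D (D_x - D_y)^2)$ suppresses propagation across color or
intensity discontinuities; $G = \max(\cos \angle(\nabla_x, \nabla_y),
\delta)$ suppresses it across inconsistent boundary normals (orthogonal or
opposite directions floor at $\delta$). A neighbor contributes the slot
aligned with the consuming direction (sign of the dot product); reliable
neighbors contribute confidence 1 with no direction penalty, since no
boundary normal is defined on a reliable plateau.

Writing the decay as one factor of $a$ per step makes the cumulative decay
after $n$ steps exactly $a^n$: with $\gamma_I = \gamma_D = 0$ and
$\delta = 1$ every weight collapses and $C(x) = a^{T(x)}$, a pure
distance-decayed confidence. This reduction is enforced by test against an
independently coded distance-decay filter. The alternative reading — a
factor $a^{T(x)}$ applied on top of already-decayed neighbor confidences —
double-counts the decay ($a^{1+2+\dots+T}$) and breaks that reduction, so
it was rejected. Defaults follow the filter's design point $a = 0.8$,
$\gamma_I = 0.1^{-2} = 100$, $\gamma_D = 0.01^{-2} = 10^4$, $\delta = 0$;
the bandwidths are also readable from configuration because the exponent
notation admits a second reading ($0.1 \times 10^{-2}$).

## The ordered filter

At step $t$ every pixel with $T = t$ becomes the weighted mean of its
already-processed 8-neighbors with weights
$w = B(x,y)\, G(x,y)\, C(y; \text{toward } x)$. All weights are
nonnegative, so every filtered value is a convex combination of reliable
values reached through the propagation chain; reliable pixels are returned
bit-identical. Two numerical edge cases are handled explicitly:

* weight sums below $10^{-300}$ are treated as vanished (the Gaussian $B$
  underflows to subnormals for large working-value jumps, and the product
  $w \cdot v$ can then round to zero while $w$ itself does not); the pixel
  falls back to the unweighted mean of its processed neighbors, preserving
  the convex-combination property;
* if the reliability partition marks *no* pixel reliable, the pixel with
  the flattest window (first in raster order) seeds the propagation.

For RGB restoration the partition, ordering, confidence and the scalar
filter run on luminance; the color channels are then repainted with the
same weight structure using the fully filtered luminance as the working
raster. Initialization uses bilinear upsampling by default (bicubic is
available for the prototype map); both are separable, pixel-center aligned,
edge-clamped kernels implemented in the package so the two paths share
identical grid conventions.

# Correlogram features

Colors are quantized to $m$ colors — uniform per-channel binning when $m$
is a perfect cube (the default $m = 64 = 4^3$), otherwise seeded k-means.
With pixel distance measured in the $L_\infty$ norm, the correlogram entry
$\gamma_{ij}^{(k)}$ is the probability that a pixel at distance exactly
$k$ from a color-$c_i$ pixel has color $c_j$, estimated over all ordered
pairs on the distance-$k$ square ring; ring positions outside the image are
excluded from numerator and denominator alike, so borders introduce no
bias. The autocorrelogram keeps the same-color diagonal
$\alpha_i^{(k)} = \gamma_{ii}^{(k)}$, needing only $O(md)$ storage. The
default distance set $\{1, 3, 5, 7\}$ spans sub-gland to gland-scale
structure at the generator's magnification; larger $d$ raises cost
quadratically with little extra texture information at tile scale. The
implementation is verified exactly against an $O(n^4)$ all-pairs
enumeration on random images.

# Nonlocal patch graph and spectral features

Patches use reflect padding (mirrored about the border pixel, no edge
duplication) so every pixel owns a patch. The kernel
$W_{ij} = \exp(-\lVert R_i f - R_j f \rVert^2 / 2\sigma^2)$ uses
$\sigma$ = median pairwise patch distance over a seeded subsample of at
most 1000 pairs — scale-adaptive and, floored at $10^{-8}$, well defined
even on constant tiles. Full kernels over all $n^2$ patches are quadratic
in pixel count, so when the patch count exceeds `sample_cap` a seeded
uniform subsample of centers defines the graph; pixels off the graph are
untouched by spectral filtering. The Laplacian $L = D - W$ is decomposed
by a full symmetric eigensolve; eigenvalues are reported ascending with the
zero-frequency constant eigenvector first, and each eigenvector's sign is
fixed by making its first non-negligible entry positive so bases are
reproducible across runs.

Contrast adjustment projects the per-center intensity signal onto the first
`k_bands` eigenvectors, scales each coefficient by a per-band gain, and
adds back the unprojected residual; unit gains reproduce the input exactly
and boosting low bands raises large-scale contrast while leaving
high-frequency residual (noise) untouched. The normalized squared
projection coefficients are the *graph-frequency energies* used as
classifier features; a constant tile yields a pure zero-frequency spectrum
by construction.

# Tiles, features and the memory-cell classifier

Images are tiled row-major with configurable side and stride. The per-tile
feature vector concatenates the flattened autocorrelogram
($m \cdot |d|$ entries) with the first `k_bands` energies (16 by default,
enough to capture the smooth structure of a 64 px tile). Features are
min-max normalized per column using training-set statistics, stored in the
model so prediction applies the identical transform; after normalization
all distances are divided by $\sqrt{p}$ so they lie in $[0, 1]$.

Training presents examples in a seeded random order. The novelty threshold
is the mean pairwise affinity (normalized Euclidean distance) over all
training pairs. A candidate farther than the threshold from every
same-label cell founds a new memory cell; otherwise it stimulates its
nearest same-label cell and pulls it toward itself by step
$1/\text{stimulation}$ — a running mean over the candidates a cell has
absorbed, which is how a cell's receptive area grows. At capacity the
least-stimulated cell is evicted (ties: lowest index), except that the last
cell of a class is never evicted. Prediction returns the nearest cell's
label and the score $d_-/(d_+ + d_-)$ from the distances to the nearest
cell of each class: a value in $[0, 1]$, higher for more malignant-like
queries, 0.5 at equidistance. Heatmaps paint per-tile scores back into
image coordinates, averaging overlaps — a functional stand-in for CNN
activation maps, not a claim of equivalence.

AUC is computed by the Mann–Whitney rank statistic with midranks for ties,
and the ROC construction moves through tie blocks diagonally so trapezoidal
integration reproduces the rank AUC to $10^{-10}$; the two routes are
cross-checked in the tests. Stratified splitting allocates
$\lfloor n_c \cdot \text{fraction} \rfloor$ training items per class and
distributes the rounding remainder by largest fractional part.

# The synthetic study

The generator draws gland motifs as perturbed annuli: a hematoxylin-purple
epithelial ring around a near-white lumen on eosin-pink stroma, with the
boundary radius displaced by low-order sinusoids of amplitude
$(1 - \text{regularity}) \cdot r$. Benign-like tissue uses regularity 0.9
(round, well-separated glands), malignant-like 0.2 (irregular, fused
blobs). Gland radii are absolute (6–12 px), mimicking fixed magnification,
so tiles cut at any image size see the same morphology scale. Noise is
additive Gaussian (sd 8 on the 8-bit scale), clipped to $[0, 255]$;
per-image seeds are master seed + index, making every dataset
bit-reproducible.

The standard study conditions are 200 images per class at 64 px, factor-2
block degradation with noise sd 4, restoration with the default filter
parameters, and a 70/30 stratified split. Restoration is not cosmetic
here: quantization at 4 bins per channel is noise-sensitive, and skipping
the restoration stage drops test accuracy from ~0.93 to ~0.62 under
otherwise identical conditions — the filter is what makes the correlogram
features stable.

What the generator does *not* emulate: real H&E stain variability,
out-of-focus regions, tissue folds, nuclear detail, or whole-slide formats.
Passing tests therefore demonstrate that the pipeline recovers a known
morphological signal under controlled degradation — not clinical
performance. The headline clinical figures reported for this family of
methods were obtained on a private collection and are out of scope here.

# Problem sizes and numerical choices

* Per-image patch graphs in the pipeline use 512 sampled centers of the
  4096 available at 64 px. Spectral energies are noticeably undersampled at
  256 centers (end-to-end accuracy ~0.89) and stable at 512 (~0.95); the
  full graph would be two orders of magnitude more expensive for no
  measurable gain at this tile size. Standalone `nonlocal_kernel()` calls
  default to a 2048-center cap.
* Eigen-decompositions use the symmetric solver; reconstruction and
  orthonormality are test-enforced at $10^{-6}$/$10^{-8}$.
* All tie-breaks (nearest cell, eviction, donor pixels, remainder
  allocation) resolve to the lowest index, so every stage is deterministic
  under a fixed master seed; two runs with the same configuration produce
  byte-identical CSV/JSON artifacts.
* The heatmap localization check trains its model on 32 px tiles (one
  gland each, 150 per class) because the classification unit for heatmaps
  is the tile: a model trained on whole 64 px images scores 32 px windows
  near-uninformatively. Composite fixtures paste a 48 px malignant texture
  into a 96 px benign background.

# Known limitations

* The ordered filter is single-scale; heavily degraded inputs whose
  reliable set is sparse propagate over long chains and lose detail.
* Correlogram features discard orientation; tissues differing only in
  anisotropy are not separated.
* The memory-cell scheme fixes its novelty threshold from the training
  set once; it does not adapt during streaming use.
* Subsampled patch graphs leave off-graph pixels unchanged in
  `spectral_filter()`; for full-image contrast adjustment choose
  `sample_cap` at least the pixel count.

```{r example, eval = FALSE}
# the standard synthetic study end to end
res <- run_pipeline(pipeline_config())
print(res)
```
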