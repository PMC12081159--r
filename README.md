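# histotile

Tile-based analysis of prostate histopathology images: reliability-guided
restoration of degraded images, correlogram and patch-manifold spectral
texture descriptors, and an immune-inspired memory-cell classifier that
separates benign-like from malignant-like tissue and paints per-tile
malignancy heatmaps. Built for image-analysis researchers who need the full
pipeline — restoration → features → classification → evaluation — to be
reproducible and testable without access to clinical data: a seeded
generator of synthetic tissue images ships with the package.

## The method in brief

**Restoration.** After upsampling a degraded image, a pixel is *unreliable*
when the max–min range of its local window exceeds a threshold τ. Unreliable
pixels are re-estimated in increasing chessboard distance *T* to the
reliable set, each becoming a weighted mean of already-processed neighbors
with weights

  w(x,y) = B(x,y) · G(x,y) · C(y),
  B = exp(−γ_I‖I_x−I_y‖²) · exp(−γ_D(D_x−D_y)²),
  G = max(cos∠(∇T_x, ∇T_y), δ),

where the directional confidence C decays by a factor *a* per propagation
step (reliable pixels carry confidence [1, 0] and are never modified).
Defaults: a = 0.8, γ_I = 100, γ_D = 10⁴, δ = 0.

**Features.** Colors quantized to m = 64; the autocorrelogram
ac_i^(k) = Pr(color c_i at L∞ distance exactly k | c_i) is taken at
k ∈ {1, 3, 5, 7}, concatenated with the leading energies of the image's
signal in the eigenbasis of the nonlocal patch-graph Laplacian
L = D − W, W_ij = exp(−‖R_i f − R_j f‖² / 2σ²) ("graph frequencies").

**Classification.** Feature vectors are min-max normalized; a candidate
farther than the mean pairwise affinity from every same-label prototype
founds a new *memory cell*, otherwise it stimulates and shifts its nearest
cell (running mean). Prediction is nearest-cell, scored by
d₋/(d₊ + d₋); evaluation reports accuracy/precision/recall/F1, midrank AUC
and ROC points.

## Worked example

```r
library(histotile)

res <- run_pipeline(pipeline_config())   # 200 synthetic tiles/class, seed 42
print(res)
#> histotile pipeline run: 400 images (120 test)
#> Binary classification metrics (n = 120, positive = malignant)
#>   accuracy 0.9333  precision 0.9062  recall 0.9667  F1 0.9355  AUC 0.9658
#>   confusion: tp 58  fp 6  tn 54  fn 2
#>   memory cells: 11, similarity threshold 0.1010
```

The pipeline simulated 400 tissue images (benign: regular gland annuli;
malignant: irregular fused blobs), degraded each by factor-2 block
averaging plus noise, restored them with the ordered confidence filter,
extracted 272 features per image (256 autocorrelogram + 16 spectral
energies), and trained the memory-cell classifier on a stratified 70%.
Accuracy 0.9333 means 112 of the 120 held-out images were labeled
correctly; AUC 0.966 is the probability that a random malignant image
outscores a random benign one. Eleven prototypes sufficed because the
novelty threshold (mean pairwise affinity 0.101) absorbs most candidates
into existing cells.

Individual stages are ordinary functions:

```r
img  <- as_unit(generate_tissue_image(tissue_spec(seed = 7)))
low  <- as_unit(degrade_image(generate_tissue_image(tissue_spec(seed = 7)), 2, 4))
rest <- restore_image(low, 2)                       # $image, $mask, $order, $conf
q    <- quantize_colors(img, 64)
ac   <- autocorrelogram(color_correlogram(q, c(1, 3, 5, 7)))
g    <- spectral_basis(build_laplacian(nonlocal_kernel(
          extract_patches(luminance(img), 5))))
en   <- graph_frequency_energy(luminance(img), g, 16)
```

A command-line front end (`exec/histotile`) exposes the stages as
subcommands (`simulate`, `filter`, `features`, `spectra`, `train`,
`classify`, `evaluate`, `heatmap`, `run`) with `--config`/`--seed`/`--out`
flags.

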