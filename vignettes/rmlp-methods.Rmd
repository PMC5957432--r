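---
title: "Region mosaicking on Laplacian pyramids: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region mosaicking on Laplacian pyramids: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmlp)
```

## The problem

A microscope (or any high-magnification optic) has a shallow depth of field:
each exposure of a three-dimensional specimen is sharp only where the surface
crosses the current focal plane. A focus series — a stack of aligned frames
captured at stepped focal depths — contains a sharp version of every pixel
*somewhere* in the stack. Multi-focus fusion assembles those pieces into one
all-in-focus image.

The key physical observation this package builds on is that in-focus pixels
of one frame form **contiguous regions** (a level set of the specimen's depth
map), not scattered points. The classical pixel-level Laplacian-pyramid
fusion ignores this: it selects each transform coefficient independently, so
neighboring output pixels are routinely reconstructed from different frames,
which loses original detail and introduces color distortion. Region
mosaicking instead segments contiguous focus regions once, in the spatial
domain, and then copies *whole regions* from single source frames at every
pyramid scale.

## The pipeline

For a stack of $N$ aligned frames $I_1,\dots,I_N$:

1. **Focus measurement.** The modified Laplacian
   $\nabla^2_M I(x,y) = |2I - I_{x-1} - I_{x+1}| + |2I - I_{y-1} - I_{y+1}|$
   is summed over a $(2w{+}1)\times(2w{+}1)$ window, counting values at least
   $T$, giving the Sum-Modified-Laplacian (SML) focus map of each frame
   (`sml()`).
2. **Winner mask.** $M_0(i,j) = \arg\max_n \mathrm{SML}_n(i,j)$
   (`initial_mask()`).
3. **Density-based region growing (DBRG).** $M_0$ is noisy where all frames
   are defocused or textureless; `dbrg_segment()` refines it into contiguous
   regions (below).
4. **Pyramids.** Each frame is decomposed into a $K$-level Laplacian pyramid;
   the mask is decomposed into a $K$-level categorical mask pyramid by
   $2\times 2$ majority vote (`laplacian_pyramid()`, `mask_pyramid()`).
5. **Mosaicking.** At every level, each coefficient is *copied* from the
   pyramid of the frame its mask cell names — pure selection, no averaging
   (`mosaic_fuse()`, `fuse_top_layer()`); the fused pyramid is collapsed by
   `pyr_reconstruct()`.

RGB stacks are fused per channel by default; a shared mask computed from the
Rec. 601 luminance is available (`color_mode = "shared-mask"`) when identical
region geometry across channels matters more than per-channel optimality.

## DBRG in detail

For a pixel $p$ and radius $R$, the label densities are the label frequencies
inside the discrete disk $\{(i,j): (i-x)^2+(j-y)^2 \le R^2\}$ clipped to the
image. A pixel whose maximum density is **strictly** above $0.5$ is a seed
with that majority label. Clusters start from seeds (scanned in row-major
order), grow by absorbing unlabeled pixels of the cluster's label within
distance $R$ of a cluster seed, and extend transitively only through absorbed
pixels that are themselves seeds. Pixels never reached — isolated noise and
smooth-region pixels — take the label of the nearest labeled pixel in
Chebyshev ("checker-board") distance, computed by simultaneous 8-connected
expansion from all labeled pixels; equal distances resolve to the smallest
label.

Design choices worth recording:

* **Density normalization.** Densities divide by the *cell count* of the
  clipped discrete disk, not by the continuous area $\pi R^2$. With area
  normalization a uniformly labeled neighborhood near an image corner would
  score about $0.25$ and produce no seeds, making the $0.5$ threshold
  unusable; with cell-count normalization the threshold has its intended
  strict-majority meaning, and the comparison `2*count > disk_size` is exact
  integer arithmetic.
* **A consequence on adversarial masks.** The discrete $R=8$ disk has 197
  cells, 101 of them sharing the center's parity. On a perfect
  two-color checkerboard the majority density is therefore
  $101/197 \approx 0.513 > 0.5$: every pixel is a seed for its own parity
  class. Strict majority over an odd cell count can never tie; "no seeds"
  situations arise from genuinely mixed neighborhoods, not from balanced
  ones.
* **Determinism.** All tie-breaks (argmax of SML, of densities, of majority
  votes; equal Chebyshev distances) resolve to the smallest source index, and
  seeds are visited in row-major order, so segmentation and fusion are fully
  deterministic functions of their inputs.
* **No-seed fallback.** If a mask has no seeds at all (possible when $R$
  dwarfs every region), the initial mask is returned unchanged with a
  warning; the algorithm's leftover-assignment step is undefined without at
  least one labeled pixel.
* **Radius default.** $R = \max(4, \mathrm{round}(8 \cdot \min(H,W)/480))$:
  radius 8 is the recommended value for $720\times480$ frames and should
  scale with image size. $R$ must exceed the label-noise grain but stay well
  below the region width; the tests' 256-pixel stripes use $R=8$.
* **Implementation note.** Disk counting decomposes the disk into per-row
  horizontal box filters applied as banded-matrix products, so all densities
  are exact integer counts at BLAS speed; cluster growth dilates small
  frontiers by coordinate arithmetic and large ones through the same
  box-filter path.

## Pyramids

The generating kernel is the standard 5-tap binomial $(1,4,6,4,1)/16$
(separable, the $a=0.375$ family), with **reflect** (mirror-without-edge-repeat)
borders: reflection preserves constants exactly and avoids the edge
darkening zero padding would cause. Level sizes follow the ceil-halving
chain, so odd dimensions are handled exactly and `pyr_expand()` crops to the
precise target shape; `reconstruct(decompose(I)) = I` holds to floating-point
accuracy for every image and depth, which the tests assert at $10^{-6}$.

Depth defaults to $K = 6$ (capped by image size so every level keeps both
dimensions $\ge 2$), the depth reported as optimal alongside 7 for
$720\times480$ material.

**Top-level rule.** The literal per-level formulation recomputes the top
mask as the argmax of SML on the base images, while the mask-pyramid
formulation requires every level to be a down-sampled copy of the one mask.
The down-sampled copy is the default (`top_rule = "mask"`): it keeps regions
"similar figures" across levels, which is the point of region mosaicking.
The literal variant stays available as `top_rule = "sml"` for comparison.

**Baseline.** `lp_fuse()` implements the classical pixel-level rule —
band-pass coefficients by largest absolute value, base level by averaging
(the common convention; the region method replaces the base average with
mask selection).

## Metrics

`rmse()` is the plain root-mean-square error. `ssim()` uses the standard
stabilized form with $C_1 = (K_1 L)^2$, $C_2 = (K_2 L)^2$,
$K_1 = 0.01, K_2 = 0.03, L = 255$, an $11\times11$ Gaussian window with
$\sigma = 1.5$, reflect borders, and averages the per-pixel SSIM map.
(Unsquared stabilizers would be dimensionally inconsistent with the variance
terms; the squared form is the one defined by the SSIM literature.) Color
images are scored per channel and averaged. `ssim(x, x)` is exactly 1 by
construction.

## The synthetic generator

`make_ground_truth()` (band-limited noise, concentric rings, or multi-octave
"natural" texture), `make_depth_map()` (row-ramp stripes, radial bowls, or
smoothed-noise blobs, all with contiguous level sets) and `render_stack()`
emulate a focus series: frame $n$ focuses at depth $d_n = (n-1)/(N-1)$ and
each pixel is blurred with $\sigma(x,y) = \sigma_{\max}\,|{\rm depth}(x,y) - d_n|$,
plus optional i.i.d. Gaussian noise. The spatially varying blur is
approximated by quantizing $\sigma$ into at most 16 uniform bands per frame,
blurring once per band, and compositing; each band uses its *lower* edge so
exactly-in-focus pixels stay bit-identical to the truth. Everything is
bit-reproducible per seed, and the generators restore the caller's RNG
state.

Default study geometry, chosen to keep the full test suite in seconds-scale
while leaving each of the 8 stripes (32 rows) much wider than the default
disk radius: $256\times256$ pixels, $N=8$ frames, $\sigma_{\max}=4$,
noise levels 0 and 2.

What the generator does **not** emulate: optical point-spread functions
(defocus disks, diffraction rings), depth discontinuities with occlusion,
misregistration between frames, or signal-dependent sensor noise. Passing
tests therefore demonstrate the algorithmic contracts (selection provenance,
mask recovery, reconstruction exactness, metric ordering) — not performance
on optically realistic material.

## Observed behavior on the synthetic conditions, and limitations

Two honest caveats, both visible in the package's own test runs:

* **Pyramid depth barely matters on clean synthetic stacks.** With a
  near-perfect DBRG mask and stripes whose best frame is near-exact, fused
  RMSE is essentially flat in $K$ and slightly *favors shallow* pyramids
  (hard selection is already near-optimal; extra levels only widen blending
  across stripe boundaries). The reported advantage of 6–7 levels belongs to
  real stacks with imperfect masks, where coarse levels heal fine-level
  selection errors. The deep-vs-shallow acceptance expectation is left
  failing rather than tuned.
* **Hard selection keeps the noise it selects.** Region mosaicking copies
  pixels from single frames, so additive noise of standard deviation
  $\sigma$ passes through to the output almost unattenuated, and the
  *difference* metric noisy-minus-clean RMSE is close to $\sigma$. The
  pixel-level baseline shows a smaller difference only because its large
  clean error absorbs the noise in quadrature; comparing effective added
  noise $\sqrt{\mathrm{RMSE}^2_{\rm noisy} - \mathrm{RMSE}^2_{\rm clean}}$
  (reported by `scripts/acceptance.R`) shows choose-max *amplifies* noise
  while mosaicking does not. The degradation-difference acceptance
  expectation is likewise left failing, with both formulations reported.

Further limitations: frames must be pre-aligned (no registration is
performed); moving objects and exposure changes are out of scope; masks with
more than 255 sources cannot be exported as 8-bit PNG; and no feathering is
applied in transition zones — smoothing across region boundaries arises only
from the reconstruction itself.

## Reproducing a fusion

```{r, eval = FALSE}
truth <- make_ground_truth(c(256, 256), kind = "texture", seed = 7)
depth <- make_depth_map(c(256, 256), kind = "stripes")
stack <- render_stack(truth, depth, n_frames = 8, sigma_max = 4, seed = 7)
res <- rmlp_fuse(stack$frames, R = 8, K = 6)
c(rmse(res$fused, truth), ssim(res$fused, truth))
```

The same pipeline is scriptable from a shell via `inst/cli/rmlp.R`
(`simulate`, `fuse`, `evaluate` subcommands) with JSON sidecars recording
every resolved parameter, so a run is reproducible from its outputs alone.
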