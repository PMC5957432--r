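# rmlp — multi-focus image fusion via region mosaicking on Laplacian pyramids

High-magnification optics capture each exposure sharp only where the
specimen crosses the focal plane. Given a pre-aligned focus series
(a *multi-focus stack*), **rmlp** produces a single all-in-focus image.
It is aimed at microscopy and macro work where the in-focus pixels of each
frame form contiguous regions, and at anyone who needs the intermediate
products — focus maps, focus-region masks, pyramid decompositions — as
first-class objects.

## Method

For frames $I_1,\dots,I_N$:

1. **Focus measure** — Sum-Modified-Laplacian per pixel:
   $\mathrm{SML}(i,j)=\sum_{|x-i|\le w,\,|y-j|\le w}\nabla^2_M I(x,y)$ for
   $\nabla^2_M I \ge T$, with
   $\nabla^2_M I = |2I - I_{x-1} - I_{x+1}| + |2I - I_{y-1} - I_{y+1}|$.
2. **Winner mask** — $M_0(i,j)=\arg\max_n \mathrm{SML}_n(i,j)$.
3. **Density-based region growing** — pixels whose radius-$R$ disk
   neighborhood has a strict label majority seed clusters that grow
   transitively through density-connected seeds; leftovers take the nearest
   label in Chebyshev distance. The result is a mask of contiguous focus
   regions.
4. **Region mosaicking** — each frame's Laplacian pyramid ($K$ levels,
   5-tap binomial kernel) is supervised by a mask pyramid (categorical
   $2\times2$ majority downsampling of the DBRG mask): every coefficient at
   every scale is *copied* from the single frame its mask cell names, and the
   fused pyramid is collapsed to the output image.

Because corresponding regions are similar figures across mask levels, almost
every output pixel is reconstructed entirely from one source frame, which
preserves original detail and avoids the color distortion of pixel-level
choose-max fusion (`lp_fuse()`, included as the classical baseline).
`rmse()` and `ssim()` score results against a ground-truth reference, and a
synthetic generator (`make_ground_truth()`, `make_depth_map()`,
`render_stack()`) builds focus stacks with known truth for validation.

## Worked example

```r
library(rmlp)

truth <- make_ground_truth(c(256, 256), kind = "texture", seed = 7)
depth <- make_depth_map(c(256, 256), kind = "stripes")
stack <- render_stack(truth, depth, n_frames = 8, sigma_max = 4, seed = 7)
res   <- rmlp_fuse(stack$frames, R = 8, K = 6)
res
#> rmlp fusion result: 256 x 256 image
#>   parameters: w = 1, T = 0, R = 8, K = 6, per-channel, top = mask
#>   mask: 8 source labels over 256 x 256 pixels

round(range(sapply(stack$frames, rmse, reference = truth)), 2)
#> [1]  8.09 15.33

baseline <- pyr_reconstruct(lp_fuse(lapply(stack$frames, laplacian_pyramid, K = 6)))
c(rmlp = rmse(res$fused, truth), lp_pixel = rmse(baseline, truth))
#>       rmlp   lp_pixel
#> 0.01635101 1.81981379
c(rmlp = ssim(res$fused, truth), lp_pixel = ssim(baseline, truth))
#>      rmlp  lp_pixel
#> 0.9999998 0.9970558

mean(res$mask == stack$true_mask)
#> [1] 0.9601135
```

Every single frame is 8–15 gray levels away from the truth (RMSE on the
0–255 scale); region mosaicking lands within 0.02 gray levels — two orders
of magnitude below the pixel-level Laplacian baseline — and its focus-region
mask names the truly sharpest frame on 96% of pixels (disagreements sit on
stripe boundaries where neighboring frames are equally sharp).

## Command line

```sh
Rscript inst/cli/rmlp.R simulate --out stackdir --shape 256x256 --frames 8 --sigma-max 4 --seed 1
Rscript inst/cli/rmlp.R fuse --input stackdir/frames --output fused.png --radius 8 --levels 6 --save-mask
Rscript inst/cli/rmlp.R evaluate --test fused.png --ref stackdir/truth.png
```

`fuse` writes a JSON sidecar with all resolved parameters next to the output;
`evaluate` prints `{"rmse": ..., "ssim": ...}`.

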