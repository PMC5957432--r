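# Synthetic multi-focus stacks with known ground truth. The generator
# emulates microscope focus series in which each frame is sharp on one
# contiguous depth band (stripe-shaped for elongated objects, radial or
# blob-shaped for rounded ones) and increasingly defocused away from it.

rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(array(lo, dim = dim(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L]) * (hi - lo) + lo
}

#' Generate an all-in-focus ground-truth image
#'
#' Deterministic per seed. Kinds: `"texture"` is band-limited Gaussian noise
#' (sharp detail everywhere, so the focus measure discriminates at every
#' pixel); `"rings"` is a concentric-ring intensity pattern with added fine
#' texture, evoking machined circular objects; `"natural"` sums noise octaves
#' at several scales for a 1/f-like spectrum.
#'
#' @param dim image dimensions `c(H, W)`, at least 16 x 16.
#' @param kind `"texture"`, `"rings"` or `"natural"`.
#' @param seed RNG seed.
#' @return numeric matrix with values in `[0, 255]`.
#' @export
make_ground_truth <- function(dim, kind = c("texture", "rings", "natural"),
                              seed = 1L) {
  kind <- match.arg(kind)
  dim <- as.integer(dim[1:2])
  if (any(dim < 16L))
    stop("ground-truth images must be at least 16 x 16", call. = FALSE)
  H <- dim[1L]; W <- dim[2L]
  with_seed(seed, {
    switch(kind,
      texture = {
        z <- blur_image(matrix(stats::rnorm(H * W), H, W), 1.5)
        rescale_range(z, 10, 245)
      },
      rings = {
        r <- sqrt(outer((seq_len(H) - (H + 1) / 2)^2,
                        (seq_len(W) - (W + 1) / 2)^2, `+`))
        base <- 127.5 * (1 + sin(2 * pi * r / 16))
        fine <- blur_image(matrix(stats::rnorm(H * W), H, W), 1)
        clamp(base + rescale_range(fine, -20, 20), 0, 255)
      },
      natural = {
        acc <- matrix(0, H, W)
        for (o in 0:3)
          acc <- acc + blur_image(matrix(stats::rnorm(H * W), H, W), 2^o) / 2^o
        rescale_range(acc, 10, 245)
      })
  })
}

#' Generate a depth map with contiguous level sets
#'
#' Values in `[0, 1]`. `"stripes"` ramps linearly down the rows
#' (`depth = (row - 1) / (H - 1)`, constant per row), mirroring focus series
#' in which each frame is sharp on one horizontal stripe; `"radial"` grows
#' with distance from the image center; `"blobs"` is smoothed noise, giving
#' irregular but contiguous depth regions.
#'
#' @param dim image dimensions `c(H, W)`.
#' @param kind `"stripes"`, `"radial"` or `"blobs"`.
#' @param seed RNG seed (used by `"blobs"` only).
#' @return numeric matrix with values in `[0, 1]`.
#' @export
make_depth_map <- function(dim, kind = c("stripes", "radial", "blobs"),
                           seed = 1L) {
  kind <- match.arg(kind)
  dim <- as.integer(dim[1:2])
  if (any(dim < 2L)) stop("degenerate depth-map shape", call. = FALSE)
  H <- dim[1L]; W <- dim[2L]
  switch(kind,
    stripes = matrix(rep((seq_len(H) - 1) / (H - 1), W), H, W),
    radial = {
      r <- sqrt(outer((seq_len(H) - (H + 1) / 2)^2,
                      (seq_len(W) - (W + 1) / 2)^2, `+`))
      r / max(r)
    },
    blobs = with_seed(seed, {
      z <- blur_image(matrix(stats::rnorm(H * W), H, W), min(H, W) / 8)
      rescale_range(z, 0, 1)
    }))
}

blur_any <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (is_color(img)) {
    out <- img
    for (ch in seq_len(dim(img)[3L])) out[, , ch] <- blur_image(img[, , ch], sigma)
    out
  } else {
    blur_image(img, sigma)
  }
}

#' Render a multi-focus stack from a ground truth and a depth map
#'
#' Frame `n` focuses at depth `d_n = (n-1)/(N-1)`; each pixel is defocused
#' with Gaussian blur of strength `sigma_max * |depth - d_n|`. The spatially
#' varying blur is approximated by quantizing the per-frame blur strengths
#' into at most `max_bands` uniform bands (each band blurred with its lower
#' edge, so exactly-in-focus pixels stay unblurred) and compositing.
#' Optionally adds i.i.d. zero-mean Gaussian noise per frame. Bit-identical
#' for a fixed seed.
#'
#' @param truth ground-truth image (matrix or H x W x 3 array), range
#'   `[0, 255]`.
#' @param depth depth map in `[0, 1]`, same H x W.
#' @param n_frames number of frames N (>= 2).
#' @param sigma_max blur at unit focus distance, in pixels (>= 0; 0 renders
#'   every frame equal to the truth).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (intensity units; >= 0).
#' @param seed RNG seed for the noise.
#' @param max_bands maximum number of blur-quantization bands (default 16).
#' @return an object of class `"synthetic_stack"`: list with `ground_truth`,
#'   `depth_map`, `frames` (list of N images), `true_mask` (label matrix,
#'   `argmin_n |depth - d_n|`, smallest n on ties) and `params`.
#' @export
render_stack <- function(truth, depth, n_frames = 8L, sigma_max = 4,
                         noise_sd = 0, seed = 1L, max_bands = 16L) {
  if (!is.matrix(depth) || any(depth < 0) || any(depth > 1))
    stop("`depth` must be a matrix with values in [0, 1]", call. = FALSE)
  hw_truth <- if (is_color(truth)) dim(truth)[1:2] else dim(truth)
  if (!identical(as.integer(hw_truth), as.integer(dim(depth))))
    stop("`truth` and `depth` shapes differ", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  if (sigma_max < 0 || noise_sd < 0)
    stop("`sigma_max` and `noise_sd` must be non-negative", call. = FALSE)
  max_bands <- max(1L, as.integer(max_bands))

  H <- nrow(depth); W <- ncol(depth)
  d <- (seq_len(n_frames) - 1) / (n_frames - 1)

  frames <- vector("list", n_frames)
  for (n in seq_len(n_frames)) {
    smap <- sigma_max * abs(depth - d[n])
    if (sigma_max == 0) {
      frames[[n]] <- truth
      next
    }
    edges <- seq(0, sigma_max, length.out = max_bands + 1L)
    band <- findInterval(smap, edges, rightmost.closed = TRUE)
    band <- clamp(band, 1L, max_bands)
    frame <- if (is_color(truth)) array(0, dim = dim(truth)) else matrix(0, H, W)
    for (b in sort(unique(as.vector(band)))) {
      sel <- band == b
      blurred <- blur_any(truth, edges[b])
      if (is_color(truth)) {
        for (ch in seq_len(dim(truth)[3L])) {
          pl <- frame[, , ch]; pl[sel] <- blurred[, , ch][sel]
          frame[, , ch] <- pl
        }
      } else {
        frame[sel] <- blurred[sel]
      }
    }
    frames[[n]] <- frame
  }

  if (noise_sd > 0) {
    frames <- with_seed(seed, lapply(frames, function(f)
      f + stats::rnorm(length(f), sd = noise_sd)))
  }

  bestd <- abs(depth - d[1L])
  true_mask <- matrix(1L, H, W)
  for (n in seq_len(n_frames)[-1L]) {
    dn <- abs(depth - d[n])
    upd <- dn < bestd              # strict: ties keep the smaller frame
    true_mask[upd] <- n
    bestd[upd] <- dn[upd]
  }
  attr(true_mask, "n_sources") <- n_frames

  structure(list(ground_truth = truth, depth_map = depth, frames = frames,
                 true_mask = true_mask,
                 params = list(n_frames = n_frames, sigma_max = sigma_max,
                               noise_sd = noise_sd, seed = as.integer(seed),
                               max_bands = max_bands)),
            class = "synthetic_stack")
}

#' @export
print.synthetic_stack <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "synthetic multi-focus stack: %d frames of %s, sigma_max = %g, noise_sd = %g, seed = %d\n",
    p$n_frames, paste(dim(x$depth_map), collapse = " x "), p$sigma_max,
    p$noise_sd, p$seed))
  invisible(x)
}
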