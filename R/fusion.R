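# Region mosaicking on Laplacian pyramids: the focus-region mask is
# decomposed into a categorical mask pyramid that supervises, at every
# pyramid level, which source each coefficient is copied from. Because the
# mask levels are down-sampled copies of one mask, corresponding regions are
# similar figures across levels and almost every output pixel is
# reconstructed from a single source image.

# Per-label cell counts over ceil-halving 2x2 blocks.
block_count <- function(ind) {
  H <- nrow(ind); W <- ncol(ind)
  m <- ceiling(H / 2); w2 <- ceiling(W / 2)
  oddr <- seq.int(1L, H, 2L); oddc <- seq.int(1L, W, 2L)
  out <- ind[oddr, oddc, drop = FALSE]
  nr <- H %/% 2L; nc <- W %/% 2L
  if (nr > 0L) {
    evenr <- seq.int(2L, H, 2L)
    out[seq_len(nr), ] <- out[seq_len(nr), ] + ind[evenr, oddc, drop = FALSE]
  }
  if (nc > 0L) {
    evenc <- seq.int(2L, W, 2L)
    out[, seq_len(nc)] <- out[, seq_len(nc)] + ind[oddr, evenc, drop = FALSE]
  }
  if (nr > 0L && nc > 0L) {
    out[seq_len(nr), seq_len(nc)] <-
      out[seq_len(nr), seq_len(nc)] + ind[evenr, evenc, drop = FALSE]
  }
  stopifnot(nrow(out) == m, ncol(out) == w2)
  out
}

#' Mask pyramid by 2 x 2 majority vote
#'
#' Down-samples a label mask level by level: each coarse cell takes the
#' majority label of its (up to) 2 x 2 block of finer cells, smallest label
#' on ties. Labels are categorical, so majority vote plays the role the
#' Gaussian filter plays for intensities. Level 1 is the input mask; level
#' shapes follow the ceil-halving chain of the image pyramids.
#'
#' @param mask integer label matrix.
#' @param K number of levels, matching the Laplacian pyramids' depth.
#' @param n_sources number of labels `N`.
#' @return list of `K` integer matrices with class `"mask_pyramid"`.
#' @export
mask_pyramid <- function(mask, K, n_sources = NULL) {
  n <- n_sources_of(mask, n_sources)
  assert_mask(mask, n)
  K <- as.integer(K)
  kmax <- max_levels(dim(mask))
  if (K < 2L) stop("`K` must be >= 2", call. = FALSE)
  if (K > kmax)
    stop(sprintf("K = %d too deep for a %s mask; maximum feasible K is %d",
                 K, paste(dim(mask), collapse = "x"), kmax), call. = FALSE)
  levels <- vector("list", K)
  levels[[1L]] <- mask
  for (k in seq_len(K - 1L)) {
    cur <- levels[[k]]
    best <- block_count((cur == 1L) + 0)
    lab <- matrix(1L, nrow(best), ncol(best))
    for (lv in seq_len(n)[-1L]) {
      cnt <- block_count((cur == lv) + 0)
      upd <- cnt > best           # strict: ties keep the smaller label
      lab[upd] <- as.integer(lv)
      best[upd] <- cnt[upd]
    }
    attr(lab, "n_sources") <- n
    levels[[k + 1L]] <- lab
  }
  attr(levels[[1L]], "n_sources") <- n
  structure(levels, class = "mask_pyramid")
}

#' Region-mosaicking fusion of Laplacian pyramids
#'
#' Pure per-cell selection: at every level `k`, the fused coefficient at
#' `(i,j)` is copied from the Laplacian pyramid of the source named by mask
#' level `k` at `(i,j)` -- no arithmetic mixing. The base (last) level is
#' selected the same way from the Gaussian bases.
#'
#' @param lps list of `"laplacian_pyramid"` objects, one per source.
#' @param masks a `"mask_pyramid"` of the same depth and level shapes.
#' @return a fused `"laplacian_pyramid"`.
#' @export
mosaic_fuse <- function(lps, masks) {
  if (!is.list(lps) || length(lps) < 1L)
    stop("`lps` must be a non-empty list of Laplacian pyramids", call. = FALSE)
  K <- length(lps[[1L]])
  if (length(masks) != K)
    stop("mask pyramid depth differs from the Laplacian pyramids'",
         call. = FALSE)
  N <- length(lps)
  fused <- vector("list", K)
  for (k in seq_len(K)) {
    m <- masks[[k]]
    assert_same_shape(lps[[1L]][[k]], m, sprintf("level %d", k))
    if (max(m) > N)
      stop(sprintf("mask level %d names source %d but only %d sources given",
                   k, max(m), N), call. = FALSE)
    acc <- matrix(0, nrow(m), ncol(m))
    for (n in seq_len(N)) {
      sel <- m == n
      if (any(sel)) acc[sel] <- lps[[n]][[k]][sel]
    }
    fused[[k]] <- acc
  }
  structure(fused, class = "laplacian_pyramid")
}

#' Fuse the top (base) pyramid level under a label mask
#'
#' `F(i,j)` is the Gaussian base of the source named by `top_mask(i,j)`.
#'
#' @param gaussian_bases list of base-level matrices, one per source.
#' @param top_mask integer label matrix of the same shape.
#' @return numeric matrix.
#' @export
fuse_top_layer <- function(gaussian_bases, top_mask) {
  N <- length(gaussian_bases)
  if (N < 1L) stop("no base images given", call. = FALSE)
  assert_same_shape(gaussian_bases[[1L]], top_mask, "base and mask")
  if (max(top_mask) > N)
    stop(sprintf("mask names source %d but only %d sources given",
                 max(top_mask), N), call. = FALSE)
  out <- matrix(0, nrow(top_mask), ncol(top_mask))
  for (n in seq_len(N)) {
    sel <- top_mask == n
    if (any(sel)) out[sel] <- gaussian_bases[[n]][sel]
  }
  out
}

rmlp_fuse_gray <- function(stack, w, threshold, R, K, top_rule, mask = NULL) {
  N <- length(stack)
  lapply(stack, assert_image, arg = "stack[[i]]")
  for (n in seq_len(N)) assert_same_shape(stack[[1L]], stack[[n]], "stack images")
  H <- nrow(stack[[1L]]); W <- ncol(stack[[1L]])
  K <- as.integer(min(K, max_levels(c(H, W))))
  if (is.null(mask)) {
    maps <- lapply(stack, sml, w = w, threshold = threshold)
    m0 <- initial_mask(maps)
    mask <- dbrg_segment(m0, R = R, n_sources = N)
  } else {
    assert_mask(mask, N)
  }
  lps <- lapply(stack, laplacian_pyramid, K = K)
  mpyr <- mask_pyramid(mask, K, n_sources = N)
  fused_lp <- mosaic_fuse(lps, mpyr)
  bases <- lapply(lps, `[[`, K)
  if (top_rule == "sml") {
    top_mask <- initial_mask(lapply(bases, sml, w = w, threshold = threshold))
  } else {
    top_mask <- mpyr[[K]]
  }
  fused_lp[[K]] <- fuse_top_layer(bases, top_mask)
  list(fused = pyr_reconstruct(fused_lp), mask = mask, K = K)
}

#' Fuse a multi-focus image stack by region mosaicking on Laplacian pyramids
#'
#' Full pipeline: per-source SML focus maps ([sml()]), pixel-level winner
#' mask ([initial_mask()]), density-based region growing ([dbrg_segment()]),
#' per-source Laplacian pyramids, mask pyramid ([mask_pyramid()]),
#' region-mosaicking selection ([mosaic_fuse()], [fuse_top_layer()]) and
#' reconstruction ([pyr_reconstruct()]). Deterministic for fixed inputs and
#' parameters.
#'
#' RGB stacks (H x W x 3 arrays) are fused per channel by default; with
#' `color_mode = "shared-mask"` one mask is computed from the Rec. 601
#' luminance and applied to all three channels.
#'
#' @param stack list of N >= 2 aligned images of identical shape: numeric
#'   matrices (grayscale) or H x W x 3 arrays (RGB), nominal range
#'   `[0, 255]`. With N = 1 the single image is returned with a warning.
#' @param w SML window half-width (default 1, a 3 x 3 window).
#' @param threshold SML discrimination threshold `T` (default 0).
#' @param R DBRG disk radius; default [default_radius()] of the image size.
#' @param K pyramid depth; default 6, capped at [max_levels()].
#' @param color_mode `"per-channel"` (default) or `"shared-mask"`.
#' @param top_rule how the base level is selected: `"mask"` (default, the
#'   down-sampled mask pyramid's top level, keeping regions consistent across
#'   levels) or `"sml"` (argmax of SML recomputed on the base images).
#' @param mask optional precomputed label mask (integer matrix with labels in
#'   `1..N`); when given, focus measurement and segmentation are skipped and
#'   the mask supervises the fusion directly (applied to all channels of a
#'   color stack).
#' @return an object of class `"rmlp_result"`: list with `fused` (matrix or
#'   H x W x 3 array), `mask` (label matrix, or list of three for per-channel
#'   color fusion), and `params`.
#' @export
#' @examples
#' truth <- make_ground_truth(c(64, 64), "texture", seed = 1)
#' depth <- make_depth_map(c(64, 64), "stripes")
#' st <- render_stack(truth, depth, n_frames = 4, sigma_max = 3, seed = 1)
#' res <- rmlp_fuse(st$frames, R = 4, K = 4)
#' rmse(res$fused, truth) < min(sapply(st$frames, rmse, truth))
rmlp_fuse <- function(stack, w = 1L, threshold = 0, R = NULL, K = 6L,
                      color_mode = c("per-channel", "shared-mask"),
                      top_rule = c("mask", "sml"), mask = NULL) {
  color_mode <- match.arg(color_mode)
  top_rule <- match.arg(top_rule)
  if (!is.list(stack) || length(stack) < 1L)
    stop("`stack` must be a non-empty list of images", call. = FALSE)
  N <- length(stack)
  color <- is_color(stack[[1L]])
  if (color) {
    for (im in stack) {
      if (!is_color(im) || dim(im)[3L] != 3L)
        stop("color stacks must consist of H x W x 3 arrays", call. = FALSE)
      assert_same_shape(stack[[1L]], im, "stack images")
    }
  }
  params <- list(w = w, threshold = threshold, R = R, K = K,
                 color_mode = color_mode, top_rule = top_rule)
  if (N == 1L) {
    warning("stack has a single image; returning a copy")
    return(structure(list(fused = stack[[1L]], mask = NULL, params = params),
                     class = "rmlp_result"))
  }
  if (!color) {
    g <- rmlp_fuse_gray(stack, w, threshold, R, K, top_rule, mask = mask)
    params$K <- g$K
    return(structure(list(fused = g$fused, mask = g$mask, params = params),
                     class = "rmlp_result"))
  }
  channel <- function(ch) lapply(stack, function(a) a[, , ch])
  if (is.null(mask) && color_mode == "shared-mask") {
    lum <- lapply(stack, function(a)
      0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L])
    maps <- lapply(lum, sml, w = w, threshold = threshold)
    mask <- dbrg_segment(initial_mask(maps), R = R, n_sources = N)
  }
  if (!is.null(mask)) {
    per <- lapply(1:3, function(ch)
      rmlp_fuse_gray(channel(ch), w, threshold, R, K, top_rule, mask = mask))
    masks <- mask
  } else {
    per <- lapply(1:3, function(ch)
      rmlp_fuse_gray(channel(ch), w, threshold, R, K, top_rule))
    masks <- lapply(per, `[[`, "mask")
  }
  H <- dim(stack[[1L]])[1L]; W <- dim(stack[[1L]])[2L]
  fused <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) fused[, , ch] <- per[[ch]]$fused
  params$K <- per[[1L]]$K
  structure(list(fused = fused, mask = masks, params = params),
            class = "rmlp_result")
}

#' @export
print.rmlp_result <- function(x, ...) {
  d <- dim(x$fused)
  cat(sprintf("rmlp fusion result: %s image\n",
              paste(d, collapse = " x ")))
  p <- x$params
  cat(sprintf("  parameters: w = %s, T = %s, R = %s, K = %s, %s, top = %s\n",
              p$w, p$threshold, p$R %||% "auto", p$K, p$color_mode,
              p$top_rule))
  if (!is.null(x$mask)) {
    nm <- if (is.list(x$mask)) x$mask[[1L]] else x$mask
    cat(sprintf("  mask: %d source labels over %s pixels\n",
                n_sources_of(nm), paste(dim(nm), collapse = " x ")))
  }
  invisible(x)
}
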