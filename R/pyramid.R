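# Gaussian and Laplacian pyramids (Burt-Adelson 5-tap kernel, reflective
# borders, ceil-halving level sizes) and the classical pixel-level
# Laplacian-pyramid fusion baseline.

#' Maximum feasible pyramid depth for an image size
#'
#' Largest `K` such that every level of the ceil-halving chain keeps both
#' dimensions at least 2.
#'
#' @param dim image dimensions `c(H, W)`.
#' @return integer `K >= 1`.
#' @export
max_levels <- function(dim) {
  d <- as.integer(dim[1:2])
  K <- 1L
  while (all(ceiling(d / 2) >= 2L)) {
    d <- ceiling(d / 2)
    K <- K + 1L
  }
  K
}

#' REDUCE: filter and decimate one pyramid level
#'
#' Separable 5-tap binomial filtering (`(1,4,6,4,1)/16` on each axis) with
#' reflective borders, sampled at even grid positions; the output has shape
#' `(ceil(H/2), ceil(W/2))`. Constants are preserved exactly.
#'
#' @param img numeric matrix, at least 2 x 2.
#' @return numeric matrix of half linear size.
#' @export
pyr_reduce <- function(img) {
  assert_image(img)
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop("image must be at least 2 x 2 to reduce", call. = FALSE)
  reduce_matrix(nrow(img)) %*% img %*% t(reduce_matrix(ncol(img)))
}

#' EXPAND: upsample a pyramid level to a target shape
#'
#' Zero-interleaved upsampling followed by filtering with the doubled 5-tap
#' binomial kernel on each axis; `target_dim` must be a shape whose
#' ceil-halving gives `dim(img)`. Constants expand to the same constant.
#'
#' @param img numeric matrix (the coarser level).
#' @param target_dim integer vector `c(H, W)` of the finer level.
#' @return numeric matrix of shape `target_dim`.
#' @export
pyr_expand <- function(img, target_dim) {
  assert_image(img)
  target_dim <- as.integer(target_dim[1:2])
  if (!identical(as.integer(ceiling(target_dim / 2)), as.integer(dim(img))))
    stop(sprintf(
      "target shape %s is incompatible with a %s level (ceil-halving mismatch)",
      paste(target_dim, collapse = "x"), paste(dim(img), collapse = "x")),
      call. = FALSE)
  expand_matrix(target_dim[1L]) %*% img %*% t(expand_matrix(target_dim[2L]))
}

#' Gaussian pyramid
#'
#' `levels[[1]]` is the source image; each further level is
#' [pyr_reduce()] of the previous one.
#'
#' @param img numeric matrix.
#' @param K number of levels (>= 2); must not exceed [max_levels()].
#' @return list of `K` matrices with class `"gaussian_pyramid"`.
#' @export
gaussian_pyramid <- function(img, K = 6L) {
  assert_image(img)
  K <- as.integer(K)
  kmax <- max_levels(dim(img))
  if (K < 2L) stop("`K` must be >= 2", call. = FALSE)
  if (K > kmax)
    stop(sprintf("K = %d too deep for a %s image; maximum feasible K is %d",
                 K, paste(dim(img), collapse = "x"), kmax), call. = FALSE)
  levels <- vector("list", K)
  levels[[1L]] <- img
  for (k in seq_len(K - 1L)) levels[[k + 1L]] <- pyr_reduce(levels[[k]])
  structure(levels, class = "gaussian_pyramid")
}

#' Laplacian pyramid
#'
#' Band-pass levels `G_k - expand(G_{k+1})` for `k < K-1`; the last level is
#' the Gaussian base `G_{K-1}`. Exactly invertible by [pyr_reconstruct()].
#'
#' @inheritParams gaussian_pyramid
#' @return list of `K` matrices with class `"laplacian_pyramid"`.
#' @export
laplacian_pyramid <- function(img, K = 6L) {
  g <- gaussian_pyramid(img, K)
  K <- length(g)
  lp <- vector("list", K)
  for (k in seq_len(K - 1L))
    lp[[k]] <- g[[k]] - pyr_expand(g[[k + 1L]], dim(g[[k]]))
  lp[[K]] <- g[[K]]
  structure(lp, class = "laplacian_pyramid")
}

#' Reconstruct an image from a Laplacian pyramid
#'
#' Starting from the base level, each finer level adds its band-pass detail
#' to the expanded running reconstruction: `G_k = LP_k + expand(G_{k+1})`.
#'
#' @param lp a `"laplacian_pyramid"` (list of levels, base last).
#' @return numeric matrix with the shape of level 1.
#' @export
pyr_reconstruct <- function(lp) {
  if (!is.list(lp) || length(lp) < 2L)
    stop("`lp` must be a Laplacian pyramid with at least 2 levels",
         call. = FALSE)
  K <- length(lp)
  for (k in seq.int(K - 1L, 1L)) {
    if (!identical(as.integer(ceiling(dim(lp[[k]]) / 2)),
                   as.integer(dim(lp[[k + 1L]]))))
      stop("malformed pyramid: level shapes do not ceil-halve", call. = FALSE)
  }
  g <- lp[[K]]
  for (k in seq.int(K - 1L, 1L)) g <- lp[[k]] + pyr_expand(g, dim(lp[[k]]))
  g
}

#' Pixel-level Laplacian-pyramid fusion (baseline)
#'
#' The classical choose-max rule: each band-pass coefficient is taken from
#' the source whose coefficient has the largest absolute value (ties go to
#' the smallest source index); the base level is the mean of the source
#' bases.
#'
#' @param lps list of `"laplacian_pyramid"` objects of identical geometry.
#' @return a fused `"laplacian_pyramid"`.
#' @seealso [rmlp_fuse()] for the region-mosaicking rule.
#' @export
lp_fuse <- function(lps) {
  if (!is.list(lps) || length(lps) < 1L)
    stop("`lps` must be a non-empty list of Laplacian pyramids", call. = FALSE)
  K <- length(lps[[1L]])
  for (p in lps) {
    if (length(p) != K)
      stop("pyramids differ in depth", call. = FALSE)
    for (k in seq_len(K))
      assert_same_shape(lps[[1L]][[k]], p[[k]], sprintf("level %d", k))
  }
  fused <- vector("list", K)
  for (k in seq_len(K - 1L)) {
    best <- lps[[1L]][[k]]
    besta <- abs(best)
    for (n in seq_along(lps)[-1L]) {
      a <- abs(lps[[n]][[k]])
      upd <- a > besta            # strict: ties keep the smaller index
      best[upd] <- lps[[n]][[k]][upd]
      besta[upd] <- a[upd]
    }
    fused[[k]] <- best
  }
  fused[[K]] <- Reduce(`+`, lapply(lps, `[[`, K)) / length(lps)
  structure(fused, class = "laplacian_pyramid")
}
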