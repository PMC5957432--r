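#' Modified Laplacian of an image
#'
#' Absolute second differences in the two axis directions,
#' `|2I(x,y) - I(x-1,y) - I(x+1,y)| + |2I(x,y) - I(x,y-1) - I(x,y+1)|`,
#' with unit pixel step. Taking absolute values before summing prevents
#' opposite-sign second derivatives from cancelling, which makes the operator
#' a reliable sharpness cue. Borders are handled by edge replication, so the
#' response of a constant or linear ramp image is zero everywhere.
#'
#' @param img numeric matrix (single-channel image).
#' @return numeric matrix of the same shape, all values >= 0.
#' @seealso [sml()]
#' @export
#' @examples
#' im <- matrix(0, 5, 5); im[3, 3] <- 1
#' modified_laplacian(im)[3, 3]  # 4
modified_laplacian <- function(img) {
  assert_image(img)
  H <- nrow(img); W <- ncol(img)
  up    <- img[c(1L, seq_len(H - 1L)), , drop = FALSE]
  down  <- img[c(seq_len(H)[-1L], H), , drop = FALSE]
  left  <- img[, c(1L, seq_len(W - 1L)), drop = FALSE]
  right <- img[, c(seq_len(W)[-1L], W), drop = FALSE]
  abs(2 * img - up - down) + abs(2 * img - left - right)
}

#' Sum-Modified-Laplacian focus measure
#'
#' Windowed sum of the modified Laplacian: at each pixel, modified-Laplacian
#' values of at least `threshold` are summed over the (2w+1) x (2w+1) window
#' centered there (window clipped at the image border; sub-threshold cells are
#' not counted). High values mark in-focus pixels.
#'
#' @param img numeric matrix (single-channel image).
#' @param w window half-width in pixels; the default `w = 1` gives the usual
#'   3 x 3 window.
#' @param threshold discrimination threshold `T` (intensity units) applied to
#'   each modified-Laplacian value before it enters the window sum. Default 0,
#'   i.e. a plain windowed sum.
#' @return numeric matrix of the same shape as `img`; all values >= 0.
#' @export
#' @examples
#' im <- matrix(0, 5, 5); im[3, 3] <- 1
#' sml(im)[3, 3]               # 8
#' sml(im, threshold = 2)[3, 3]  # 4: the four ML = 1 neighbors are gated out
sml <- function(img, w = 1L, threshold = 0) {
  assert_image(img)
  if (length(w) != 1L || !is.finite(w) || w < 1 || w != round(w))
    stop("`w` must be an integer >= 1", call. = FALSE)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("`threshold` must be a non-negative number", call. = FALSE)
  m <- modified_laplacian(img)
  if (threshold > 0) m[m < threshold] <- 0
  box <- rep(1, 2L * as.integer(w) + 1L)
  A <- same_matrix(nrow(img), box, "zero")
  B <- same_matrix(ncol(img), box, "zero")
  out <- A %*% m %*% t(B)
  attr(out, "w") <- as.integer(w)
  attr(out, "threshold") <- threshold
  out
}
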