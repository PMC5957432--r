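# Reference-based fusion quality metrics. For color images both metrics are
# computed per channel and averaged.

metric_channels <- function(a, b, f) {
  if (is_color(a) != is_color(b))
    stop("both images must be grayscale or both color", call. = FALSE)
  if (is_color(a)) {
    assert_same_shape(a, b)
    mean(vapply(seq_len(dim(a)[3L]),
                function(ch) f(a[, , ch], b[, , ch]), numeric(1)))
  } else {
    assert_image(a); assert_image(b); assert_same_shape(a, b)
    f(a, b)
  }
}

#' Root-mean-square error between two images
#'
#' `sqrt(mean((I - I')^2))` over all pixels; 0 iff the images are identical.
#' Color images: per-channel RMSE, averaged.
#'
#' @param fused,reference numeric matrices (or H x W x 3 arrays) of the same
#'   shape.
#' @return non-negative scalar.
#' @export
rmse <- function(fused, reference) {
  metric_channels(fused, reference, function(a, b) sqrt(mean((a - b)^2)))
}

#' Mean structural similarity (SSIM)
#'
#' Sliding-window SSIM with stabilizers `C1 = (K1*L)^2`, `C2 = (K2*L)^2`:
#' windowed means, variances and covariance are computed with a Gaussian
#' window (default 11 x 11, sigma 1.5; reflective borders) and the per-pixel
#' SSIM map is averaged. `ssim(x, x)` is exactly 1; values lie in `[-1, 1]`.
#' Color images: per-channel SSIM, averaged.
#'
#' @inheritParams rmse
#' @param K1,K2 stabilizer constants (defaults 0.01 and 0.03).
#' @param L dynamic range of the pixel values (default 255).
#' @param window `"gaussian"` (default) or `"uniform"`.
#' @param window_size odd window width in pixels (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(fused, reference, K1 = 0.01, K2 = 0.03, L = 255,
                 window = c("gaussian", "uniform"), window_size = 11L,
                 sigma = 1.5) {
  window <- match.arg(window)
  if (K1 <= 0 || K2 <= 0 || L <= 0)
    stop("`K1`, `K2` and `L` must be positive", call. = FALSE)
  if (window_size < 1L || window_size %% 2L == 0L)
    stop("`window_size` must be a positive odd integer", call. = FALSE)
  kern <- if (window == "gaussian") {
    hw <- (window_size - 1L) %/% 2L
    k <- exp(-(seq.int(-hw, hw))^2 / (2 * sigma^2))
    k / sum(k)
  } else {
    rep(1 / window_size, window_size)
  }
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  metric_channels(fused, reference, function(x, y) {
    wfilt <- function(m) filter_separable(m, kern, border = "reflect")
    mux <- wfilt(x); muy <- wfilt(y)
    sx2 <- wfilt(x * x) - mux * mux
    sy2 <- wfilt(y * y) - muy * muy
    sxy <- wfilt(x * y) - mux * muy
    num <- (2 * mux * muy + C1) * (2 * sxy + C2)
    den <- (mux * mux + muy * muy + C1) * (sx2 + sy2 + C2)
    mean(num / den)
  })
}
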