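# Low-level separable filtering and discrete-disk machinery.
#
# All linear filters are realized as banded matrices applied by ordinary
# matrix products (row filter: A %*% img, column filter: img %*% t(B)),
# which is both exact and fast under BLAS at the image sizes this package
# targets. Matrices are cached per (length, kernel, border) in a package
# environment.

.rmlp_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .rmlp_cache[[key]]
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .rmlp_cache)
  }
  v
}

# Mirror-without-edge-repeat index folding into 1..n (reflect border).
fold_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n - 2L
  i0 <- (as.integer(idx) - 1L) %% period
  over <- i0 >= n
  i0[over] <- period - i0[over]
  i0 + 1L
}

# n x n matrix applying a centered 1-D kernel along a length-n axis.
# border: "reflect" folds indices, "zero" drops out-of-range taps,
# "replicate" clamps them to the edge.
same_matrix <- function(n, kernel, border = c("reflect", "zero", "replicate")) {
  border <- match.arg(border)
  key <- paste("same", n, border, paste(signif(kernel, 12), collapse = ","))
  cache_get(key, function() {
    hw <- (length(kernel) - 1L) %/% 2L
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      src <- i + seq.int(-hw, hw)
      for (t in seq_along(src)) {
        s <- src[t]
        if (border == "reflect") {
          s <- fold_index(s, n)
        } else if (border == "replicate") {
          s <- min(max(s, 1L), n)
        } else if (s < 1L || s > n) {
          next
        }
        M[i, s] <- M[i, s] + kernel[t]
      }
    }
    M
  })
}

# ceil(n/2) x n decimating filter matrix: out[i] = sum_m k[m] in[2i-1+m],
# reflect border (the Gaussian-pyramid REDUCE step along one axis).
reduce_matrix <- function(n, kernel = binomial5()) {
  key <- paste("reduce", n, paste(signif(kernel, 12), collapse = ","))
  cache_get(key, function() {
    m <- ceiling(n / 2)
    hw <- (length(kernel) - 1L) %/% 2L
    M <- matrix(0, m, n)
    for (i in seq_len(m)) {
      src <- fold_index(2L * i - 1L + seq.int(-hw, hw), n)
      for (t in seq_along(src)) M[i, src[t]] <- M[i, src[t]] + kernel[t]
    }
    M
  })
}

# n_target x ceil(n_target/2) upsampling matrix: zero-interleave then filter
# with the doubled kernel, reflect border applied to coarse-grid indices.
expand_matrix <- function(n_target, kernel = binomial5()) {
  key <- paste("expand", n_target, paste(signif(kernel, 12), collapse = ","))
  cache_get(key, function() {
    n_src <- ceiling(n_target / 2)
    hw <- (length(kernel) - 1L) %/% 2L
    M <- matrix(0, n_target, n_src)
    for (i in seq_len(n_target)) {
      for (k in seq.int(-hw, hw)) {
        t0 <- (i - 1L) + k            # 0-based fine-grid tap
        if (t0 %% 2L == 0L) {
          s <- fold_index(t0 %/% 2L + 1L, n_src)
          M[i, s] <- M[i, s] + 2 * kernel[k + hw + 1L]
        }
      }
    }
    M
  })
}

# Burt-Adelson 5-tap generating kernel (a = 0.375).
binomial5 <- function() c(1, 4, 6, 4, 1) / 16

gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq.int(-hw, hw))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable same-size filtering with one 1-D kernel on both axes.
filter_separable <- function(img, kernel, border = "reflect") {
  A <- same_matrix(nrow(img), kernel, border)
  B <- same_matrix(ncol(img), kernel, border)
  A %*% img %*% t(B)
}

# Gaussian blur with reflective borders; sigma = 0 is the identity.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  filter_separable(img, gaussian_kernel(sigma))
}

# ---- discrete disk helpers -------------------------------------------------

isqrt <- function(v) {
  if (v < 0) return(-1L)
  w <- as.integer(floor(sqrt(v)))
  while ((w + 1L)^2 <= v) w <- w + 1L
  while (w^2 > v) w <- w - 1L
  w
}

# Integer offsets of the discrete disk {(dr,dc): dr^2 + dc^2 <= R^2}.
disk_offsets <- function(R) {
  dr <- rep(seq.int(-R, R), each = 2L * R + 1L)
  dc <- rep(seq.int(-R, R), times = 2L * R + 1L)
  keep <- dr * dr + dc * dc <= R * R
  cbind(dr = dr[keep], dc = dc[keep])
}

# Vertical shift with zero fill: out[i, ] = m[i + k, ] (0 outside).
shift_rows <- function(m, k) {
  H <- nrow(m)
  out <- matrix(0, H, ncol(m))
  if (k >= 0) {
    if (k < H) out[seq_len(H - k), ] <- m[seq.int(k + 1L, H), , drop = FALSE]
  } else {
    if (-k < H) out[seq.int(-k + 1L, H), ] <- m[seq_len(H + k), , drop = FALSE]
  }
  out
}

# Exact disk-neighborhood sum: out[i,j] = sum of mat over the discrete disk
# of radius R centered at (i,j), clipped to the image. Decomposes the disk
# into per-row horizontal box filters (banded-matrix products), so counts on
# 0/1 inputs are exact integers.
disk_sum <- function(mat, R) {
  H <- nrow(mat); W <- ncol(mat)
  drs <- seq.int(-R, R)
  wds <- vapply(drs, function(d) isqrt(R * R - d * d), integer(1))
  out <- matrix(0, H, W)
  for (wd in unique(wds)) {
    box <- rep(1, 2L * wd + 1L)
    B <- same_matrix(W, box, "zero")
    rowsum_ <- mat %*% t(B)
    for (d in drs[wds == wd]) out <- out + shift_rows(rowsum_, d)
  }
  out
}
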