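# Brute-force nested-loop oracles, kept deliberately naive and independent of
# the vectorized implementation paths they check.

# modified Laplacian with edge replication, pixel by pixel
oracle_ml <- function(img) {
  H <- nrow(img); W <- ncol(img)
  at <- function(i, j) img[min(max(i, 1L), H), min(max(j, 1L), W)]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[i, j] <- abs(2 * img[i, j] - at(i - 1L, j) - at(i + 1L, j)) +
      abs(2 * img[i, j] - at(i, j - 1L) - at(i, j + 1L))
  }
  out
}

# windowed sum of thresholded ML values, window clipped at the border
oracle_sml <- function(img, w = 1L, threshold = 0) {
  m <- oracle_ml(img)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (di in -w:w) for (dj in -w:w) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= H && jj >= 1L && jj <= W && m[ii, jj] >= threshold)
        s <- s + m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# per-label densities in the clipped discrete disk around (ci, cj)
oracle_density <- function(mask, ci, cj, R, n) {
  H <- nrow(mask); W <- ncol(mask)
  counts <- numeric(n)
  total <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if ((i - ci)^2 + (j - cj)^2 <= R^2) {
      total <- total + 1L
      counts[mask[i, j]] <- counts[mask[i, j]] + 1L
    }
  }
  counts / total
}

# one level of 2x2 majority-vote downsampling, ties to the smallest label
oracle_block_majority <- function(mask, n) {
  H <- nrow(mask); W <- ncol(mask)
  m <- ceiling(H / 2); w2 <- ceiling(W / 2)
  out <- matrix(0L, m, w2)
  for (i in seq_len(m)) for (j in seq_len(w2)) {
    cnt <- integer(n)
    for (di in 0:1) for (dj in 0:1) {
      ii <- 2L * i - 1L + di; jj <- 2L * j - 1L + dj
      if (ii <= H && jj <= W) cnt[mask[ii, jj]] <- cnt[mask[ii, jj]] + 1L
    }
    out[i, j] <- which.max(cnt)   # which.max takes the first maximum
  }
  out
}

# direct 2-D 5x5 binomial convolution (reflect border) plus decimation
oracle_reduce <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  H <- nrow(img); W <- ncol(img)
  refl <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  m <- ceiling(H / 2); w2 <- ceiling(W / 2)
  out <- matrix(0, m, w2)
  for (i in seq_len(m)) for (j in seq_len(w2)) {
    s <- 0
    for (di in -2:2) for (dj in -2:2) {
      s <- s + k[di + 3] * k[dj + 3] *
        img[refl(2L * i - 1L + di, H), refl(2L * j - 1L + dj, W)]
    }
    out[i, j] <- s
  }
  out
}

# pixel-level choose-max fusion of band levels, first index on |.| ties
oracle_lp_fuse_level <- function(levels) {
  H <- nrow(levels[[1]]); W <- ncol(levels[[1]])
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- vapply(levels, function(l) l[i, j], numeric(1))
    out[i, j] <- vals[which.max(abs(vals))]
  }
  out
}

random_int_image <- function(H, W, seed, lo = 0L, hi = 255L) {
  set.seed(seed)
  matrix(sample.int(hi - lo + 1L, H * W, replace = TRUE) + lo - 1L, H, W)
}

random_mask <- function(H, W, n, seed) {
  set.seed(seed)
  matrix(sample.int(n, H * W, replace = TRUE), H, W)
}

# two-frame stack sharp on complementary halves of `truth`
halfsharp_stack <- function(truth, sigma = 3) {
  H <- nrow(truth)
  blurred <- rmlp:::blur_image(truth, sigma)
  top <- truth; top[(H %/% 2 + 1):H, ] <- blurred[(H %/% 2 + 1):H, ]
  bot <- truth; bot[1:(H %/% 2), ] <- blurred[1:(H %/% 2), ]
  list(top, bot)
}
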