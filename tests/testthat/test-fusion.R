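test_that("mask pyramid downsampling is a 2x2 majority vote with smallest-label ties", {
  uni <- matrix(3L, 16, 16)
  mp <- mask_pyramid(uni, K = 3, n_sources = 4)
  for (lv in mp) expect_true(all(lv == 3L))

  half <- matrix(1L, 8, 8); half[, 5:8] <- 2L
  mp <- mask_pyramid(half, K = 3, n_sources = 2)
  expect_true(all(mp[[2]][, 1:2] == 1L) && all(mp[[2]][, 3:4] == 2L))
  expect_true(all(mp[[3]][, 1] == 1L) && all(mp[[3]][, 2] == 2L))

  tie <- rbind(c(1L, 1L, 2L, 1L), c(2L, 2L, 2L, 1L),
               c(1L, 2L, 1L, 2L), c(2L, 1L, 2L, 1L))  # every block tied 2-2
  expect_true(all(mask_pyramid(tie, K = 2, n_sources = 2)[[2]] == 1L))

  for (s in 1:4) {
    n <- c(2L, 4L)[s %% 2 + 1]
    msk <- random_mask(32, 32, n, seed = 400 + s)
    mp <- mask_pyramid(msk, K = 4, n_sources = n)
    cur <- msk
    for (k in 2:4) {
      cur <- oracle_block_majority(cur, n)
      expect_identical(matrix(as.integer(mp[[k]]), nrow(cur)), cur,
                       label = sprintf("seed %d level %d", s, k))
    }
  }
  expect_error(mask_pyramid(uni, K = 9, n_sources = 4), "maximum feasible")
})

test_that("mosaic fusion is pure per-cell selection", {
  set.seed(31)
  img <- matrix(runif(32 * 32, 0, 255), 32)
  lp <- laplacian_pyramid(img, K = 3)
  uni2 <- mask_pyramid(matrix(1L, 32, 32), K = 3, n_sources = 1)
  fused <- mosaic_fuse(list(lp), uni2)
  for (k in 1:3) expect_identical(fused[[k]], lp[[k]])   # N = 1 identity

  lp2 <- laplacian_pyramid(matrix(runif(32 * 32, 0, 255), 32), K = 3)
  all2 <- mask_pyramid(matrix(2L, 32, 32), K = 3, n_sources = 2)
  fused <- mosaic_fuse(list(lp, lp2), all2)
  for (k in 1:3) expect_identical(fused[[k]], lp2[[k]])

  half <- matrix(1L, 32, 32); half[17:32, ] <- 2L
  mp <- mask_pyramid(half, K = 3, n_sources = 2)
  fused <- mosaic_fuse(list(lp, lp2), mp)
  for (k in 1:3) {
    m <- mp[[k]]
    expect_identical(fused[[k]][m == 1L], lp[[k]][m == 1L])
    expect_identical(fused[[k]][m == 2L], lp2[[k]][m == 2L])
  }

  expect_error(mosaic_fuse(list(lp), all2), "source 2")
})

test_that("top-layer fusion selects base pixels by label", {
  b1 <- matrix(1, 4, 4); b2 <- matrix(2, 4, 4)
  expect_equal(fuse_top_layer(list(b1, b1), matrix(c(1L, 2L), 4, 4)), b1)
  expect_equal(fuse_top_layer(list(b1, b2), matrix(2L, 4, 4)), b2)
  stripes <- matrix(rep(c(1L, 2L), each = 8), 4, 4)
  out <- fuse_top_layer(list(b1, b2), stripes)
  expect_equal(out, matrix(as.numeric(stripes), 4, 4))
  expect_error(fuse_top_layer(list(b1), matrix(1L, 3, 3)), "shape")
})

test_that("a stack of identical images fuses to itself (gray and color)", {
  img <- make_ground_truth(c(96, 96), "texture", seed = 2)
  res <- rmlp_fuse(rep(list(img), 8))
  expect_lt(max(abs(res$fused - img)), 1e-6)

  col <- array(0, c(96, 96, 3))
  col[, , 1] <- img; col[, , 2] <- img / 2; col[, , 3] <- sqrt(img)
  res <- rmlp_fuse(rep(list(col), 4))
  expect_lt(max(abs(res$fused - col)), 1e-6)
})

test_that("single-image stacks warn and return a copy", {
  img <- matrix(1:20 + 0, 4, 5)
  expect_warning(res <- rmlp_fuse(list(img)), "single")
  expect_identical(res$fused, img)
})

test_that("fusing two half-sharp frames beats both sources against truth", {
  truth <- make_ground_truth(c(128, 128), "texture", seed = 6)
  st <- halfsharp_stack(truth, sigma = 3)
  res <- rmlp_fuse(st, R = 8, K = 5)
  r <- rmse(res$fused, truth)
  expect_lt(r, min(rmse(st[[1]], truth), rmse(st[[2]], truth)))
})

test_that("region provenance: block-aligned regions are copied bit-for-bit", {
  set.seed(55)
  imgs <- lapply(1:2, function(i) matrix(runif(64 * 64, 0, 255), 64))
  lps <- lapply(imgs, laplacian_pyramid, K = 4)
  mask <- matrix(1L, 64, 64); mask[, 33:64] <- 2L   # aligned to 2^3
  mp <- mask_pyramid(mask, K = 4, n_sources = 2)
  fused <- mosaic_fuse(lps, mp)
  for (k in 1:4) {
    m <- mp[[k]]
    for (n in 1:2)
      expect_identical(fused[[k]][m == n], lps[[n]][[k]][m == n],
                       label = sprintf("level %d source %d", k, n))
  }
})

test_that("fusion is covariant under stack permutation", {
  truth <- make_ground_truth(c(128, 128), "texture", seed = 11)
  st <- halfsharp_stack(truth, sigma = 3)

  # the estimated DBRG mask relabels covariantly
  f1 <- rmlp_fuse(st, R = 8, K = 5)
  f2 <- rmlp_fuse(rev(st), R = 8, K = 5)
  expect_true(all(f1$mask == 3L - f2$mask))

  # with a block-aligned mask (no majority-vote ties) the fused image is
  # bit-identical under permutation + relabeling
  mask <- matrix(1L, 128, 128); mask[65:128, ] <- 2L
  g1 <- rmlp_fuse(st, K = 5, mask = mask)
  g2 <- rmlp_fuse(rev(st), K = 5, mask = 3L - mask)
  expect_identical(g1$fused, g2$fused)
})

test_that("fusing the fused image with itself is the identity", {
  truth <- make_ground_truth(c(128, 128), "texture", seed = 11)
  st <- halfsharp_stack(truth, sigma = 3)
  f <- rmlp_fuse(st, R = 8, K = 5)$fused
  again <- rmlp_fuse(list(f, f), R = 8, K = 5)$fused
  expect_lt(max(abs(again - f)), 1e-6)
})

test_that("color fusion reduces to the gray path on replicated channels", {
  truth <- make_ground_truth(c(64, 64), "texture", seed = 8)
  st <- halfsharp_stack(truth, sigma = 3)
  gray <- rmlp_fuse(st, R = 6, K = 4)
  col_stack <- lapply(st, function(m) array(rep(m, 3), c(dim(m), 3)))
  col <- rmlp_fuse(col_stack, R = 6, K = 4)
  for (ch in 1:3) expect_equal(col$fused[, , ch], gray$fused)

  shared <- rmlp_fuse(col_stack, R = 6, K = 4, color_mode = "shared-mask")
  expect_equal(shared$fused[, , 1], gray$fused)
  expect_true(is.matrix(shared$mask))

  bad <- col_stack; bad[[2]] <- bad[[2]][, , 1:2]
  expect_error(rmlp_fuse(bad), "3")
})
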