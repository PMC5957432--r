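test_that("generators are bit-deterministic per seed", {
  for (kind in c("texture", "rings", "natural")) {
    expect_identical(make_ground_truth(c(64, 48), kind, seed = 3),
                     make_ground_truth(c(64, 48), kind, seed = 3),
                     label = kind)
  }
  expect_false(identical(make_ground_truth(c(64, 48), "texture", seed = 3),
                         make_ground_truth(c(64, 48), "texture", seed = 4)))
  expect_identical(make_depth_map(c(64, 48), "blobs", seed = 5),
                   make_depth_map(c(64, 48), "blobs", seed = 5))
  truth <- make_ground_truth(c(64, 64), "texture", seed = 1)
  depth <- make_depth_map(c(64, 64), "stripes")
  s1 <- render_stack(truth, depth, 4, 3, noise_sd = 2, seed = 9)
  s2 <- render_stack(truth, depth, 4, 3, noise_sd = 2, seed = 9)
  expect_identical(s1$frames, s2$frames)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_ground_truth(c(32, 32), "texture", seed = 77))
  expect_identical(.Random.seed, before)
  a <- runif(1)
  set.seed(123)
  expect_identical(runif(1), a)
})

test_that("ground-truth kinds have their stated structure", {
  tex <- make_ground_truth(c(64, 64), "texture", seed = 2)
  expect_true(all(tex >= 0 & tex <= 255))
  expect_gt(mean(sml(tex) > 0), 0.99)   # focus measure discriminates a.e.

  rings <- make_ground_truth(c(65, 65), "rings", seed = 2)
  rot <- t(rings)[, rev(seq_len(65))]   # 90-degree rotation about the center
  expect_gt(stats::cor(as.vector(rings), as.vector(rot)),
            stats::cor(as.vector(rings[, 9:65]), as.vector(rings[, 1:57])))

  expect_error(make_ground_truth(c(8, 64)), "16 x 16")
})

test_that("depth maps are in [0,1] with the stated geometry", {
  d <- make_depth_map(c(64, 32), "stripes")
  expect_equal(d[, 1], (0:63) / 63)
  expect_true(all(apply(d, 1, function(r) length(unique(r)) == 1)))

  r <- make_depth_map(c(65, 65), "radial")
  expect_equal(r[33, 33], 0)
  expect_equal(max(r), 1)
  center_ring <- r[33, 43]; outer_ring <- r[33, 60]
  expect_lt(center_ring, outer_ring)

  b <- make_depth_map(c(64, 64), "blobs", seed = 6)
  expect_true(all(b >= 0 & b <= 1))
})

test_that("rendered stacks follow the defocus model", {
  truth <- make_ground_truth(c(64, 64), "texture", seed = 4)
  depth <- make_depth_map(c(64, 64), "stripes")

  sharp <- render_stack(truth, depth, 4, sigma_max = 0, noise_sd = 0)
  for (f in sharp$frames) expect_identical(f, truth)

  st <- render_stack(truth, depth, 2, sigma_max = 4, noise_sd = 0)
  s1 <- sml(st$frames[[1]]); s2 <- sml(st$frames[[2]])
  expect_gt(mean(s1[1:32, ]), mean(s2[1:32, ]))   # frame 1 sharp on top
  expect_gt(mean(s2[33:64, ]), mean(s1[33:64, ]))

  # true masks form contiguous bands in frame order matching argmin arithmetic
  # (edge bands are half-width because focal planes sit at depth 0 and 1)
  st4 <- render_stack(truth, depth, 4, sigma_max = 4)
  tm <- st4$true_mask
  expect_true(all(apply(tm, 1, function(r) length(unique(r)) == 1)))
  expect_true(!is.unsorted(tm[, 1]))
  expect_equal(sort(unique(as.vector(tm))), 1:4)
  d_n <- (0:3) / 3
  want <- vapply(depth[, 1], function(z) which.min(abs(z - d_n)), integer(1))
  expect_identical(as.integer(tm[, 1]), want)
  expect_equal(tabulate(tm[, 1]), c(11, 21, 21, 11))

  expect_error(render_stack(truth, depth, 1), "n_frames")
  expect_error(render_stack(truth, depth, 4, sigma_max = -1), "non-negative")
  expect_error(render_stack(truth, depth[1:10, ], 4), "shapes differ")
})

test_that("the SML winner mask agrees with the true mask away from band boundaries", {
  truth <- make_ground_truth(c(128, 128), "texture", seed = 5)
  depth <- make_depth_map(c(128, 128), "stripes")
  st <- render_stack(truth, depth, 4, sigma_max = 4, noise_sd = 0)
  m0 <- initial_mask(lapply(st$frames, sml))
  boundary <- which(diff(st$true_mask[, 1]) != 0)
  keep <- setdiff(seq_len(128), outer(boundary, -3:4, `+`))
  expect_gt(mean(m0[keep, ] == st$true_mask[keep, ]), 0.9)
})

test_that("fusing a rendered stack recovers the ground truth better than any frame", {
  truth <- make_ground_truth(c(128, 128), "texture", seed = 6)
  depth <- make_depth_map(c(128, 128), "stripes")
  st <- render_stack(truth, depth, 4, sigma_max = 4, noise_sd = 0)
  res <- rmlp_fuse(st$frames, R = 8, K = 5)
  expect_lt(rmse(res$fused, truth),
            min(vapply(st$frames, rmse, numeric(1), reference = truth)))
})

test_that("color stacks render and fuse above the best frame's SSIM", {
  gray <- make_ground_truth(c(96, 96), "texture", seed = 10)
  truth <- array(0, c(96, 96, 3))
  truth[, , 1] <- gray
  truth[, , 2] <- rmlp:::clamp(0.8 * gray + 20, 0, 255)
  truth[, , 3] <- rmlp:::clamp(255 - gray, 0, 255)
  depth <- make_depth_map(c(96, 96), "stripes")
  st <- render_stack(truth, depth, 4, sigma_max = 4, noise_sd = 0)
  res <- rmlp_fuse(st$frames, R = 6, K = 5)
  expect_gt(ssim(res$fused, truth),
            max(vapply(st$frames, ssim, numeric(1), reference = truth)))
})
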