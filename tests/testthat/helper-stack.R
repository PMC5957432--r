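# Reference synthetic study stack (built once per test run): 256x256 textured
# ground truth, stripe depth, 8 frames, blur scale 4, no noise.
reference_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- make_ground_truth(c(256, 256), "texture", seed = 7)
      depth <- make_depth_map(c(256, 256), "stripes")
      st <- render_stack(truth, depth, n_frames = 8, sigma_max = 4,
                         noise_sd = 0, seed = 7)
      cache <<- list(truth = truth, depth = depth, stack = st)
    }
    cache
  }
})

lp_baseline_fuse <- function(frames, K = 6L) {
  pyr_reconstruct(lp_fuse(lapply(frames, laplacian_pyramid, K = K)))
}
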