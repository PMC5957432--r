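Package: rmlp
Title: Multi-Focus Image Fusion via Region Mosaicking on Laplacian Pyramids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses a stack of pre-aligned multi-focus microscope images into a
    single all-in-focus image. Per-pixel sharpness is measured with the
    Sum-Modified-Laplacian focus operator, contiguous in-focus regions are
    segmented by density-based region growing, and the stack is fused by
    supervising each source's Laplacian pyramid with a categorical mask
    pyramid so that whole regions are mosaicked from single sources. Includes
    the classical pixel-level Laplacian-pyramid fusion baseline, RMSE and
    SSIM reference metrics, a synthetic multi-focus stack generator with
    known ground truth, and a small command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
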