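# Image stack I/O. PNG and TIFF (8- or 16-bit) are read into floating-point
# matrices/arrays on the nominal [0, 255] scale; writes are 8-bit after
# rounding and clamping (16-bit for depth maps).

#' Read a single image file
#'
#' PNG and TIFF are supported; 16-bit files are rescaled to `[0, 255]`.
#' Alpha channels are dropped; single-channel images come back as matrices,
#' RGB as H x W x 3 arrays.
#'
#' @param path file path.
#' @return numeric matrix or H x W x 3 array, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' for '%s' (PNG/TIFF only)",
                 ext, path), call. = FALSE))
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3L] == 2L) img <- img[, , 1L]          # gray + alpha
    else if (dim(img)[3L] >= 4L) img <- img[, , 1:3]    # drop alpha
    else if (dim(img)[3L] == 1L) img <- img[, , 1L]
  }
  img * 255
}

#' Load an aligned multi-focus stack
#'
#' `paths` may be a directory (all PNG/TIFF files inside, in lexicographic
#' filename order, which defines the frame order) or a character vector of
#' files. All frames must have identical dimensions.
#'
#' @param paths directory or vector of file paths.
#' @return list of images with class `"image_stack"`; attribute `sources`
#'   records the file paths.
#' @export
load_stack <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
  }
  if (length(paths) < 1L)
    stop("no readable PNG/TIFF images found", call. = FALSE)
  imgs <- lapply(paths, read_image)
  dims <- vapply(imgs, function(im)
    paste(dim(im)[1:2], collapse = "x"), character(1))
  if (length(unique(dims)) > 1L) {
    bad <- paste(sprintf("%s (%s)", basename(paths), dims), collapse = ", ")
    stop(sprintf("stack images differ in size: %s", bad), call. = FALSE)
  }
  if (length(imgs) == 1L)
    warning("stack contains a single image")
  structure(imgs, class = "image_stack", sources = paths)
}

#' Write an image as 8-bit PNG or TIFF
#'
#' Values are rounded and clamped to `[0, 255]` on export.
#'
#' @param img numeric matrix or H x W x 3 array on the `[0, 255]` scale.
#' @param path output path ending in .png, .tif or .tiff.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  v <- clamp(round(img), 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format '.%s' (PNG/TIFF only)", ext),
         call. = FALSE))
  invisible(path)
}

#' Write a label mask as an 8-bit grayscale PNG
#'
#' Pixel value n encodes source label n directly (so up to 255 sources);
#' [read_mask()] restores the integer labels exactly.
#'
#' @param mask integer label matrix.
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 255L)
    stop("masks with more than 255 labels cannot be stored as 8-bit PNG",
         call. = FALSE)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path .png path.
#' @return integer label matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  mode(m) <- "integer"
  m
}

# 16-bit TIFF round trip for depth maps (values in [0, 1]).
write_depth <- function(depth, path) {
  tiff::writeTIFF(clamp(depth, 0, 1), path, bits.per.sample = 16L)
  invisible(path)
}

read_depth <- function(path) {
  tiff::readTIFF(path)
}
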