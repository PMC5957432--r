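# Density-based region growing (DBRG) on the pixel-level winner mask.
#
# The initial mask labels each pixel with the source image whose SML is
# largest there. That mask is noisy in defocused and smooth areas, so it is
# refined: pixels whose radius-R disk neighborhood has a strict majority
# label become seeds; clusters grow from seeds through density-connected
# seed pixels, absorbing same-label pixels in range; leftover pixels take
# the label of the nearest labeled pixel under Chebyshev distance.

#' Pixel-level winner mask from focus measures
#'
#' Labels each pixel with the index of the source image whose focus measure
#' (SML) is largest there; ties go to the smallest source index.
#'
#' @param focus_maps list of numeric matrices, one SML map per source image,
#'   all of the same shape.
#' @return integer matrix of labels in `1..length(focus_maps)`, with attribute
#'   `n_sources`.
#' @export
initial_mask <- function(focus_maps) {
  if (!is.list(focus_maps) || length(focus_maps) < 1L)
    stop("`focus_maps` must be a non-empty list of matrices", call. = FALSE)
  lapply(focus_maps, assert_image, arg = "focus_maps[[i]]")
  for (n in seq_along(focus_maps))
    assert_same_shape(focus_maps[[1L]], focus_maps[[n]], "focus maps")
  best <- focus_maps[[1L]]
  lab <- matrix(1L, nrow(best), ncol(best))
  for (n in seq_along(focus_maps)[-1L]) {
    upd <- focus_maps[[n]] > best   # strict: ties keep the smaller index
    lab[upd] <- as.integer(n)
    best[upd] <- focus_maps[[n]][upd]
  }
  attr(lab, "n_sources") <- length(focus_maps)
  lab
}

n_sources_of <- function(mask, n_sources = NULL) {
  n <- n_sources %||% attr(mask, "n_sources") %||% max(mask)
  as.integer(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_mask <- function(mask, n_sources) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("`mask` must be an integer matrix of labels", call. = FALSE)
  if (any(mask != round(mask)) || any(mask < 1L) || any(mask > n_sources))
    stop(sprintf("mask labels must be integers in [1, %d]", n_sources),
         call. = FALSE)
  invisible(mask)
}

#' Per-label density in a disk neighborhood
#'
#' Fraction of each label among the pixels of the discrete disk
#' `{(i,j): (i-x)^2 + (j-y)^2 <= R^2}` centered at `center`, clipped to the
#' image. Densities are exact cell-count ratios and sum to 1.
#'
#' @param mask integer label matrix.
#' @param center length-2 integer vector `c(row, col)`.
#' @param R disk radius in pixels (>= 1).
#' @param n_sources number of labels; defaults to the mask's `n_sources`
#'   attribute or its maximum.
#' @return named numeric vector of length `n_sources`.
#' @export
neighborhood_density <- function(mask, center, R, n_sources = NULL) {
  n <- n_sources_of(mask, n_sources)
  assert_mask(mask, n)
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  if (length(center) != 2L || center[1L] < 1L || center[1L] > H ||
      center[2L] < 1L || center[2L] > W)
    stop("`center` must be a pixel inside the image", call. = FALSE)
  offs <- disk_offsets(as.integer(R))
  r <- center[1L] + offs[, 1L]
  c <- center[2L] + offs[, 2L]
  keep <- r >= 1L & r <= H & c >= 1L & c <= W
  labs <- mask[cbind(r[keep], c[keep])]
  counts <- tabulate(labs, nbins = n)
  stats::setNames(counts / sum(counts), seq_len(n))
}

# All-pixel density counts: list(counts = list of N integer matrices,
# total = matrix of in-image disk cardinalities).
density_counts <- function(mask, R, n_sources) {
  total <- disk_sum(matrix(1, nrow(mask), ncol(mask)), R)
  counts <- lapply(seq_len(n_sources), function(n)
    disk_sum((mask == n) + 0, R))
  list(counts = counts, total = total)
}

# Seed matrices: seed = strict majority (2 * max count > disk size);
# majority = smallest label attaining the maximum count.
seed_matrices <- function(mask, R, n_sources) {
  dc <- density_counts(mask, R, n_sources)
  maxc <- dc$counts[[1L]]
  maj <- matrix(1L, nrow(mask), ncol(mask))
  for (n in seq_len(n_sources)[-1L]) {
    upd <- dc$counts[[n]] > maxc
    maj[upd] <- as.integer(n)
    maxc[upd] <- dc$counts[[n]][upd]
  }
  list(seeds = 2 * maxc > dc$total, majority = maj)
}

#' Seed pixels of the density-based segmentation
#'
#' A pixel is a seed when the most frequent label in its radius-`R` disk
#' neighborhood has density strictly greater than 0.5.
#'
#' @inheritParams neighborhood_density
#' @return data frame with columns `row`, `col`, `label` (the majority label),
#'   one row per seed pixel, in row-major pixel order.
#' @export
find_seeds <- function(mask, R, n_sources = NULL) {
  n <- n_sources_of(mask, n_sources)
  assert_mask(mask, n)
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  sm <- seed_matrices(mask, as.integer(R), n)
  idx <- which(t(sm$seeds))  # row-major order
  W <- ncol(mask)
  row <- (idx - 1L) %/% W + 1L
  col <- (idx - 1L) %% W + 1L
  data.frame(row = row, col = col,
             label = sm$majority[cbind(row, col)])
}

# Dilate a set of pixels (linear indices, column-major) by the discrete disk.
# Coordinate expansion for small frontiers, box-filter path for large ones.
dilate_disk <- function(idx, H, W, R, offs) {
  if (length(idx) * nrow(offs) <= 2e6) {
    r0 <- (idx - 1L) %% H + 1L
    c0 <- (idx - 1L) %/% H + 1L
    m <- nrow(offs)
    rr <- rep(r0, times = m) + rep(offs[, 1L], each = length(idx))
    cc <- rep(c0, times = m) + rep(offs[, 2L], each = length(idx))
    keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    unique((cc[keep] - 1L) * H + rr[keep])
  } else {
    frontier <- matrix(0, H, W)
    frontier[idx] <- 1
    which(disk_sum(frontier, R) > 0.5)
  }
}

# Zero-filled 2-D shift: out[i,j] = m[i+dr, j+dc].
shift2 <- function(m, dr, dc) {
  out <- shift_rows(m, dr)
  if (dc == 0L) return(out)
  H <- nrow(out); W <- ncol(out)
  res <- matrix(0, H, W)
  if (dc > 0) {
    if (dc < W) res[, seq_len(W - dc)] <- out[, seq.int(dc + 1L, W)]
  } else {
    if (-dc < W) res[, seq.int(-dc + 1L, W)] <- out[, seq_len(W + dc)]
  }
  res
}

# Assign every 0 cell the label of its nearest labeled pixel under Chebyshev
# distance, by simultaneous 8-connected multi-source expansion; at equal
# distance the smallest label wins.
chebyshev_fill <- function(labels) {
  shifts <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  while (any(un <- labels == 0L)) {
    cand <- matrix(Inf, nrow(labels), ncol(labels))
    for (s in seq_len(nrow(shifts))) {
      sh <- shift2(labels, shifts[s, 1L], shifts[s, 2L])
      upd <- un & sh > 0 & sh < cand
      cand[upd] <- sh[upd]
    }
    newly <- un & is.finite(cand)
    if (!any(newly)) break   # nothing labeled anywhere: cannot fill
    labels[newly] <- as.integer(cand[newly])
  }
  labels
}

#' Default disk radius for a given image size
#'
#' `max(4, round(8 * min(H, W) / 480))`: the radius 8 recommended for
#' 720 x 480 frames, scaled proportionally to the shorter image side.
#'
#' @param dim image dimensions `c(H, W)`.
#' @return integer radius.
#' @export
default_radius <- function(dim) {
  max(4L, as.integer(round(8 * min(dim[1L], dim[2L]) / 480)))
}

#' Density-based region growing segmentation of a label mask
#'
#' Refines a pixel-level winner mask into contiguous focus regions. Seed
#' pixels (strict disk-majority, see [find_seeds()]) found in row-major order
#' each start or extend a cluster labeled with the seed's majority label; the
#' cluster grows by absorbing unlabeled pixels whose initial label equals the
#' cluster label within disk radius `R` of a cluster seed, and expansion
#' propagates transitively through absorbed pixels that are themselves seeds.
#' Remaining pixels (noise or smooth-region pixels) take the label of the
#' nearest labeled pixel under Chebyshev ("checker-board") distance, smallest
#' label on ties. If the mask has no seeds at all the input is returned
#' unchanged with a warning.
#'
#' @param mask integer label matrix (e.g. from [initial_mask()]).
#' @param R disk radius in pixels; default [default_radius()] of the mask
#'   size.
#' @param n_sources number of labels `N`; defaults to the mask's `n_sources`
#'   attribute or its maximum.
#' @return integer label matrix of the same shape, every cell in `1..N`,
#'   with attribute `n_sources`.
#' @export
dbrg_segment <- function(mask, R = NULL, n_sources = NULL) {
  n <- n_sources_of(mask, n_sources)
  assert_mask(mask, n)
  H <- nrow(mask); W <- ncol(mask)
  R <- as.integer(R %||% default_radius(c(H, W)))
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)

  sm <- seed_matrices(mask, R, n)
  if (!any(sm$seeds)) {
    warning("no seed pixels at this radius; returning the initial mask")
    out <- mask
    attr(out, "n_sources") <- n
    return(out)
  }

  offs <- disk_offsets(R)
  out <- matrix(0L, H, W)
  # row-major traversal of seed pixels
  rm_order <- as.vector(t(matrix(seq_len(H * W), H, W)))
  seed_order <- rm_order[sm$seeds[rm_order]]

  for (p in seed_order) {
    if (out[p] != 0L) next
    lab <- sm$majority[p]
    out[p] <- lab
    cores <- p
    same <- mask == lab
    repeat {
      reach <- dilate_disk(cores, H, W, R, offs)
      reach <- reach[out[reach] == 0L & same[reach]]
      if (length(reach) == 0L) break
      out[reach] <- lab
      cores <- reach[sm$seeds[reach]]
      if (length(cores) == 0L) break
    }
  }

  if (any(out == 0L)) out <- chebyshev_fill(out)
  attr(out, "n_sources") <- n
  out
}
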