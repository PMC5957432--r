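assert_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix (single-channel image)", arg),
         call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s differ in shape: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

is_color <- function(img) is.array(img) && length(dim(img)) == 3L

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
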