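#' Validate an image grid
#'
#' An image grid is a plain numeric matrix of per-pixel luminance values,
#' nominally in \[0, 1\], finest raster currency of the package.  Row index is
#' the image row (top to bottom), column index the image column.
#'
#' @param x object to validate.
#' @param arg name used in error messages.
#' @return the matrix, invisibly coerced to double storage.
#' @keywords internal
as_image_grid <- function(x, arg = "image") {
  if (is.vector(x) && is.numeric(x) && length(x) == 1L) x <- matrix(x, 1L, 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Clip values to the nominal luminance range
#' @param x numeric matrix or vector.
#' @param lo,hi range bounds.
#' @return clipped object of the same shape.
#' @keywords internal
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Evaluate a function with a temporary RNG state seeded by `seed`, restoring
# the caller's .Random.seed afterwards.  Generators stay pure in their spec.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
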