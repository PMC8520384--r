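# Gaussian / Laplacian pyramid machinery.
#
# Kernel: separable 5-tap binomial [1,4,6,4,1]/16.  It preserves constants,
# and the zero-insertion upsampler convolved with 2x the same kernel also
# preserves constants (the even/odd tap sums are both 1/2).  Boundaries are
# handled by reflect-101 (mirror about the edge sample, no edge duplication),
# which keeps constant preservation exact at the borders even for the
# zero-inserted upsampling grid.

.PYR_KERNEL <- c(1, 4, 6, 4, 1) / 16

#' Reflect-101 index map
#'
#' Maps out-of-range indices into \[1, n\] by mirroring about the first and
#' last sample (period 2n - 2).  For n = 1 every index maps to 1.
#'
#' @param i integer vector of (possibly out-of-range) indices.
#' @param n extent.
#' @return integer vector of in-range indices.
#' @keywords internal
reflect101 <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  m <- (i - 1L) %% p
  ifelse(m < n, m + 1L, p - m + 1L)
}

# Separable 5-tap convolution with reflect-101 boundaries.
# `w` is the 1-D kernel (length 5, offsets -2..2).
conv5 <- function(x, w = .PYR_KERNEL) {
  nr <- nrow(x); nc <- ncol(x)
  # rows
  out <- matrix(0, nr, nc)
  for (d in -2:2) {
    idx <- reflect101(seq_len(nr) + d, nr)
    out <- out + w[d + 3L] * x[idx, , drop = FALSE]
  }
  # columns
  out2 <- matrix(0, nr, nc)
  for (d in -2:2) {
    idx <- reflect101(seq_len(nc) + d, nc)
    out2 <- out2 + w[d + 3L] * out[, idx, drop = FALSE]
  }
  out2
}

# Blur and decimate: keep samples 1, 3, 5, ... in each dimension, giving
# ceil(n/2) samples (the odd-size rule of the pyramid dimension law).
pyr_down <- function(x) {
  g <- conv5(x)
  g[seq(1L, nrow(x), by = 2L), seq(1L, ncol(x), by = 2L), drop = FALSE]
}

# Zero-insertion upsample to an explicit target size (th, tw), followed by
# convolution with twice the kernel.  th must be 2*nrow(x)-1 or 2*nrow(x).
pyr_up <- function(x, th, tw) {
  nr <- nrow(x); nc <- ncol(x)
  if (!(th %in% c(2L * nr - 1L, 2L * nr)) || !(tw %in% c(2L * nc - 1L, 2L * nc))) {
    stop("upsampling target dimensions incompatible with source", call. = FALSE)
  }
  y <- matrix(0, th, tw)
  y[seq(1L, by = 2L, length.out = nr), seq(1L, by = 2L, length.out = nc)] <- x
  conv5(y, 2 * .PYR_KERNEL)
}

new_pyramid <- function(kind, levels) {
  structure(list(kind = kind, levels = levels), class = "img_pyramid")
}

#' @export
print.img_pyramid <- function(x, ...) {
  dims <- vapply(x$levels, function(l) paste(dim(l), collapse = "x"), "")
  cat(sprintf("<%s pyramid, %d level(s): %s>\n", x$kind, length(x$levels),
              paste(dims, collapse = " | ")))
  invisible(x)
}

check_levels <- function(image, n_levels) {
  if (length(n_levels) != 1L || n_levels < 1L || n_levels != round(n_levels)) {
    stop("`n_levels` must be a positive integer", call. = FALSE)
  }
  if (2^(n_levels - 1) > min(dim(image))) {
    stop(sprintf(
      "image of size %dx%d is too small for %d pyramid level(s)",
      nrow(image), ncol(image), n_levels), call. = FALSE)
  }
}

#' Build a Gaussian pyramid
#'
#' Level 0 is the input itself; each coarser level is obtained by blurring
#' with a separable 5-tap binomial kernel (reflect-101 boundaries) and
#' decimating by two, so level l+1 has `ceiling(dim(level l) / 2)` pixels in
#' each dimension.
#'
#' @param image numeric matrix of luminance values.
#' @param n_levels number of levels (>= 1); `2^(n_levels-1)` must not exceed
#'   the smaller image dimension.
#' @return an object of class `img_pyramid` with `kind = "gaussian"` and
#'   `levels`, a list of matrices from finest to coarsest.
#' @seealso [build_laplacian_pyramid()], [collapse_laplacian()]
#' @export
#' @examples
#' g <- build_gaussian_pyramid(matrix(runif(256), 16, 16), 3)
#' sapply(g$levels, dim)   # 16,8,4
build_gaussian_pyramid <- function(image, n_levels) {
  image <- as_image_grid(image)
  check_levels(image, n_levels)
  levels <- vector("list", n_levels)
  levels[[1L]] <- image
  if (n_levels > 1L) {
    for (l in 2:n_levels) levels[[l]] <- pyr_down(levels[[l - 1L]])
  }
  new_pyramid("gaussian", levels)
}

#' Build a Laplacian pyramid
#'
#' Band level l is `G_l - u(G_{l+1})`, where u is the zero-insertion
#' upsampler matched to the downsampling kernel; the coarsest level is the
#' Gaussian residual.  Collapsing the result reproduces the input to
#' floating-point round-off.
#'
#' @inheritParams build_gaussian_pyramid
#' @return an `img_pyramid` with `kind = "laplacian"`.
#' @export
build_laplacian_pyramid <- function(image, n_levels) {
  g <- build_gaussian_pyramid(image, n_levels)
  levels <- g$levels
  if (n_levels > 1L) {
    for (l in 1:(n_levels - 1L)) {
      gl <- g$levels[[l]]
      levels[[l]] <- gl - pyr_up(g$levels[[l + 1L]], nrow(gl), ncol(gl))
    }
  }
  new_pyramid("laplacian", levels)
}

#' Collapse a Laplacian pyramid
#'
#' Recursive coarse-to-fine reconstruction `G_l = L_l + u(G_{l+1})`,
#' returning the level-0 image.
#'
#' @param pyr an `img_pyramid` of kind `"laplacian"`.
#' @return numeric matrix with the dimensions of level 0.
#' @export
collapse_laplacian <- function(pyr) {
  if (!inherits(pyr, "img_pyramid")) stop("`pyr` must be an img_pyramid", call. = FALSE)
  if (!identical(pyr$kind, "laplacian")) {
    stop("collapse_laplacian() requires a laplacian pyramid", call. = FALSE)
  }
  n <- length(pyr$levels)
  g <- pyr$levels[[n]]
  if (n > 1L) {
    for (l in (n - 1L):1L) {
      ll <- pyr$levels[[l]]
      g <- ll + pyr_up(g, nrow(ll), ncol(ll))
    }
  }
  g
}
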