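# Synthetic ultrasound-like phantoms with known ground truth.
#
# The degradation model is the standard desk-scale ultrasound surrogate:
# a clean piecewise-smooth scene multiplied by unit-mean gamma speckle
# (shape parameter = number of "looks"; larger = milder speckle), then
# additive Gaussian sensor noise, clipped to [0, 1].

#' Phantom specification
#'
#' @param size integer vector `c(H, W)`.
#' @param scene `"step"` (left/right two-tone split), `"ellipse-chambers"`
#'   (dark elliptic chambers on a brighter field, an echo-like cartoon), or
#'   `"checkerboard"`.
#' @param tones luminance levels in \[0, 1\]; for `"step"` the left and right
#'   tone, for `"ellipse-chambers"` background then chamber tones, for
#'   `"checkerboard"` the two tile tones.
#' @param speckle_shape shape parameter of unit-mean multiplicative gamma
#'   speckle, or `NULL` for none.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param hole optional mask spec: `list(type = "rect", row, col, height,
#'   width)` or `list(type = "disk", row, col, radius)`.
#' @param tile checkerboard tile size in pixels.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128, 128), scene = c("step", "ellipse-chambers", "checkerboard"),
                         tones = c(0.2, 0.8), speckle_shape = NULL, noise_sd = 0,
                         hole = NULL, tile = 8, seed = 1) {
  scene <- match.arg(scene)
  if (length(size) != 2L || any(size < 1) || any(size != round(size))) {
    stop("`size` must be two positive integers", call. = FALSE)
  }
  if (any(tones < 0 | tones > 1)) stop("`tones` must lie in [0, 1]", call. = FALSE)
  if (!is.null(speckle_shape) && speckle_shape <= 0) {
    stop("`speckle_shape` must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(size = as.integer(size), scene = scene, tones = tones,
                 speckle_shape = speckle_shape, noise_sd = noise_sd,
                 hole = hole, tile = as.integer(tile), seed = seed),
            class = "phantom_spec")
}

#' Generate a speckled phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (degraded), `truth` (clean scene), and `mask`
#'   (logical; the hole, all-`FALSE` when no hole was requested).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(c(64, 64), "step", speckle_shape = 16, seed = 7))
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec", call. = FALSE)
  H <- spec$size[1]; W <- spec$size[2]
  truth <- switch(spec$scene,
    "step" = {
      t <- matrix(spec$tones[2], H, W)
      t[, seq_len(floor(W / 2))] <- spec$tones[1]
      t
    },
    "checkerboard" = {
      ri <- (seq_len(H) - 1L) %/% spec$tile
      ci <- (seq_len(W) - 1L) %/% spec$tile
      par <- outer(ri, ci, function(a, b) (a + b) %% 2L)
      matrix(spec$tones[par + 1L], H, W)
    },
    "ellipse-chambers" = {
      bg <- spec$tones[1]
      ch <- if (length(spec$tones) > 1L) spec$tones[-1L] else rep(0.1, 2L)
      t <- matrix(bg, H, W)
      rows <- matrix(seq_len(H), H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      centres <- list(c(0.35, 0.35, 0.22, 0.16), c(0.35, 0.70, 0.18, 0.14),
                      c(0.72, 0.40, 0.20, 0.20), c(0.72, 0.75, 0.16, 0.13))
      for (i in seq_along(centres)) {
        cc <- centres[[i]]
        inside <- ((rows - cc[1] * H) / (cc[3] * H))^2 +
          ((cols - cc[2] * W) / (cc[4] * W))^2 <= 1
        t[inside] <- ch[(i - 1L) %% length(ch) + 1L]
      }
      t
    })
  image <- with_seed(spec$seed, {
    img <- truth
    if (!is.null(spec$speckle_shape)) {
      img <- img * matrix(rgamma(H * W, shape = spec$speckle_shape,
                                 rate = spec$speckle_shape), H, W)
    }
    if (spec$noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    clip01(img)
  })
  mask <- hole_mask(spec$hole, H, W)
  list(image = image, truth = truth, mask = mask)
}

hole_mask <- function(hole, H, W) {
  m <- matrix(FALSE, H, W)
  if (is.null(hole)) return(m)
  if (identical(hole$type, "rect")) {
    r2 <- hole$row + hole$height - 1L; c2 <- hole$col + hole$width - 1L
    if (hole$row < 1L || hole$col < 1L || r2 > H || c2 > W) {
      stop("hole exceeds image bounds", call. = FALSE)
    }
    m[hole$row:r2, hole$col:c2] <- TRUE
  } else if (identical(hole$type, "disk")) {
    if (hole$row - hole$radius < 1 || hole$row + hole$radius > H ||
        hole$col - hole$radius < 1 || hole$col + hole$radius > W) {
      stop("hole exceeds image bounds", call. = FALSE)
    }
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    m <- (rows - hole$row)^2 + (cols - hole$col)^2 <= hole$radius^2
  } else {
    stop("unknown hole type; use \"rect\" or \"disk\"", call. = FALSE)
  }
  m
}
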