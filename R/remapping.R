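# Point-wise nonlinear remapping and the variance-adaptive parameter fields.

#' Point-wise nonlinear detail remapping
#'
#' The mapping applied to every pixel before each pyramid band is extracted:
#' \deqn{r(i) = i - m_f (i - g)\, e^{-(i-g)^2 / 2\sigma_r^2}}
#' where `g` is the Gaussian-pyramid coefficient at the corresponding
#' position and scale, `sigma_r` the contour discrimination threshold, and
#' `m_f` the amplitude factor.  Intensities within about `sigma_r` of `g`
#' (local detail / speckle) are pulled toward `g`; for `|i - g| >> sigma_r`
#' (genuine contours) the map approaches the identity, which is what makes
#' the smoothing edge-preserving.  `m_f = 0` is the identity;
#' `m_f` in (0, 1] smooths.
#'
#' @param i numeric vector or matrix of luminance values.
#' @param g reference coefficient (scalar or same shape as `i`).
#' @param sigma_r contour discrimination threshold, > 0.
#' @param m_f amplitude factor (scalar or same shape as `i`).
#' @return remapped values, same shape as `i`.
#' @export
#' @examples
#' remap(0.6, g = 0.5, sigma_r = 0.1, m_f = 1)  # 0.6 - 0.1*exp(-0.5)
remap <- function(i, g, sigma_r, m_f) {
  if (any(sigma_r <= 0)) stop("`sigma_r` must be > 0", call. = FALSE)
  d <- i - g
  i - m_f * d * exp(-d^2 / (2 * sigma_r^2))
}

#' Local variance field
#'
#' Population variance (divide by n) of the intensities in the mirror-padded
#' (2k+1) x (2k+1) window centred at every pixel, the local-change field
#' driving the adaptive parameters.  Mirror padding is reflect-101, matching
#' the pyramid boundary rule.
#'
#' @param image numeric matrix.
#' @param k window half-width, integer >= 1.
#' @return matrix of the same dimensions, all values >= 0.
#' @export
local_variance <- function(image, k) {
  image <- as_image_grid(image)
  if (length(k) != 1L || k < 1L || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  m1 <- box_mean(image, k)
  m2 <- box_mean(image^2, k)
  pmax(m2 - m1^2, 0)
}

# Separable box mean over a (2k+1)^2 reflect-101-padded window.
box_mean <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (d in -k:k) out <- out + x[reflect101(seq_len(nr) + d, nr), , drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (d in -k:k) out2 <- out2 + out[, reflect101(seq_len(nc) + d, nc), drop = FALSE]
  out2 / (2 * k + 1)^2
}

#' Variance-adaptive parameter fields
#'
#' Converts the local-variance field into per-pixel remapping parameters.
#' The contour threshold must fall where local change is large (so contours
#' are not smoothed over); a saturating inverse form avoids the blow-up of a
#' plain reciprocal on flat regions:
#' \deqn{\sigma_{ra}(p) = \sigma_0 \bar V / (\bar V + V(p)), \qquad
#'       m_{fa}(p) = m_0\, \sigma_{ra}(p) / \sigma_0}
#' with \eqn{\bar V} the image mean of V plus 1e-12.  Both fields are
#' strictly decreasing in V(p); at V = 0 the full strength
#' (\eqn{\sigma_0, m_0}) applies, at \eqn{V = \bar V} exactly half.
#'
#' @param V local-variance field from [local_variance()].
#' @param base_sigma base contour threshold \eqn{\sigma_0 > 0}.
#' @param base_mf base amplitude factor \eqn{m_0}.
#' @return list with elements `sigma_ra`, `m_fa` (matrices), `base_sigma`,
#'   `base_mf`, and `vbar`.
#' @export
adaptive_fields <- function(V, base_sigma, base_mf) {
  V <- as_image_grid(V, "V")
  if (any(V < 0)) stop("`V` must be nonnegative", call. = FALSE)
  if (length(base_sigma) != 1L || base_sigma <= 0) {
    stop("`base_sigma` must be a positive scalar", call. = FALSE)
  }
  vbar <- mean(V) + 1e-12
  sigma_ra <- base_sigma * vbar / (vbar + V)
  list(sigma_ra = sigma_ra,
       m_fa = base_mf * sigma_ra / base_sigma,
       base_sigma = base_sigma, base_mf = base_mf, vbar = vbar)
}
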