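# Multi-scale edge-preserving filter (Steps 1-4) and the structure/texture
# decomposition that feeds the inpainting stage.
#
# Reference semantics, per band coefficient (l, x, y): take the Gaussian
# coefficient g = G_l[x, y], remap the *input* image point-wise with
# (g, sigma_r, m_f), build the remapped image's Laplacian pyramid, and keep
# its level-l coefficient at (x, y).  The coarsest Gaussian residual is
# copied unchanged and the assembled pyramid is collapsed.  The default
# "window" method evaluates only the sub-window of the input that can
# influence each coefficient (in compiled code) and is exactly equivalent
# up to floating-point round-off; the "exhaustive" method is the literal
# per-coefficient reference, tractable for small images.

#' Filter configuration
#'
#' @param n_levels number of pyramid levels (>= 1).
#' @param base_sigma base contour discrimination threshold \eqn{\sigma_0}
#'   (luminance units, > 0).  Intensity excursions of this order around the
#'   local Gaussian coefficient are treated as detail and smoothed.
#' @param base_mf base amplitude factor \eqn{m_0} in \[0, 1\]; 0 disables the
#'   remapping (identity filter).
#' @param adaptive if `TRUE`, per-pixel parameters are derived from the
#'   local-variance field via [adaptive_fields()]; if `FALSE` the base
#'   scalars are used everywhere.
#' @param k half-width of the local-variance window (used when
#'   `adaptive = TRUE`).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(n_levels = 3, base_sigma = 0.15, base_mf = 1,
                          adaptive = FALSE, k = 2) {
  if (length(n_levels) != 1L || n_levels < 1L || n_levels != round(n_levels)) {
    stop("`n_levels` must be a positive integer", call. = FALSE)
  }
  if (base_sigma <= 0) stop("`base_sigma` must be > 0", call. = FALSE)
  if (base_mf < 0 || base_mf > 1) stop("`base_mf` must lie in [0, 1]", call. = FALSE)
  if (k < 1L || k != round(k)) stop("`k` must be a positive integer", call. = FALSE)
  structure(list(n_levels = as.integer(n_levels), base_sigma = base_sigma,
                 base_mf = base_mf, adaptive = isTRUE(adaptive),
                 k = as.integer(k)),
            class = "filter_config")
}

# 2x2 block mean with ceil-halving (trailing odd row/col replicated so the
# last block still averages real cells); brings the full-resolution adaptive
# fields down to the grid of each pyramid level.
downsample_box <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[pmin(seq_len(nr + nr %% 2L), nr), pmin(seq_len(nc + nc %% 2L), nc), drop = FALSE]
  o <- seq(1L, nrow(xp), by = 2L); e <- o + 1L
  oc <- seq(1L, ncol(xp), by = 2L); ec <- oc + 1L
  (xp[o, oc, drop = FALSE] + xp[e, oc, drop = FALSE] +
     xp[o, ec, drop = FALSE] + xp[e, ec, drop = FALSE]) / 4
}

# Per-band-level parameter fields (list index l = pyramid subscript l-1),
# each a matrix with the dimensions of the corresponding Gaussian level.
level_param_fields <- function(image, cfg, gauss) {
  n <- cfg$n_levels
  sig <- vector("list", max(n - 1L, 0L))
  mf <- vector("list", max(n - 1L, 0L))
  if (n == 1L) return(list(sigma = sig, mf = mf))
  if (cfg$adaptive) {
    af <- adaptive_fields(local_variance(image, cfg$k), cfg$base_sigma, cfg$base_mf)
    s_full <- af$sigma_ra; m_full <- af$m_fa
    for (l in seq_len(n - 1L)) {
      sig[[l]] <- s_full; mf[[l]] <- m_full
      stopifnot(all(dim(s_full) == dim(gauss$levels[[l]])))
      s_full <- downsample_box(s_full); m_full <- downsample_box(m_full)
    }
  } else {
    for (l in seq_len(n - 1L)) {
      d <- dim(gauss$levels[[l]])
      sig[[l]] <- matrix(cfg$base_sigma, d[1L], d[2L])
      mf[[l]] <- matrix(cfg$base_mf, d[1L], d[2L])
    }
  }
  list(sigma = sig, mf = mf)
}

#' Multi-scale edge-preserving filter
#'
#' Smooths texture and speckle while preserving contours by remapping the
#' image once per Laplacian-pyramid coefficient around that coefficient's
#' Gaussian value (see [remap()]), then collapsing the assembled output
#' pyramid.  Output is clipped to \[0, 1\].
#'
#' @param image numeric matrix of luminance values in \[0, 1\].
#' @param cfg a [filter_config()].
#' @param method `"window"` (compiled sub-window evaluation, the default) or
#'   `"exhaustive"` (literal per-coefficient reference; small images only).
#' @return filtered image, same dimensions, values in \[0, 1\].
#' @export
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' sm <- multiscale_filter(img, filter_config(n_levels = 2, base_sigma = 0.2))
multiscale_filter <- function(image, cfg, method = c("window", "exhaustive")) {
  image <- as_image_grid(image)
  if (!inherits(cfg, "filter_config")) stop("`cfg` must be a filter_config", call. = FALSE)
  method <- match.arg(method)
  check_levels(image, cfg$n_levels)
  n <- cfg$n_levels
  gauss <- build_gaussian_pyramid(image, n)
  if (n == 1L) return(clip01(image))
  fields <- level_param_fields(image, cfg, gauss)
  bands <- if (method == "window") {
    local_laplacian_bands(image, gauss$levels, fields$sigma, fields$mf)
  } else {
    exhaustive_bands(image, gauss, fields)
  }
  pyr <- new_pyramid("laplacian", c(bands, gauss$levels[n]))
  clip01(collapse_laplacian(pyr))
}

# Literal reference: one full remapped pyramid per output coefficient.
exhaustive_bands <- function(image, gauss, fields) {
  n <- length(gauss$levels)
  bands <- vector("list", n - 1L)
  for (l in seq_len(n - 1L)) {
    gl <- gauss$levels[[l]]
    out <- matrix(0, nrow(gl), ncol(gl))
    for (x in seq_len(nrow(gl))) {
      for (y in seq_len(ncol(gl))) {
        r <- remap(image, gl[x, y], fields$sigma[[l]][x, y], fields$mf[[l]][x, y])
        gr <- r
        for (j in seq_len(l - 1L)) gr <- pyr_down(gr)
        band <- gr - pyr_up(pyr_down(gr), nrow(gr), ncol(gr))
        out[x, y] <- band[x, y]
      }
    }
    bands[[l]] <- out
  }
  bands
}

#' Structure/texture decomposition
#'
#' `structure` is the multi-scale filtered image; `texture` is the exact
#' residual `image - structure`, so the two components always add back to
#' the input.
#'
#' @inheritParams multiscale_filter
#' @return an object of class `decomposition`: list with `structure` and
#'   `texture` matrices.
#' @export
decompose <- function(image, cfg, method = c("window", "exhaustive")) {
  image <- as_image_grid(image)
  s <- multiscale_filter(image, cfg, method)
  structure(list(structure = s, texture = image - s), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<structure/texture decomposition, %dx%d; texture sd %.4g>\n",
              nrow(x$structure), ncol(x$structure), stats::sd(x$texture)))
  invisible(x)
}

#' Read a filter configuration from a JSON file
#'
#' Accepts keys `n_levels`, `sigma0`, `mf0`, `adaptive`, `k`; missing keys
#' fall back to the [filter_config()] defaults.
#'
#' @param path path to a JSON file.
#' @return a `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("reading JSON configs requires the 'jsonlite' package", call. = FALSE)
  }
  j <- jsonlite::fromJSON(path)
  d <- filter_config()
  filter_config(n_levels = j$n_levels %||% d$n_levels,
                base_sigma = j$sigma0 %||% d$base_sigma,
                base_mf = j$mf0 %||% d$base_mf,
                adaptive = j$adaptive %||% d$adaptive,
                k = j$k %||% d$k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
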