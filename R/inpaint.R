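# Exemplar-based (sample-block-matching) restoration of masked regions.
#
# Greedy front-driven fill in the style of exemplar inpainting: at each step
# the fill-front pixel with the largest priority C(p) * D(p) is chosen, the
# best-matching fully-known source block is located by masked SSD, and its
# pixels are copied into the unknown part of the target block.  The data
# term D is computed on the *structure* component of the image (the
# edge-preserving smoothed image), so the fill is guided along the main
# structural contours rather than along texture or speckle.

EPS_DATA <- 1e-3  # keeps flat regions fillable (D > 0 everywhere)

#' Initialise inpainting bookkeeping
#'
#' @param image numeric matrix of luminance values.
#' @param mask logical (or 0/1) matrix, `TRUE`/nonzero marking pixels to
#'   repair.
#' @param k patch half-width; patches are (2k+1) x (2k+1).
#' @return an object of class `inpaint_state`: list with `filled` (working
#'   image), `mask` (current unknown set), `mask0` (original unknown set),
#'   `confidence`, and `k`.
#' @export
inpaint_state <- function(image, mask, k = 4) {
  image <- as_image_grid(image)
  mask <- as_mask(mask, dim(image))
  if (!any(mask)) stop("`mask` marks no pixels to repair", call. = FALSE)
  if (all(mask)) stop("`mask` covers the entire image; nothing known to copy from", call. = FALSE)
  if (k < 1L || k != round(k)) stop("`k` must be a positive integer", call. = FALSE)
  structure(list(filled = image, mask = mask, mask0 = mask,
                 confidence = ifelse(mask, 0, 1), k = as.integer(k)),
            class = "inpaint_state")
}

as_mask <- function(mask, dims) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical or numeric matrix", call. = FALSE)
  }
  if (!all(dim(mask) == dims)) stop("`mask` dimensions must match the image", call. = FALSE)
  mask
}

# Fill front: unknown pixels 4-adjacent to at least one known pixel.
front_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  known <- !mask
  adj <- matrix(FALSE, nr, nc)
  adj[-1, ] <- adj[-1, ] | known[-nr, ]
  adj[-nr, ] <- adj[-nr, ] | known[-1, ]
  adj[, -1] <- adj[, -1] | known[, -nc]
  adj[, -nc] <- adj[, -nc] | known[, -1]
  which(mask & adj, arr.ind = TRUE)
}

#' Fill priority of a front pixel
#'
#' `P(p) = C(p) * D(p)`: `C(p)` is the mean confidence of the known pixels'
#' confidences over the (2k+1)^2 patch (in-image part), and
#' `D(p) = |isophote(S, p) . n(p)| + eps` with the isophote (gradient
#' rotated 90 degrees) taken on the structure image `S` and `n` the unit
#' normal of the fill front estimated by central differences on the mask.
#'
#' @param state an [inpaint_state()].
#' @param structure structure image (same dimensions) used for the data term.
#' @param p integer vector `c(row, col)` of a pixel on the fill front.
#' @return scalar priority > 0.
#' @export
inpaint_priority <- function(state, structure, p) {
  if (!inherits(state, "inpaint_state")) stop("`state` must be an inpaint_state", call. = FALSE)
  fr <- front_pixels(state$mask)
  if (!any(fr[, 1] == p[1] & fr[, 2] == p[2])) {
    stop("`p` is not on the fill front", call. = FALSE)
  }
  conf_term(state, p[1], p[2]) * data_term(structure, state$mask, p[1], p[2])
}

conf_term <- function(state, r, c) {
  k <- state$k
  nr <- nrow(state$filled); nc <- ncol(state$filled)
  rows <- max(1L, r - k):min(nr, r + k)
  cols <- max(1L, c - k):min(nc, c + k)
  mean(state$confidence[rows, cols])
}

grad_central <- function(x, r, c) {
  nr <- nrow(x); nc <- ncol(x)
  gr <- (x[min(r + 1L, nr), c] - x[max(r - 1L, 1L), c]) / 2
  gc <- (x[r, min(c + 1L, nc)] - x[r, max(c - 1L, 1L)]) / 2
  c(gr, gc)
}

data_term <- function(structure, mask, r, c) {
  gS <- grad_central(structure, r, c)
  iso <- c(-gS[2], gS[1])                     # isophote: gradient rotated 90 deg
  gm <- grad_central(mask + 0, r, c)          # front normal from the mask
  nn <- sqrt(sum(gm^2))
  if (nn == 0) return(EPS_DATA)
  abs(sum(iso * (gm / nn))) + EPS_DATA
}

#' Best-matching source block by masked SSD
#'
#' Scans every fully-known candidate block centre (patch entirely inside the
#' image and free of originally-masked pixels) and returns the centre whose
#' block minimises the sum of squared differences with the target patch,
#' computed only over the target's currently-known pixels (point-wise
#' product with the known-pixel indicator).  Ties break by scan order:
#' smallest row, then smallest column.  A target patch with no known pixel
#' has SSD 0 against every candidate, so the first candidate in scan order
#' is returned.
#'
#' @param state an [inpaint_state()].
#' @param center integer vector `c(row, col)` of the target patch centre.
#' @return list with `center` (row, col of the best source) and `ssd`.
#' @export
inpaint_best_match <- function(state, center) {
  k <- state$k
  img <- state$filled
  nr <- nrow(img); nc <- ncol(img)
  valid <- valid_candidates(state$mask0, k)
  if (!any(valid)) stop("no fully-known source block exists; region unfillable", call. = FALSE)
  ch <- nr - 2L * k; cw <- nc - 2L * k      # candidate-centre grid extents
  ssd <- matrix(0, ch, cw)
  r0 <- center[1]; c0 <- center[2]
  for (du in -k:k) {
    tr <- r0 + du
    if (tr < 1L || tr > nr) next
    for (dv in -k:k) {
      tc <- c0 + dv
      if (tc < 1L || tc > nc) next
      if (state$mask[tr, tc]) next          # unknown target pixel: no data term
      tval <- img[tr, tc]
      block <- img[(k + 1L + du):(nr - k + du), (k + 1L + dv):(nc - k + dv), drop = FALSE]
      ssd <- ssd + (block - tval)^2
    }
  }
  ssd[!valid] <- Inf
  best <- unname(arg_min_scan(ssd))
  list(center = c(best[1] + k, best[2] + k), ssd = ssd[best[1], best[2]])
}

# candidate validity: (2k+1)^2 block inside the image with no original-mask
# pixel; computed once per state via a box sum over the mask
valid_candidates <- function(mask0, k) {
  cnt <- box_mean(mask0 + 0, k) * (2 * k + 1)^2
  ch <- nrow(mask0) - 2L * k; cw <- ncol(mask0) - 2L * k
  if (ch < 1L || cw < 1L) {
    stop("image too small for the requested patch size", call. = FALSE)
  }
  cnt[(k + 1L):(nrow(mask0) - k), (k + 1L):(ncol(mask0) - k), drop = FALSE] < 0.5
}

# arg-min with scan-order (row-major) tie-break: smallest row, then column
arg_min_scan <- function(x) {
  mn <- min(x)
  hits <- which(x == mn, arr.ind = TRUE)
  hits[order(hits[, 1], hits[, 2])[1L], ]
}

# Harmonic (Laplace) infill of the masked region from its boundary values:
# Jacobi iterations of the 4-neighbour mean, known pixels held fixed.  Used
# only to neutralise the arbitrary content inside the hole before the
# structure component driving the priorities is extracted; the copied fill
# itself never uses these values.
harmonic_init <- function(image, mask, tol = 1e-6, max_iter = 2000L) {
  x <- image
  x[mask] <- mean(image[!mask])
  nr <- nrow(x); nc <- ncol(x)
  up <- function(m) m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- function(m) m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- function(m) m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  for (it in seq_len(max_iter)) {
    avg <- (up(x) + dn(x) + lf(x) + rt(x)) / 4
    delta <- max(abs(avg[mask] - x[mask]))
    x[mask] <- avg[mask]
    if (delta < tol) break
  }
  x
}

#' Structure-guided exemplar inpainting
#'
#' Repairs the masked region by repeated block copying: the masked region is
#' first harmonically initialised from its boundary, the structure component
#' of that image is extracted once with [decompose()], and the fill front is
#' then processed in order of decreasing priority (confidence times
#' structural data term), each step copying the unknown pixels of the target
#' block from the best-matching fully-known block ([inpaint_best_match()]).
#' Known pixels are never rewritten, and copied values always come from
#' never-masked source blocks of the original image.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param mask logical/numeric matrix, nonzero = repair.
#' @param k patch half-width (default 4, i.e. 9x9 blocks).
#' @param cfg [filter_config()] used to extract the structure component.
#' @param trace if `TRUE`, also return the order in which front pixels were
#'   chosen.
#' @return the completed image, or if `trace = TRUE` a list with elements
#'   `image`, `order` (matrix of chosen front centres, fill order), and
#'   `structure`.
#' @export
inpaint_image <- function(image, mask, k = 4, cfg = filter_config(), trace = FALSE) {
  state <- inpaint_state(image, mask, k)
  S <- decompose(harmonic_init(state$filled, state$mask0), cfg)$structure
  order_log <- NULL
  while (any(state$mask)) {
    fr <- front_pixels(state$mask)
    if (nrow(fr) == 0L) stop("fill front is empty but unknown pixels remain", call. = FALSE)
    pr <- numeric(nrow(fr))
    for (i in seq_len(nrow(fr))) {
      pr[i] <- conf_term(state, fr[i, 1], fr[i, 2]) *
        data_term(S, state$mask, fr[i, 1], fr[i, 2])
    }
    ord <- order(-pr, fr[, 1], fr[, 2])[1L]
    p <- fr[ord, ]
    if (trace) order_log <- rbind(order_log, p)
    cp <- conf_term(state, p[1], p[2])
    src <- inpaint_best_match(state, p)$center
    state <- fill_patch(state, p, src, cp)
  }
  if (trace) {
    rownames(order_log) <- NULL
    list(image = state$filled, order = order_log, structure = S)
  } else {
    state$filled
  }
}

# copy source block pixels into the unknown positions of the target block
fill_patch <- function(state, p, src, cp) {
  k <- state$k
  nr <- nrow(state$filled); nc <- ncol(state$filled)
  for (du in -k:k) {
    tr <- p[1] + du
    if (tr < 1L || tr > nr) next
    for (dv in -k:k) {
      tc <- p[2] + dv
      if (tc < 1L || tc > nc) next
      if (!state$mask[tr, tc]) next
      state$filled[tr, tc] <- state$filled[src[1] + du, src[2] + dv]
      state$confidence[tr, tc] <- cp
      state$mask[tr, tc] <- FALSE
    }
  }
  state
}
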