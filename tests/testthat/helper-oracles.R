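# Independent brute-force oracles used to check the package's fast paths.
# Everything here is deliberately naive (double loops, full enumeration) and
# shares no code with the implementation beyond the reflect-101 boundary
# convention, which is part of the contract being checked.

rand_img <- function(h, w = h) matrix(runif(h * w), h, w)

# reflect-101 index (triangle wave with period 2n-2)
refl_idx <- function(i, n) {
  if (n == 1L) return(1L)
  p <- 2L * n - 2L
  m <- (i - 1L) %% p
  if (m < n) m + 1L else p - m + 1L
}

# population variance over the mirror-padded (2k+1)^2 window, double loop
naive_local_variance <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- numeric((2 * k + 1)^2)
      q <- 0L
      for (dr in -k:k) {
        for (dc in -k:k) {
          q <- q + 1L
          vals[q] <- img[refl_idx(r + dr, nr), refl_idx(c + dc, nc)]
        }
      }
      out[r, c] <- mean((vals - mean(vals))^2)
    }
  }
  out
}

# naive separable 5-tap convolution, double loop
naive_conv5 <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  t1 <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (d in -2:2) acc <- acc + w[d + 3] * x[refl_idx(r + d, nr), c]
    t1[r, c] <- acc
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (d in -2:2) acc <- acc + w[d + 3] * t1[r, refl_idx(c + d, nc)]
    out[r, c] <- acc
  }
  out
}

naive_down <- function(x) {
  g <- naive_conv5(x, c(1, 4, 6, 4, 1) / 16)
  g[seq(1, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]
}

naive_up <- function(x, th, tw) {
  y <- matrix(0, th, tw)
  y[seq(1, by = 2, length.out = nrow(x)), seq(1, by = 2, length.out = ncol(x))] <- x
  naive_conv5(y, 2 * c(1, 4, 6, 4, 1) / 16)
}

# naive per-coefficient multiscale filter (fixed scalar parameters)
naive_multiscale <- function(img, n_levels, sigma0, mf0) {
  gauss <- list(img)
  for (l in 2:n_levels) gauss[[l]] <- naive_down(gauss[[l - 1]])
  bands <- vector("list", n_levels - 1)
  for (l in seq_len(n_levels - 1)) {
    gl <- gauss[[l]]
    out <- matrix(0, nrow(gl), ncol(gl))
    for (x in seq_len(nrow(gl))) for (y in seq_len(ncol(gl))) {
      d <- img - gl[x, y]
      r <- img - mf0 * d * exp(-d^2 / (2 * sigma0^2))
      gr <- r
      for (j in seq_len(l - 1)) gr <- naive_down(gr)
      band <- gr - naive_up(naive_down(gr), nrow(gr), ncol(gr))
      out[x, y] <- band[x, y]
    }
    bands[[l]] <- out
  }
  g <- gauss[[n_levels]]
  for (l in (n_levels - 1):1) g <- bands[[l]] + naive_up(g, nrow(bands[[l]]), ncol(bands[[l]]))
  pmin(pmax(g, 0), 1)
}

# brute-force masked-SSD argmin over all fully-known candidate centres
brute_best_match <- function(img, mask_orig, mask_now, center, k) {
  nr <- nrow(img); nc <- ncol(img)
  best <- NULL
  for (rr in (k + 1):(nr - k)) {
    for (cc in (k + 1):(nc - k)) {
      if (any(mask_orig[(rr - k):(rr + k), (cc - k):(cc + k)])) next
      ssd <- 0
      for (du in -k:k) for (dv in -k:k) {
        tr <- center[1] + du; tc <- center[2] + dv
        if (tr < 1 || tr > nr || tc < 1 || tc > nc || mask_now[tr, tc]) next
        ssd <- ssd + (img[rr + du, cc + dv] - img[tr, tc])^2
      }
      if (is.null(best) || ssd < best$ssd) best <- list(center = c(rr, cc), ssd = ssd)
    }
  }
  best
}

# AUC as the pairwise concordance fraction (ties counted one half)
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by enumeration of all assignments (no ties)
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  sums <- combn(N, n1, FUN = sum)
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

# Fisher two-sided p by direct enumeration with factorials
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  prob <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
          lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) - lfactorial(d))
  }
  ps <- vapply(0:min(r1, c1), prob, 0)
  ps <- ps[!is.na(ps)]
  p0 <- prob(tab[1, 1])
  sum(ps[ps <= p0 * (1 + 1e-7)])
}

# fixed-seed step phantom with uniform additive noise, used by several tests
step_phantom <- function(n = 128, seed = 11, lo = 0.2, hi = 0.8, amp = 0.05) {
  truth <- matrix(hi, n, n)
  truth[, seq_len(n %/% 2)] <- lo
  noise <- matrix(0, n, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  noise[] <- runif(n * n, -amp, amp)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(truth = truth, image = pmin(pmax(truth + noise, 0), 1))
}
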