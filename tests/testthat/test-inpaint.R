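make_hole <- function(n, r0, c0, h, w) {
  m <- matrix(FALSE, n, n); m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE; m
}

test_that("state bookkeeping: confidence, front, and contract errors", {
  img <- matrix(0.5, 12, 12)
  m <- make_hole(12, 5, 5, 4, 4)
  st <- inpaint_state(img, m, k = 2)
  expect_equal(unique(st$confidence[m]), 0)
  expect_equal(unique(st$confidence[!m]), 1)
  expect_error(inpaint_state(img, matrix(FALSE, 12, 12), 2), "no pixels")
  expect_error(inpaint_state(img, matrix(TRUE, 12, 12), 2), "entire image")
  S <- matrix(0.5, 12, 12)
  expect_error(inpaint_priority(st, S, c(6, 6)), "front")  # interior of hole
})

test_that("priority: confidence fraction, flat-structure floor, edge maximality", {
  img <- matrix(0.5, 15, 15)
  m <- make_hole(15, 6, 6, 5, 5)
  st <- inpaint_state(img, m, k = 2)
  S <- matrix(0.5, 15, 15)
  # corner front pixel: 5x5 patch has 9 hole pixels -> C = 16/25
  p_corner <- inpaint_priority(st, S, c(6, 6))
  expect_equal(p_corner, (16 / 25) * 1e-3, tolerance = 1e-12)
  # flat structure: data term is exactly the epsilon floor everywhere
  p_side <- inpaint_priority(st, S, c(6, 8))
  expect_equal(p_side / (10 / 25), 1e-3, tolerance = 1e-12)
  # a vertical tone edge crossing a horizontal front maximises the data term
  tone <- matrix(0.2, 15, 15); tone[, 8:15] <- 0.8
  top <- cbind(6, 6:10)                     # the horizontal top front row
  d <- apply(top, 1, function(p)
    inpaint_priority(st, tone, p) / echorestore:::conf_term(st, p[1], p[2]))
  expect_true(top[which.max(d), 2] %in% c(7, 8))  # where the edge crosses
})

test_that("best match equals the brute-force masked-SSD oracle", {
  set.seed(31)
  for (i in 1:10) {
    img <- rand_img(20)
    r0 <- sample(4:12, 1); c0 <- sample(4:12, 1)
    m <- make_hole(20, r0, c0, 5, 5)
    imgh <- img; imgh[m] <- 0
    st <- inpaint_state(imgh, m, k = 2)
    for (tgt in list(c(r0, c0), c(r0, c0 + 2), c(r0 + 4, c0 + 4))) {
      got <- inpaint_best_match(st, tgt)
      want <- brute_best_match(imgh, m, m, tgt, 2)
      expect_equal(got$center, unname(want$center))
      expect_equal(got$ssd, want$ssd, tolerance = 1e-12)
    }
  }
})

test_that("ties break by scan order; empty-support targets return the first candidate", {
  img <- matrix(0.7, 16, 16)
  m <- make_hole(16, 7, 7, 3, 3)
  st <- inpaint_state(img, m, k = 2)
  got <- inpaint_best_match(st, c(7, 7))
  expect_equal(got$center, c(3, 3))   # first fully-known centre in scan order
  expect_equal(got$ssd, 0)
  # fully-unknown target patch: SSD 0 over empty support for all candidates
  m2 <- make_hole(16, 6, 6, 5, 5)
  img2 <- rand_img(16); img2[m2] <- 0
  st2 <- inpaint_state(img2, m2, k = 2)
  got2 <- inpaint_best_match(st2, c(8, 8))
  expect_equal(got2$ssd, 0)
  expect_equal(got2$center, c(3, 3))
})

test_that("constant image fills exactly and known pixels are preserved bitwise", {
  img <- matrix(0.7, 24, 24)
  m <- make_hole(24, 10, 9, 5, 6)
  imgh <- img; imgh[m] <- 0
  out <- inpaint_image(imgh, m, k = 3, cfg = filter_config(n_levels = 2))
  expect_true(all(out == 0.7))
  set.seed(33)
  img <- rand_img(24)
  imgh <- img; imgh[m] <- 0
  out <- inpaint_image(imgh, m, k = 3, cfg = filter_config(n_levels = 2))
  expect_identical(out[!m], imgh[!m])
  # copy-only fill: values stay inside the observed source range
  expect_gte(min(out), min(imgh[!m]))
  expect_lte(max(out), max(imgh[!m]))
})

test_that("a hole straddling a straight edge is restored with the right tones", {
  tt <- matrix(0.75, 64, 64); tt[, 1:32] <- 0.25
  m <- make_hole(64, 28, 28, 10, 10)
  img <- tt; img[m] <- 0
  out <- inpaint_image(img, m, k = 4, cfg = filter_config(n_levels = 3))
  wrong <- sum((out[m] > 0.5) != (tt[m] > 0.5))
  expect_lte(wrong / sum(m), 0.02)
})

test_that("structure guidance fills the edge crossing before flat front pixels", {
  tt <- matrix(0.75, 40, 40); tt[, 1:20] <- 0.25
  m <- make_hole(40, 16, 16, 9, 9)    # hole straddles the tone boundary
  img <- tt; img[m] <- 0
  res <- inpaint_image(img, m, k = 3, cfg = filter_config(n_levels = 2),
                       trace = TRUE)
  first <- res$order[1, ]
  # the first filled centre sits on the tone boundary columns of the front
  expect_true(first[2] %in% 19:22)
  expect_lt(max(abs(res$image[m] - tt[m])), 0.26)
})

test_that("unfillable configurations raise errors", {
  img <- rand_img(9)
  m <- matrix(TRUE, 9, 9); m[5, 5] <- FALSE   # no fully-known 5x5 patch
  expect_error(inpaint_image(img, m, k = 2, cfg = filter_config(n_levels = 1)),
               "unfillable")
})
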