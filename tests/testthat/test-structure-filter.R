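test_that("identity limits: m0 = 0 and constant inputs reproduce the input", {
  set.seed(5)
  for (i in 1:4) {
    img <- rand_img(sample(8:24, 1), sample(8:24, 1))
    out <- multiscale_filter(img, filter_config(n_levels = 2, base_mf = 0))
    expect_lt(max(abs(out - img)), 1e-10)
  }
  cimg <- matrix(0.55, 20, 16)
  out <- multiscale_filter(cimg, filter_config(n_levels = 3, base_mf = 1))
  expect_equal(max(abs(out - cimg)), 0)
})

test_that("window method equals the exhaustive per-coefficient reference", {
  set.seed(6)
  cfgs <- list(filter_config(n_levels = 2, base_sigma = 0.15, base_mf = 1),
               filter_config(n_levels = 3, base_sigma = 0.25, base_mf = 0.7),
               filter_config(n_levels = 2, base_sigma = 0.1, base_mf = 1,
                             adaptive = TRUE, k = 2))
  for (dims in list(c(8, 8), c(11, 14))) {
    img <- rand_img(dims[1], dims[2])
    for (cfg in cfgs) {
      if (2^(cfg$n_levels - 1) > min(dims)) next
      expect_lt(max(abs(multiscale_filter(img, cfg, "window") -
                          multiscale_filter(img, cfg, "exhaustive"))), 1e-10)
    }
  }
})

test_that("exhaustive reference agrees with an all-naive recomputation on 8x8", {
  set.seed(8)
  img <- rand_img(8)
  got <- multiscale_filter(img, filter_config(n_levels = 2, base_sigma = 0.2,
                                              base_mf = 0.9), "exhaustive")
  expect_lt(max(abs(got - naive_multiscale(img, 2, 0.2, 0.9))), 1e-10)
})

test_that("the filter smooths flat regions while keeping the step contrast", {
  ph <- step_phantom(64, seed = 11)
  cfg <- filter_config(n_levels = 3, base_sigma = 0.15, base_mf = 1)
  out <- multiscale_filter(ph$image, cfg)
  left <- 1:28; right <- 37:64
  vin <- var(as.vector(ph$image[, left])) + var(as.vector(ph$image[, right]))
  vout <- var(as.vector(out[, left])) + var(as.vector(out[, right]))
  expect_lt(vout, vin)
  cin <- mean(ph$image[, right]) - mean(ph$image[, left])
  cout <- mean(out[, right]) - mean(out[, left])
  expect_lt(abs(cout - cin) / cin, 0.10)
})

test_that("raising m0 never increases flat-region variance on the step phantom", {
  ph <- step_phantom(64, seed = 13)
  left <- 1:28; right <- 37:64
  flatvar <- vapply(c(0, 0.5, 1), function(m0) {
    out <- multiscale_filter(ph$image, filter_config(n_levels = 3,
                                                     base_sigma = 0.15, base_mf = m0))
    var(as.vector(out[, left])) + var(as.vector(out[, right]))
  }, 0)
  expect_true(all(diff(flatvar) <= 0))
})

test_that("structure + texture add back to the input exactly", {
  set.seed(14)
  for (i in 1:3) {
    img <- rand_img(sample(10:32, 1))
    dc <- decompose(img, filter_config(n_levels = 2, base_sigma = 0.2))
    expect_lt(max(abs(dc$structure + dc$texture - img)), 1e-12)
  }
  img <- rand_img(16)
  dc0 <- decompose(img, filter_config(n_levels = 2, base_mf = 0))
  expect_lt(max(abs(dc0$texture)), 1e-10)
})

test_that("decomposition of a speckled phantom moves speckle into texture", {
  ph <- make_phantom(phantom_spec(c(64, 64), "step", tones = c(0.3, 0.7),
                                  speckle_shape = 25, seed = 21))
  dc <- decompose(ph$image, filter_config(n_levels = 3, base_sigma = 0.15))
  expect_gt(var(as.vector(dc$texture)), 0)
  flat <- ph$image[5:28, 5:28]         # well inside the left tone
  sflat <- dc$structure[5:28, 5:28]
  expect_lt(var(as.vector(sflat)), var(as.vector(flat)))
})

test_that("config validation and JSON round trip", {
  expect_error(filter_config(base_sigma = -1), "base_sigma")
  expect_error(filter_config(base_mf = 2), "base_mf")
  expect_error(multiscale_filter(rand_img(4), filter_config(n_levels = 5)),
               "too small")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeLines('{"n_levels": 2, "sigma0": 0.3, "mf0": 0.5, "adaptive": true, "k": 3}', path)
  cfg <- read_filter_config(path)
  expect_equal(cfg$n_levels, 2L)
  expect_equal(cfg$base_sigma, 0.3)
  expect_true(cfg$adaptive)
  expect_equal(cfg$k, 3L)
})
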