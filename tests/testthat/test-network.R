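test_that("reference convolution matches a literal nested-loop evaluation", {
  # identity kernel passes the interior through
  set.seed(1)
  X <- matrix(rnorm(49), 7)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  Y <- conv2d_reference(X, delta, 1L)
  expect_equal(Y[2:6, 2:6], X[2:6, 2:6])

  # all-ones 3x3 filter on a constant field sums to 9c on the interior
  Yc <- conv2d_reference(matrix(2.5, 6, 6), matrix(1, 3, 3), 1L)
  expect_equal(Yc[2:5, 2:5], matrix(9 * 2.5, 4, 4))

  # strided case against an independent four-nested-loop oracle with
  # explicit kernel flip
  X <- matrix(rnorm(25), 5)
  Kf <- matrix(rnorm(9), 3)
  S <- 2L
  oracle <- matrix(0, 2, 2)
  for (m in 1:2) for (n in 1:2) {
    acc <- 0
    for (i in -1:1) for (j in -1:1) {
      r <- S * m + i; c <- S * n + j
      if (r >= 1 && r <= 5 && c >= 1 && c <= 5) {
        acc <- acc + Kf[1 - i + 1, 1 - j + 1] * X[r, c]
      }
    }
    oracle[m, n] <- acc
  }
  expect_equal(conv2d_reference(X, Kf, S), oracle)
  expect_error(conv2d_reference(matrix(1, 2, 2), matrix(1, 3, 3)),
               "filter exceeds input")
})

test_that("multi-channel conv layer composes single-channel convolutions", {
  set.seed(2)
  x1 <- array(rnorm(36), c(6, 6, 1))
  f1 <- array(rnorm(9), c(3, 3, 1, 1))
  expect_equal(conv_layer_reference(x1, f1)[, , 1],
               pmax(conv2d_reference(x1[, , 1], f1[, , 1, 1]), 0))

  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  expect_true(all(conv_layer_reference(x, array(0, c(3, 3, 3, 2))) == 0))

  f <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  out <- conv_layer_reference(x, f, S = 1L)
  for (co in 1:2) {
    acc <- Reduce(`+`, lapply(1:3, function(ci) {
      conv2d_reference(x[, , ci], f[, , ci, co])
    }))
    expect_equal(out[, , co], pmax(acc, 0))
  }
  expect_error(conv_layer_reference(x, array(0, c(3, 3, 2, 2))),
               "channel mismatch")
})

test_that("max pooling takes windowed maxima with zero padding", {
  expect_equal(maxpool_reference(matrix(4, 6, 6), 3L, 2L), matrix(4, 3, 3))
  # strictly increasing raster values: each full window's maximum is its
  # bottom-right element
  X <- matrix(seq_len(36), 6, 6)
  Y <- maxpool_reference(X, 3L, 2L)
  for (m in 1:2) for (n in 1:2) expect_equal(Y[m, n], X[2 * m + 1, 2 * n + 1])
  # degenerate 1x1 window at stride 1 is the identity
  X <- matrix(rnorm(16), 4)
  expect_equal(maxpool_reference(X, 1L, 1L), X)
  expect_error(maxpool_reference(matrix(1, 2, 2), 3L, 1L), "window exceeds")
})

test_that("global average pooling and FC layers follow their definitions", {
  expect_equal(global_avgpool(array(3, c(4, 5, 2))), c(3, 3))
  expect_equal(global_avgpool(array(c(1, 3, 2, 4), c(2, 2, 1))), 2.5)
  set.seed(3)
  A <- array(rnorm(18), c(3, 3, 2)); B <- array(rnorm(18), c(3, 3, 2))
  expect_equal(global_avgpool(A + B), global_avgpool(A) + global_avgpool(B))

  x <- c(1, -2, 3)
  b <- c(0.5, -1)
  expect_equal(fc_forward(x, matrix(0, 2, 3), b), pmax(b, 0))
  expect_equal(fc_forward(c(2, 3), diag(2), c(0, 0)), c(2, 3))
  W <- matrix(rnorm(6), 2, 3)
  a_hand <- c(sum(W[1, ] * x) + b[1], sum(W[2, ] * x) + b[2])
  expect_equal(fc_forward(x, W, b, "identity"), a_hand)
  expect_equal(fc_forward(x, W, b, "relu"), pmax(a_hand, 0))
  expect_error(fc_forward(c(1, 2), W, b), "size mismatch")
})

test_that("skip down-sampling and residual addition behave as index maps", {
  X <- matrix(rnorm(16), 4)
  expect_identical(downsample_skip(X, 1L), X)
  X <- matrix(0:15, 4, 4, byrow = TRUE)
  expect_equal(downsample_skip(X, 2L), matrix(c(5, 13, 7, 15), 2))
  expect_equal(downsample_skip(matrix(2, 6, 6), 3L), matrix(2, 2, 2))

  A <- array(rnorm(8), c(2, 2, 2))
  expect_equal(residual_add(A, A * 0), A)
  expect_equal(residual_add(A, -A), A * 0)
  B <- array(rnorm(8), c(2, 2, 2))
  expect_equal(residual_add(A, B), A + B)
  expect_error(residual_add(A, array(0, c(2, 3, 2))), "shape mismatch")
})

test_that("production forward pass equals the composed reference operations", {
  for (case in list(list(n = 32L, ch = c(2L, 2L, 2L, 2L), seed = 1L),
                    list(n = 32L, ch = c(2L, 4L, 4L, 4L), seed = 2L))) {
    cfg <- network_config(case$n, channels = case$ch, fc_hidden = 4L,
                          batchnorm = FALSE)
    net <- build_network(cfg, seed = case$seed)
    img <- rand_image(case$n, seed = case$seed + 10)
    prod <- forward(net, img)
    ref <- reference_forward(net, img)
    expect_equal(prod, ref, tolerance = 1e-4)
  }
})

test_that("network configuration enforces the shape algebra", {
  cfg <- network_config(128L, channels = c(8L, 16L, 32L, 64L))
  expect_equal(unname(cfg$shapes),
               c(128L, 64L, 32L, 32L, 16L, 8L, 4L))
  expect_error(network_config(16L), "incompatible")
  expect_error(network_config(100L, pre_pool = 3L), "divisible")
  # the pre-pool stage re-enables large inputs on the same stack
  cfg2 <- network_config(512L, channels = c(2L, 2L, 2L, 2L),
                         pre_pool = 4L)
  expect_equal(unname(cfg2$shapes)[1], 128L)
})

test_that("output clipping and signal annihilation behave as specified", {
  cfg <- network_config(32L, channels = c(2L, 2L, 2L, 2L), fc_hidden = 3L,
                        batchnorm = FALSE, output_clip = TRUE)
  net <- build_network(cfg, seed = 1)
  # zero out everything except the output bias
  for (k in seq_along(net$units)) {
    net$units[[k]]$w[] <- 0; net$units[[k]]$b[] <- 0
  }
  net$fc1$W[] <- 0; net$fc1$b[] <- 0; net$fc2$W[] <- 0
  net$fc2$b <- 42
  img <- raster_image(array(0L, c(32, 32, 3)))
  expect_equal(forward(net, img), 10)          # clipped
  expect_equal(forward(net, img, clip = FALSE), 42)
  # any input scores within the scale when clipping is on
  expect_true(all(forward(build_network(cfg, seed = 9),
                          list(rand_image(32, 1), rand_image(32, 2))) >= 1))
})

test_that("configuration YAML and checkpoints round-trip", {
  cfg <- network_config(64L, channels = c(2L, 4L, 4L, 8L), fc_hidden = 5L)
  f <- tempfile(fileext = ".yaml")
  write_network_config(cfg, f)
  cfg2 <- read_network_config(f)
  expect_equal(cfg2, cfg)
  expect_equal(config_hash(cfg2), config_hash(cfg))

  net <- build_network(cfg, seed = 2)
  ck <- tempfile(fileext = ".rds")
  save_network(net, ck)
  expect_equal(load_network(ck), net)
})
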