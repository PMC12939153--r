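tiny_net <- function(seed = 1L, batchnorm = TRUE, input = 32L) {
  build_network(network_config(input, channels = c(2L, 2L, 2L, 2L),
                               fc_hidden = 4L, batchnorm = batchnorm),
                seed = seed)
}

tiny_images <- function(n, input = 32L, seed = 100L) {
  lapply(seq_len(n), function(i) {
    sp <- random_synthetic_spec(input, seed = seed + i, index = i)
    list(img = render_spec(sp), score = oracle_score(sp))
  })
}

test_that("sum squared loss follows its definition", {
  expect_equal(sum_squared_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sum_squared_loss(c(1, 2), c(2, 4)), 5)
  set.seed(1)
  t <- runif(6); e <- runif(6); p <- sample(6)
  expect_equal(sum_squared_loss(t[p], e[p]), sum_squared_loss(t, e))
  expect_error(sum_squared_loss(1:3, 1:2), "length mismatch")
})

test_that("training reduces the loss on a small oracle-labeled set", {
  dat <- tiny_images(10)
  ft <- fit(tiny_net(1), lapply(dat, `[[`, "img"),
            vapply(dat, `[[`, numeric(1), "score"),
            train_config(learning_rate = 1e-2, max_epochs = 200L, seed = 1))
  h <- ft$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_s3_class(ft, "fibrofit")
  expect_equal(length(predict(ft)), 10L)
  expect_equal(residuals(ft), vapply(dat, `[[`, numeric(1), "score") -
                 predict(ft))
})

test_that("a constant validation loss stops training after the patience", {
  dat <- tiny_images(8)
  ft <- fit(tiny_net(1), lapply(dat, `[[`, "img"),
            vapply(dat, `[[`, numeric(1), "score"),
            train_config(learning_rate = 1e-300, weight_decay = 0,
                         max_epochs = 100L, early_stop_patience = 4L,
                         seed = 2))
  # epoch 1 sets the best; 4 flat epochs later training halts
  expect_equal(nrow(ft$history), 5L)
})

test_that("fits are deterministic under a fixed seed", {
  dat <- tiny_images(8)
  imgs <- lapply(dat, `[[`, "img")
  y <- vapply(dat, `[[`, numeric(1), "score")
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 25L, seed = 7)
  f1 <- fit(tiny_net(3), imgs, y, cfg)
  f2 <- fit(tiny_net(3), imgs, y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$fc1, f2$model$fc1)
})

test_that("fc-only training leaves every convolutional parameter untouched", {
  dat <- tiny_images(8)
  net <- tiny_net(4)
  ft <- fit(net, lapply(dat, `[[`, "img"),
            vapply(dat, `[[`, numeric(1), "score"),
            train_config(learning_rate = 1e-2, max_epochs = 20L, seed = 1))
  for (k in seq_along(net$units)) {
    expect_identical(ft$model$units[[k]]$w, net$units[[k]]$w)
    expect_identical(ft$model$units[[k]]$b, net$units[[k]]$b)
  }
  expect_false(identical(ft$model$fc1$W, net$fc1$W))
})

test_that("the learning-rate schedule only ever halves", {
  dat <- tiny_images(10)
  ft <- fit(tiny_net(1), lapply(dat, `[[`, "img"),
            vapply(dat, `[[`, numeric(1), "score"),
            train_config(learning_rate = 1e-2, max_epochs = 150L, seed = 3))
  lr <- ft$history$lr
  expect_true(all(diff(lr) <= 0))
  changes <- which(diff(lr) < 0)
  expect_true(all(abs(lr[changes + 1] / lr[changes] - 0.5) < 1e-12))
})

test_that("a one-sample training set is memorized to high precision", {
  dat <- tiny_images(1)
  ft <- fit(tiny_net(2), list(dat[[1]]$img), dat[[1]]$score,
            train_config(learning_rate = 5e-2, dropout_rate = 0,
                         early_stop_patience = 50L,
                         max_epochs = 2000L, seed = 5))
  expect_lt(min(ft$history$train_loss), 1e-3)
})

test_that("full-scope gradients match finite differences", {
  set.seed(3)
  net <- tiny_net(3)
  imgs <- lapply(1:3, function(i) array(sample(0:255, 32 * 32 * 3, TRUE),
                                        c(32, 32, 3)))
  y <- c(2, 5, 8)
  net <- calibrate_network(net, imgs)
  feats <- network_features(net, imgs)
  net$feat_scale <- list(mu = colMeans(feats), sd = apply(feats, 2, sd))
  params <- fibroscore:::get_params(net, fc_only = FALSE)
  xs_get <- function(idx) lapply(imgs[idx], fibroscore:::image_to_input,
                                 cfg = net$cfg)
  loss_fn <- function(p) {
    m <- fibroscore:::set_params(net, p, FALSE)
    est <- fibroscore:::fc_head_forward(
      m, fibroscore:::trunk_forward_batch(m, xs_get(1:3))$features)
    mean((est - y)^2)
  }
  gr <- fibroscore:::batch_gradient(net, params, xs_get, NULL, y, 1:3,
                                    0, FALSE)
  eps <- 1e-6
  base <- loss_fn(params)
  for (uid in c(1L, 5L, 10L, 17L)) {
    key <- paste0("conv_w_", uid)
    for (rep in 1:3) {
      i <- sample(length(params[[key]]), 1)
      p2 <- params
      p2[[key]][i] <- p2[[key]][i] + eps
      num <- (loss_fn(p2) - base) / eps
      ana <- gr[[key]][i]
      expect_lt(abs(num - ana) / max(1e-4, abs(num), abs(ana)), 1e-3)
    }
  }
})

test_that("full-scope training updates convolutional parameters", {
  dat <- tiny_images(4)
  net <- tiny_net(5)
  ft <- fit(net, lapply(dat, `[[`, "img"),
            vapply(dat, `[[`, numeric(1), "score"),
            train_config(learning_rate = 1e-3, max_epochs = 5L,
                         trainable_scope = "all", seed = 1))
  expect_false(identical(ft$model$units[[1]]$w, net$units[[1]]$w))
  expect_equal(nrow(ft$history), 5L)
})

test_that("degenerate training inputs are rejected", {
  expect_error(fit(tiny_net(1), list(), numeric(0)), "empty training set")
  dat <- tiny_images(2)
  expect_error(fit(tiny_net(1), lapply(dat, `[[`, "img"), 1),
               "lengths differ")
})
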