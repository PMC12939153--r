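# Shared fixtures, generated in code.

# random RGB image with reproducible content
rand_image <- function(n = 16L, seed = 1L, id = "fix") {
  set.seed(seed)
  raster_image(array(sample(0:255, n * n * 3L, replace = TRUE),
                     c(n, n, 3L)), id = id)
}

# a small blob image on black background: a filled disc of radius r
# centered at (cy, cx) in an h x w canvas
blob_image <- function(h = 20L, w = 24L, cy = 8, cx = 15, r = 4,
                       value = c(200L, 120L, 60L), id = "blob") {
  px <- array(0L, c(h, w, 3L))
  for (k in 1:3) {
    m <- matrix(0L, h, w)
    dr <- matrix(rep(seq_len(h) - cy, w), h)
    dc <- matrix(rep(seq_len(w) - cx, each = h), h)
    m[dr^2 + dc^2 <= r^2] <- value[k]
    px[, , k] <- m
  }
  raster_image(px, id = id)
}

# independent end-to-end composition of the reference layer operations
# (normalization-free configurations only), used as the oracle against
# the production forward pass
reference_forward <- function(model, img) {
  cfg <- model$cfg
  stopifnot(!cfg$batchnorm, cfg$pre_pool == 1L)
  px <- if (inherits(img, "raster_image")) img$pixels else img
  z <- array(as.numeric(px) / 255, dim(px))
  u <- model$units
  z <- conv_layer_reference(z, u[[1]]$w, S = u[[1]]$stride, bias = u[[1]]$b)
  pooled <- lapply(seq_len(dim(z)[3]), function(c) {
    maxpool_reference(z[, , c], cfg$pool_window, cfg$pool_stride)
  })
  z <- array(unlist(pooled), c(dim(pooled[[1]]), length(pooled)))
  uid <- 1L
  for (b in 1:4) {
    sb <- if (b == 1L) 1L else 2L
    zin <- z
    z <- conv_layer_reference(z, u[[uid + 1L]]$w, S = sb, bias = u[[uid + 1L]]$b)
    z <- conv_layer_reference(z, u[[uid + 2L]]$w, S = 1L, bias = u[[uid + 2L]]$b)
    skip <- array(0, dim(z))
    for (c in seq_len(dim(zin)[3])) {
      skip[, , c] <- downsample_skip(zin[, , c], sb)
    }
    z <- residual_add(z, skip)
    zin2 <- z
    z <- conv_layer_reference(z, u[[uid + 3L]]$w, S = 1L, bias = u[[uid + 3L]]$b)
    z <- conv_layer_reference(z, u[[uid + 4L]]$w, S = 1L, bias = u[[uid + 4L]]$b)
    z <- residual_add(z, zin2)
    uid <- uid + 4L
  }
  f <- global_avgpool(z)
  h <- fc_forward(f, model$fc1$W, model$fc1$b, "relu")
  fc_forward(h, model$fc2$W, model$fc2$b, "identity")
}

# session-score table for k images, two subjects (A: 2 sessions, B: 4)
session_scores_fixture <- function(k = 6L, seed = 7L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(k)) {
    id <- sprintf("img%02d", i)
    base <- runif(1, 2, 9)
    for (p in 1:2) rows[[length(rows) + 1L]] <-
      data.frame(image_id = id, subject = "A", session = p,
                 score = round(pmin(10, pmax(1, base + runif(1, -1, 1))), 1))
    for (p in 1:4) rows[[length(rows) + 1L]] <-
      data.frame(image_id = id, subject = "B", session = p,
                 score = round(pmin(10, pmax(1, base + runif(1, -1.5, 1.5))), 1))
  }
  do.call(rbind, rows)
}
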