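# The residual regression network.
#
# Layout: a 7x7 stride-2 stem convolution and 3x3 stride-2 max-pool,
# four blocks of four 3x3 convolutions each (channels doubling and
# spatial size halving at each block transition), residual skip
# connections every two convolutions (parameter-free: the skip path is
# regularly subsampled and, at channel-doubling transitions, zero-padded
# in the channel dimension), a global average pool, and a two-layer
# fully connected head ending in a single linear scoring unit.
#
# Per the layer definitions this package implements, the rectifier lives
# inside each convolution layer and the residual addition happens after
# it.  An optional per-channel normalization stage (enabled by default)
# sits between the linear convolution and the rectifier; its statistics
# are frozen after a calibration pass over training images, so inference
# is deterministic and sample-independent.

BN_EPS <- 1e-5

#' Network configuration
#'
#' Describes the full layer stack.  The default channel widths (64, 128,
#' 256, 512) give the standard 18-layer residual layout; much narrower
#' widths (e.g. `c(8, 16, 32, 64)`) are appropriate for reduced-resolution
#' runs and are what the test-scale experiments use.
#'
#' @param input_size side length in pixels of the (square) input image.
#' @param channels integer vector of 4 block channel widths.
#' @param fc_hidden width of the hidden fully connected layer (the head is
#'   `channels[4] -> fc_hidden -> 1`).
#' @param batchnorm logical; include the per-channel normalization stage.
#' @param output_clip logical; clip predicted scores to \[1, 10\] at
#'   inference (training always sees the linear output).
#' @param pre_pool integer block-averaging factor applied to the input
#'   before the stem (1 = off).  Lets acquisition-scale images reuse the
#'   same block structure: an `f x f` mean reduces the input side by `f`.
#' @param stem_filter,stem_stride stem convolution geometry (7, 2).
#' @param pool_window,pool_stride stem max-pool geometry (3, 2).
#' @param block_filter filter size of all block convolutions (3).
#' @return A list of class `network_config` with an added `$shapes`
#'   element giving the computed spatial size after every stage.
#' @export
network_config <- function(input_size,
                           channels = c(64L, 128L, 256L, 512L),
                           fc_hidden = 64L,
                           batchnorm = TRUE,
                           output_clip = FALSE,
                           pre_pool = 1L,
                           stem_filter = 7L, stem_stride = 2L,
                           pool_window = 3L, pool_stride = 2L,
                           block_filter = 3L) {
  stopifnot(length(channels) == 4L, all(channels >= 1L),
            stem_filter %% 2L == 1L, pool_window %% 2L == 1L,
            block_filter %% 2L == 1L, fc_hidden >= 1L, pre_pool >= 1L)
  if (input_size %% pre_pool != 0L) {
    stop("input_size must be divisible by pre_pool")
  }
  cfg <- list(input_size = as.integer(input_size),
              channels = as.integer(channels),
              fc_hidden = as.integer(fc_hidden),
              batchnorm = isTRUE(batchnorm),
              output_clip = isTRUE(output_clip),
              pre_pool = as.integer(pre_pool),
              stem_filter = as.integer(stem_filter),
              stem_stride = as.integer(stem_stride),
              pool_window = as.integer(pool_window),
              pool_stride = as.integer(pool_stride),
              block_filter = as.integer(block_filter))
  # shape algebra: every stage's declared output size is its input size
  # divided by the stride (floor when not divisible)
  s <- input_size %/% pre_pool
  shapes <- c(input = s)
  s <- s %/% stem_stride;  shapes["stem"] <- s
  s <- s %/% pool_stride;  shapes["pool"] <- s
  for (b in 1:4) {
    s <- s %/% block_stride(b)
    shapes[paste0("block", b)] <- s
  }
  if (any(shapes < 1) || stem_filter > shapes["input"] ||
      block_filter > shapes["pool"]) {
    stop("input size ", input_size, " incompatible with the layer stack")
  }
  cfg$shapes <- shapes
  structure(cfg, class = "network_config")
}

block_stride <- function(b) if (b == 1L) 1L else 2L

#' Serialize / read a network configuration as YAML
#'
#' @param cfg a [network_config()].
#' @param path file path.
#' @return `read_network_config` returns a [network_config()];
#'   `write_network_config` returns `path` invisibly.
#' @export
write_network_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"))
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "shapes")], path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  do.call(network_config, yaml::read_yaml(path))
}

#' Stable hash of a network configuration
#'
#' Embedded in experiment outputs so artifacts can be traced to the exact
#' layer stack that produced them.
#'
#' @param cfg a [network_config()].
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(cfg)), f)
  unname(tools::md5sum(f))
}

new_conv_unit <- function(K, Ci, Co, stride, batchnorm) {
  w <- array(stats::rnorm(K * K * Ci * Co, sd = sqrt(2 / (K * K * Ci))),
             c(K, K, Ci, Co))
  bn <- if (batchnorm) {
    list(gamma = rep(1, Co), beta = rep(0, Co),
         mean = rep(0, Co), var = rep(1, Co))
  }
  list(w = w, b = numeric(Co), stride = as.integer(stride), bn = bn)
}

#' Build a residual regression network
#'
#' Instantiates all layer parameters (He-initialized, seeded) for the
#' layout described by `cfg`.  Only the two fully connected head layers
#' are trained in the default transfer-learning style fit; the
#' convolutional trunk then acts as a fixed feature extractor.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `fibronet`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- cfg$channels
  with_seed(seed, {
    units <- list(new_conv_unit(cfg$stem_filter, 3L, ch[1], cfg$stem_stride,
                                cfg$batchnorm))
    cin <- ch[1]
    for (b in 1:4) {
      for (k in 1:4) {
        s <- if (k == 1L) block_stride(b) else 1L
        units <- c(units, list(new_conv_unit(cfg$block_filter, cin, ch[b], s,
                                             cfg$batchnorm)))
        cin <- ch[b]
      }
    }
    fc1 <- list(W = matrix(stats::rnorm(cfg$fc_hidden * ch[4],
                                        sd = sqrt(2 / ch[4])),
                           cfg$fc_hidden, ch[4]),
                b = numeric(cfg$fc_hidden))
    fc2 <- list(W = matrix(stats::rnorm(cfg$fc_hidden,
                                        sd = sqrt(1 / cfg$fc_hidden)),
                           1L, cfg$fc_hidden),
                b = numeric(1L))
    structure(list(cfg = cfg, units = units, fc1 = fc1, fc2 = fc2,
                   calibrated = !cfg$batchnorm),
              class = "fibronet")
  })
}

#' @export
print.fibronet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<fibronet> input %d px (pre-pool %d), channels %s, head %d -> %d -> 1\n",
              cfg$input_size, cfg$pre_pool,
              paste(cfg$channels, collapse = "/"), cfg$channels[4],
              cfg$fc_hidden))
  cat(sprintf("  17 conv layers + 2 FC, normalization %s%s, output clip %s\n",
              if (cfg$batchnorm) "on" else "off",
              if (cfg$batchnorm && !x$calibrated) " (uncalibrated)" else "",
              if (cfg$output_clip) "[1,10]" else "off"))
  invisible(x)
}

# ---- forward machinery ----------------------------------------------------

relu <- function(a) {
  a[a < 0] <- 0
  a
}

bn_apply <- function(a, bn) {
  d <- dim(a)
  sc <- bn$gamma / sqrt(bn$var + BN_EPS)
  sh <- bn$beta - bn$mean * sc
  a * rep(sc, each = d[1] * d[2]) + rep(sh, each = d[1] * d[2])
}

pad_channels <- function(x, Co) {
  d <- dim(x)
  if (d[3] == Co) return(x)
  out <- array(0, c(d[1], d[2], Co))
  out[, , seq_len(d[3])] <- x
  out
}

# f x f block mean over the input image (integer reduction pre-stage)
pre_pool_image <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  m <- d[1] %/% f; n <- d[2] %/% f
  out <- array(0, c(m, n, d[3]))
  for (k in seq_len(d[3])) {
    xm <- x[seq_len(m * f), seq_len(n * f), k]
    # average f x f blocks: fold rows then columns
    xm <- rowsum(xm, rep(seq_len(m), each = f)) / f
    out[, , k] <- t(rowsum(t(xm), rep(seq_len(n), each = f))) / f
  }
  out
}

image_to_input <- function(img, cfg) {
  px <- if (inherits(img, "raster_image")) img$pixels else img
  d <- dim(px)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop("image size ", d[1], " x ", d[2],
         " incompatible with configured input size ", cfg$input_size)
  }
  x <- array(as.numeric(px) / 255, d)  # rescale to [0, 1]
  pre_pool_image(x, cfg$pre_pool)
}

# Forward pass of the convolutional trunk over a batch (list) of input
# arrays.  With calibrate = TRUE the per-channel normalization statistics
# of each layer are set from the batch as the data flows through, then
# used immediately — a single-pass calibration of the whole stack.
# Returns list(features = n x C matrix, model = possibly updated model,
# cache = per-image intermediates when keep = TRUE).
trunk_forward_batch <- function(model, xs, calibrate = FALSE, keep = FALSE) {
  cfg <- model$cfg
  n <- length(xs)
  cache <- if (keep) replicate(n, list(), simplify = FALSE)
  run_unit <- function(zs, u, uid) {
    as_ <- lapply(zs, function(z) cpp_conv_fwd(z, u$w, u$b, u$stride))
    if (!is.null(u$bn)) {
      if (calibrate) {
        d <- dim(as_[[1]])
        flat <- vapply(as_, function(a) {
          c(.colMeans(a, d[1] * d[2], d[3]),
            .colMeans(a * a, d[1] * d[2], d[3]))
        }, numeric(2 * d[3]))
        mu <- rowMeans(flat)[seq_len(d[3])]
        m2 <- rowMeans(flat)[d[3] + seq_len(d[3])]
        u$bn$mean <- mu
        u$bn$var <- pmax(m2 - mu^2, 0)
        model$units[[uid]]$bn <<- u$bn
      }
      as_ <- lapply(as_, bn_apply, bn = u$bn)
    }
    ys <- lapply(as_, relu)
    if (keep) {
      for (i in seq_len(n)) {
        cache[[i]]$unit_in[[uid]] <<- zs[[i]]
        cache[[i]]$unit_mask[[uid]] <<- ys[[i]] > 0
      }
    }
    ys
  }
  zs <- xs
  if (keep) for (i in seq_len(n)) {
    cache[[i]]$unit_in <- vector("list", length(model$units))
    cache[[i]]$unit_mask <- vector("list", length(model$units))
  }
  zs <- run_unit(zs, model$units[[1]], 1L)
  if (keep) for (i in seq_len(n)) cache[[i]]$pool_in <- zs[[i]]
  zs <- lapply(zs, cpp_maxpool_fwd, K = cfg$pool_window, S = cfg$pool_stride)
  uid <- 1L
  for (b in 1:4) {
    sb <- block_stride(b)
    block_in <- zs
    zs <- run_unit(zs, model$units[[uid + 1L]], uid + 1L)
    zs <- run_unit(zs, model$units[[uid + 2L]], uid + 2L)
    zs <- lapply(seq_len(n), function(i) {
      zs[[i]] + pad_channels(cpp_downsample(block_in[[i]], sb), cfg$channels[b])
    })
    half_in <- zs
    zs <- run_unit(zs, model$units[[uid + 3L]], uid + 3L)
    zs <- run_unit(zs, model$units[[uid + 4L]], uid + 4L)
    zs <- lapply(seq_len(n), function(i) zs[[i]] + half_in[[i]])
    if (keep) for (i in seq_len(n)) cache[[i]]$block_out[[b]] <- zs[[i]]
    uid <- uid + 4L
  }
  feats <- t(vapply(zs, global_avgpool, numeric(cfg$channels[4])))
  if (keep) for (i in seq_len(n)) cache[[i]]$final_dim <- dim(zs[[i]])
  if (calibrate) model$calibrated <- TRUE
  list(features = feats, model = model, cache = cache)
}

#' Calibrate the network's normalization statistics
#'
#' Runs the given images through the trunk once, fixing each
#' normalization layer's per-channel mean and variance to the statistics
#' of the activations it sees.  Must be done (typically on the training
#' images) before feature extraction or prediction when `batchnorm` is
#' enabled; [fit()] calls it automatically.
#'
#' @param model a `fibronet`.
#' @param images list of [raster_image()]s (or raw pixel arrays).
#' @return The calibrated `fibronet`.
#' @export
calibrate_network <- function(model, images) {
  stopifnot(inherits(model, "fibronet"))
  if (!model$cfg$batchnorm) return(model)
  xs <- lapply(images, image_to_input, cfg = model$cfg)
  trunk_forward_batch(model, xs, calibrate = TRUE)$model
}

#' Trunk feature vectors for a set of images
#'
#' @param model a calibrated `fibronet`.
#' @param images list of [raster_image()]s (or raw pixel arrays).
#' @param chunk images processed per batch (bounds peak memory).
#' @return A numeric matrix, one row of `channels[4]` features per image.
#' @export
network_features <- function(model, images, chunk = 64L) {
  stopifnot(inherits(model, "fibronet"))
  if (!model$calibrated) stop("normalization statistics not calibrated; run calibrate_network() first")
  n <- length(images)
  out <- matrix(0, n, model$cfg$channels[4])
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    xs <- lapply(images[idx], image_to_input, cfg = model$cfg)
    out[idx, ] <- trunk_forward_batch(model, xs)$features
  }
  out
}

# standardize trunk features with the fixed affine calibration stored in
# the model (set by fit() from the training features)
scale_features <- function(model, feats) {
  fs <- model$feat_scale
  if (is.null(fs)) return(feats)
  sweep(sweep(feats, 2L, fs$mu), 2L, fs$sd, "/")
}

fc_head_forward <- function(model, feats, dropout_mask = NULL) {
  feats <- scale_features(model, feats)
  h <- relu(feats %*% t(model$fc1$W) +
              rep(model$fc1$b, each = nrow(feats)))
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  drop(h %*% t(model$fc2$W)) + model$fc2$b
}

#' Forward pass: estimated fibrosity score of an image
#'
#' Runs the full network — trunk, global average pool, fully connected
#' head — and returns the scalar estimated score.  With the
#' configuration's `output_clip` (or `clip = TRUE`) the score is clipped
#' to the \[1, 10\] scoring scale.
#'
#' @param model a calibrated `fibronet`.
#' @param img a [raster_image()] or pixel array, or a list of them.
#' @param clip override the configuration's `output_clip`.
#' @return Numeric score(s).
#' @export
forward <- function(model, img, clip = NULL) {
  stopifnot(inherits(model, "fibronet"))
  imgs <- if (inherits(img, "raster_image") || is.array(img)) list(img) else img
  feats <- network_features(model, imgs)
  s <- fc_head_forward(model, feats)
  if (clip %||% model$cfg$output_clip) s <- pmin(10, pmax(1, s))
  unname(s)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS container holding all weights, the
#' configuration, its hash, and the calibration state.
#'
#' @param model a `fibronet`.
#' @param path file path (`.rds`).
#' @return `load_network` returns the `fibronet`; `save_network` returns
#'   `path` invisibly.
#' @export
save_network <- function(model, path) {
  stopifnot(inherits(model, "fibronet"))
  saveRDS(list(model = model, hash = config_hash(model$cfg)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  stopifnot(identical(ck$hash, config_hash(ck$model$cfg)))
  ck$model
}
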