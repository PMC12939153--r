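# Training.
#
# By default only the two fully connected head layers are trained
# (transfer-learning style): trunk features are extracted once and
# cached, and the head is optimized with Adam using decoupled weight
# decay, an inverted-dropout layer after the hidden unit, a
# reduce-on-plateau learning-rate schedule, and early stopping with
# best-weight restoration.  `trainable_scope = "all"` additionally
# backpropagates through the convolutional trunk (normalization layers
# stay frozen); it is intended for small configurations.

#' Training configuration
#'
#' Defaults are the study's stated hyperparameters: learning rate 1e-4,
#' L2 weight decay 0.001, dropout 0.5 after the hidden fully connected
#' layer, plateau scheduler halving the rate after 3 non-improving
#' epochs, early stopping with patience 20, up to 5000 epochs, batch
#' sizes 8 (training) and 32 (validation).
#'
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 penalty coefficient.
#' @param dropout_rate dropout probability after the hidden FC layer
#'   (the scalar output unit is never dropped).
#' @param sched_factor,sched_patience reduce-on-plateau factor and
#'   patience (epochs without validation improvement).
#' @param early_stop_patience epochs without validation improvement
#'   before training halts.
#' @param max_epochs epoch cap.
#' @param batch_train,batch_val minibatch sizes.
#' @param val_fraction fraction of the training samples held out
#'   internally for validation.
#' @param trainable_scope `"fc_only"` (default) or `"all"`.
#' @param seed integer seed; fixing it makes the whole fit
#'   deterministic.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4,
                         weight_decay = 0.001,
                         dropout_rate = 0.5,
                         sched_factor = 0.5,
                         sched_patience = 3L,
                         early_stop_patience = 20L,
                         max_epochs = 5000L,
                         batch_train = 8L,
                         batch_val = 32L,
                         val_fraction = 0.15,
                         trainable_scope = c("fc_only", "all"),
                         seed = 1L) {
  stopifnot(learning_rate > 0, dropout_rate >= 0, dropout_rate < 1,
            sched_patience >= 1, early_stop_patience >= 1,
            weight_decay >= 0, val_fraction >= 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 dropout_rate = dropout_rate,
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_train = as.integer(batch_train),
                 batch_val = as.integer(batch_val),
                 val_fraction = val_fraction,
                 trainable_scope = match.arg(trainable_scope),
                 seed = seed),
            class = "train_config")
}

#' Sum squared error loss
#'
#' The training objective: the sum over samples of squared differences
#' between target and estimated scores.
#'
#' @param targets,estimates equal-length numeric vectors.
#' @return A non-negative scalar.
#' @examples
#' sum_squared_loss(c(1, 2), c(2, 4))  # 5
#' @export
sum_squared_loss <- function(targets, estimates) {
  if (length(targets) != length(estimates)) {
    stop("length mismatch between targets and estimates")
  }
  if (length(targets) == 0L) stop("empty inputs")
  sum((targets - estimates)^2)
}

# ---- Adam with decoupled weight decay -------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (k in seq_along(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    step <- (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + eps)
    params[[k]] <- params[[k]] - lr * step - lr * wd * params[[k]]
  }
  list(params = params, state = st)
}

# ---- backward pass through the trunk (trainable_scope = "all") ------------

# gradient of one unit: relu mask, frozen normalization scale, conv backward
conv_unit_bwd <- function(u, xin, mask, gy, grads, uid) {
  ga <- gy * mask
  if (!is.null(u$bn)) {
    d <- dim(ga)
    ga <- ga * rep(u$bn$gamma / sqrt(u$bn$var + BN_EPS), each = d[1] * d[2])
  }
  r <- cpp_conv_bwd(xin, u$w, ga, u$stride)
  grads$w[[uid]] <- grads$w[[uid]] + r$gw
  grads$b[[uid]] <- grads$b[[uid]] + r$gb
  list(gx = r$gx, grads = grads)
}

# backpropagate d(loss)/d(features) through the trunk for one image,
# accumulating conv weight/bias gradients into `grads`
trunk_backward <- function(model, cache, gfeat, grads) {
  cfg <- model$cfg
  d4 <- cache$final_dim
  g <- array(rep(gfeat / (d4[1] * d4[2]), each = d4[1] * d4[2]), d4)
  for (b in 4:1) {
    base <- 1L + (b - 1L) * 4L
    u <- model$units
    # second residual pair: out = relu-conv(relu-conv(half_in)) + half_in
    r4 <- conv_unit_bwd(u[[base + 4L]], cache$unit_in[[base + 4L]],
                        cache$unit_mask[[base + 4L]], g, grads, base + 4L)
    grads <- r4$grads
    r3 <- conv_unit_bwd(u[[base + 3L]], cache$unit_in[[base + 3L]],
                        cache$unit_mask[[base + 3L]], r4$gx, grads, base + 3L)
    grads <- r3$grads
    g_half <- g + r3$gx
    # first residual pair: half_in = conv pair(block_in) + padded skip
    cprev <- dim(cache$unit_in[[base + 1L]])[3]
    din <- dim(cache$unit_in[[base + 1L]])
    g_skip <- cpp_downsample_bwd(g_half[, , seq_len(cprev), drop = FALSE],
                                 din[1], din[2], block_stride(b))
    r2 <- conv_unit_bwd(u[[base + 2L]], cache$unit_in[[base + 2L]],
                        cache$unit_mask[[base + 2L]], g_half, grads, base + 2L)
    grads <- r2$grads
    r1 <- conv_unit_bwd(u[[base + 1L]], cache$unit_in[[base + 1L]],
                        cache$unit_mask[[base + 1L]], r2$gx, grads, base + 1L)
    grads <- r1$grads
    g <- r1$gx + g_skip
  }
  g <- cpp_maxpool_bwd(cache$pool_in, g, cfg$pool_window, cfg$pool_stride)
  r0 <- conv_unit_bwd(model$units[[1L]], cache$unit_in[[1L]],
                      cache$unit_mask[[1L]], g, grads, 1L)
  r0$grads
}

# ---- fit ------------------------------------------------------------------

#' Fit a fibrosity regression network
#'
#' `fit` is a generic; the `fibronet` method trains the network on scored
#' images and returns a `fibrofit` object.
#'
#' @param object a `fibronet` from [build_network()].
#' @param ... passed to methods.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @param images list of [raster_image()]s (or pixel arrays) at the
#'   configured input size.
#' @param scores numeric target scores, one per image.
#' @param config a [train_config()].
#' @details A `val_fraction` share of the samples is held out internally
#'   for validation (when that rounds to zero, the training samples
#'   double as the validation set).  The history records the sum squared
#'   error loss, normalized per sample, for both subsets at every epoch,
#'   along with the learning rate in force.  Training halts at
#'   `max_epochs` or once the validation loss has not improved for
#'   `early_stop_patience` epochs; the returned model carries the weights
#'   of the best validation epoch.
#' @return An object of class `fibrofit`: the trained model plus
#'   `history` (data frame: epoch, train_loss, val_loss, lr), the
#'   configuration, fitted values and residuals on the training inputs.
#' @export
fit.fibronet <- function(object, images, scores, config = train_config(),
                         ...) {
  stopifnot(inherits(config, "train_config"))
  if (length(images) == 0L) stop("empty training set")
  if (length(images) != length(scores)) {
    stop("images and scores lengths differ")
  }
  model <- object
  cfg <- config
  with_seed(cfg$seed, {
    n <- length(images)
    n_val <- floor(cfg$val_fraction * n)
    idx <- sample(n)
    val_idx <- if (n_val >= 1L) idx[seq_len(n_val)] else idx
    tr_idx <- if (n_val >= 1L) idx[-seq_len(n_val)] else idx

    fc_only <- cfg$trainable_scope == "fc_only"
    xs_get <- function(idx) lapply(images[idx], image_to_input, cfg = model$cfg)
    if (model$cfg$batchnorm && !model$calibrated) {
      # normalization statistics from (a subsample of) the training images
      calib_idx <- tr_idx[seq_len(min(length(tr_idx), 256L))]
      model <- trunk_forward_batch(model, xs_get(calib_idx),
                                   calibrate = TRUE)$model
    }
    feats <- if (fc_only) network_features(model, images)
    # fix the head's feature standardization from the training features
    scale_src <- if (fc_only) {
      feats[tr_idx, , drop = FALSE]
    } else {
      trunk_forward_batch(model, xs_get(tr_idx))$features
    }
    sdv <- apply(scale_src, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    model$feat_scale <- list(mu = colMeans(scale_src), sd = sdv)

    params <- get_params(model, fc_only)
    ast <- adam_state(params)
    lr <- cfg$learning_rate
    best <- list(loss = Inf, params = params, epoch = 0L)
    sched_wait <- 0L
    stop_wait <- 0L
    hist <- vector("list", cfg$max_epochs)

    eval_loss <- function(params, which_idx) {
      m <- set_params(model, params, fc_only)
      est <- if (fc_only) {
        fc_head_forward(m, feats[which_idx, , drop = FALSE])
      } else {
        fc_head_forward(m, trunk_forward_batch(m, xs_get(which_idx))$features)
      }
      sum_squared_loss(scores[which_idx], est) / length(which_idx)
    }

    for (epoch in seq_len(cfg$max_epochs)) {
      order_ <- sample(tr_idx)
      batches <- split(order_, ceiling(seq_along(order_) / cfg$batch_train))
      for (bt in batches) {
        model <- set_params(model, params, fc_only)
        gr <- batch_gradient(model, params, xs_get, feats, scores, bt,
                             cfg$dropout_rate, fc_only)
        up <- adam_step(params, gr, ast, lr, cfg$weight_decay)
        params <- up$params
        ast <- up$state
      }
      train_loss <- eval_loss(params, tr_idx)
      val_loss <- eval_loss(params, val_idx)
      hist[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                         val_loss = val_loss, lr = lr)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        sched_wait <- 0L
        stop_wait <- 0L
      } else {
        sched_wait <- sched_wait + 1L
        stop_wait <- stop_wait + 1L
        if (sched_wait >= cfg$sched_patience) {
          lr <- lr * cfg$sched_factor
          sched_wait <- 0L
        }
        if (stop_wait >= cfg$early_stop_patience) break
      }
    }

    model <- set_params(model, best$params, fc_only)
    history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
    fitted_all <- if (fc_only) {
      fc_head_forward(model, feats)
    } else {
      fc_head_forward(model, trunk_forward_batch(
        model, xs_get(seq_along(images)))$features)
    }
    structure(list(model = model, history = history, config = cfg,
                   best_epoch = best$epoch, best_val_loss = best$loss,
                   train_idx = tr_idx, val_idx = val_idx,
                   fitted = unname(fitted_all), scores = scores),
              class = "fibrofit")
  })
}

# parameters as a flat named list (one array per entry) so the
# optimizer state can mirror it elementwise
get_params <- function(model, fc_only) {
  p <- list(W1 = model$fc1$W, b1 = model$fc1$b,
            W2 = model$fc2$W, b2 = model$fc2$b)
  if (!fc_only) {
    for (k in seq_along(model$units)) {
      p[[paste0("conv_w_", k)]] <- model$units[[k]]$w
      p[[paste0("conv_b_", k)]] <- model$units[[k]]$b
    }
  }
  p
}

set_params <- function(model, p, fc_only) {
  model$fc1$W <- p$W1; model$fc1$b <- p$b1
  model$fc2$W <- p$W2; model$fc2$b <- p$b2
  if (!fc_only) {
    for (k in seq_along(model$units)) {
      model$units[[k]]$w <- p[[paste0("conv_w_", k)]]
      model$units[[k]]$b <- p[[paste0("conv_b_", k)]]
    }
  }
  model
}

# mean squared error gradient over one minibatch
batch_gradient <- function(model, params, xs_get, feats, scores, bt,
                           dropout_rate, fc_only) {
  B <- length(bt)
  if (fc_only) {
    fb <- feats[bt, , drop = FALSE]
  } else {
    fw <- trunk_forward_batch(model, xs_get(bt), keep = TRUE)
    fb <- fw$features
  }
  fb <- scale_features(model, fb)
  a1 <- fb %*% t(params$W1) + rep(params$b1, each = B)
  h <- relu(a1)
  dmask <- if (dropout_rate > 0) {
    (matrix(stats::runif(length(h)), nrow(h)) >= dropout_rate) /
      (1 - dropout_rate)
  } else {
    matrix(1, nrow(h), ncol(h))
  }
  hd <- h * dmask
  est <- drop(hd %*% t(params$W2)) + params$b2
  gs <- 2 * (est - scores[bt]) / B                 # d(mse)/d(est)
  gW2 <- matrix(colSums(gs * hd), 1L)
  gb2 <- sum(gs)
  gh <- (gs %*% params$W2) * dmask * (a1 > 0)
  gW1 <- t(gh) %*% fb
  gb1 <- colSums(gh)
  gr <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  if (!fc_only) {
    grads <- list(w = lapply(model$units, function(u) u$w * 0),
                  b = lapply(model$units, function(u) u$b * 0))
    gfeats <- gh %*% params$W1                      # d loss / d features
    if (!is.null(model$feat_scale)) {
      gfeats <- sweep(gfeats, 2L, model$feat_scale$sd, "/")
    }
    for (i in seq_len(B)) {
      grads <- trunk_backward(model, fw$cache[[i]], gfeats[i, ], grads)
    }
    for (k in seq_along(model$units)) {
      gr[[paste0("conv_w_", k)]] <- grads$w[[k]]
      gr[[paste0("conv_b_", k)]] <- grads$b[[k]]
    }
  }
  gr
}

# ---- fibrofit methods -----------------------------------------------------

#' @export
print.fibrofit <- function(x, ...) {
  cat(sprintf("<fibrofit> %d epochs (best %d), validation loss %.4g, scope %s\n",
              nrow(x$history), x$best_epoch, x$best_val_loss,
              x$config$trainable_scope))
  invisible(x)
}

#' @export
summary.fibrofit <- function(object, ...) {
  res <- stats::residuals(object)
  cat("Fibrosity regression network fit\n")
  print(object$model)
  cat(sprintf("  %d training / %d validation samples, %d epochs (best %d)\n",
              length(object$train_idx), length(object$val_idx),
              nrow(object$history), object$best_epoch))
  cat(sprintf("  final lr %.3g, best validation loss %.4g\n",
              utils::tail(object$history$lr, 1), object$best_val_loss))
  cat(sprintf("  training residuals: min %.3f, median %.3f, max %.3f\n",
              min(res), stats::median(res), max(res)))
  invisible(object)
}

#' Predict fibrosity scores from a fitted network
#'
#' @param object a `fibrofit`.
#' @param images list of [raster_image()]s or pixel arrays; omitted, the
#'   fitted values on the training inputs are returned.
#' @param clip clip scores to \[1, 10\] (defaults to the network
#'   configuration's `output_clip`).
#' @param ... unused.
#' @return Numeric scores.
#' @export
predict.fibrofit <- function(object, images = NULL, clip = NULL, ...) {
  if (is.null(images)) return(object$fitted)
  forward(object$model, images, clip = clip)
}

#' @export
residuals.fibrofit <- function(object, ...) object$scores - object$fitted

#' @export
coef.fibrofit <- function(object, ...) {
  list(fc_hidden_W = object$model$fc1$W, fc_hidden_b = object$model$fc1$b,
       fc_out_W = object$model$fc2$W, fc_out_b = object$model$fc2$b)
}

#' @describeIn fit.fibronet plot the training and validation loss curves.
#' @param x a `fibrofit`.
#' @export
plot.fibrofit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("blue", "red"), xlab = "epoch",
                    ylab = "loss per sample", ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
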