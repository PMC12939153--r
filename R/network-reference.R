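# Slow reference implementations of every layer operation in the network.
#
# These are deliberately literal, loop-based translations of the layer
# definitions — true (kernel-flipped) convolution, windowed maxima,
# spatial means, affine maps, regular subsampling, elementwise residual
# addition — used as independent oracles against the fast production
# kernels.  All operations zero-pad at the boundary so that the declared
# output size of every layer equals its input size divided by the stride.
#
# Index convention (matching the production kernels): an output element
# (m, n), 1-based, is centered on input element (S*m, S*n).

#' Reference 2-D convolution
#'
#' Literal true convolution (the kernel is index-flipped, unlike the
#' cross-correlation most deep-learning frameworks compute): for 1-based
#' output indices `(m, n)`,
#' `Y[m, n] = sum_{i,j} Kf[h - i + 1, h - j + 1] * X[S*m + i, S*n + j]`
#' with `h = (K - 1) / 2`, out-of-range input treated as zero.
#'
#' @param X numeric matrix.
#' @param Kf odd-sized square numeric filter.
#' @param S stride (output is `floor(dim(X) / S)`).
#' @return Numeric matrix of size `floor(nrow(X)/S) x floor(ncol(X)/S)`.
#' @export
conv2d_reference <- function(X, Kf, S = 1L) {
  if (nrow(Kf) > nrow(X) || ncol(Kf) > ncol(X)) stop("filter exceeds input")
  conv2d_pad_ref(X, Kf, S)
}

# the padded convolution itself, without the size guard (layers in the
# network may legitimately see maps smaller than the filter, where the
# zero padding covers the overhang)
conv2d_pad_ref <- function(X, Kf, S = 1L) {
  K <- nrow(Kf)
  stopifnot(is.matrix(X), is.matrix(Kf), ncol(Kf) == K, K %% 2L == 1L, S >= 1L)
  h <- (K - 1L) %/% 2L
  M <- nrow(X) %/% S; N <- ncol(X) %/% S
  Y <- matrix(0, M, N)
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      acc <- 0
      for (i in -h:h) {
        r <- S * m + i
        if (r < 1L || r > nrow(X)) next
        for (j in -h:h) {
          c <- S * n + j
          if (c < 1L || c > ncol(X)) next
          acc <- acc + Kf[h - i + 1L, h - j + 1L] * X[r, c]
        }
      }
      Y[m, n] <- acc
    }
  }
  Y
}

#' Reference multi-channel convolution layer
#'
#' Each output channel is the sum over input channels of the reference
#' convolution with that channel pair's filter, plus an optional bias,
#' followed by an elementwise rectifier (ReLU), so all outputs are
#' non-negative.
#'
#' @param inputs numeric array `(H, W, C_in)`.
#' @param filters numeric array `(K, K, C_in, C_out)`.
#' @param S stride.
#' @param bias length-`C_out` numeric vector (default zeros).
#' @param relu apply the rectifier (default `TRUE`, as in the layer
#'   definition); set `FALSE` to inspect the linear response.
#' @return Numeric array `(H/S, W/S, C_out)`.
#' @export
conv_layer_reference <- function(inputs, filters, S = 1L, bias = NULL,
                                 relu = TRUE) {
  stopifnot(length(dim(inputs)) == 3L, length(dim(filters)) == 4L)
  Cin <- dim(inputs)[3]; Cout <- dim(filters)[4]
  if (dim(filters)[3] != Cin) {
    stop("channel mismatch: filters expect ", dim(filters)[3],
         " input channels, got ", Cin)
  }
  if (is.null(bias)) bias <- numeric(Cout)
  M <- dim(inputs)[1] %/% S; N <- dim(inputs)[2] %/% S
  out <- array(0, c(M, N, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(bias[co], M, N)
    for (ci in seq_len(Cin)) {
      Xci <- matrix(inputs[, , ci], dim(inputs)[1], dim(inputs)[2])
      acc <- acc + conv2d_pad_ref(Xci, filters[, , ci, co], S)
    }
    out[, , co] <- if (relu) pmax(acc, 0) else acc
  }
  out
}

#' Reference max-pooling
#'
#' Windowed maxima at stride `S`, window centered on input element
#' `(S*m, S*n)`; out-of-range positions contribute zeros (consistent with
#' the zero-padded convolution boundary rule).
#'
#' @param X numeric matrix.
#' @param K odd window size.
#' @param S stride.
#' @return Numeric matrix of size `floor(dim(X) / S)`.
#' @export
maxpool_reference <- function(X, K = 3L, S = 2L) {
  stopifnot(is.matrix(X), K %% 2L == 1L, S >= 1L)
  if (K > nrow(X) || K > ncol(X)) stop("window exceeds input")
  h <- (K - 1L) %/% 2L
  M <- nrow(X) %/% S; N <- ncol(X) %/% S
  Y <- matrix(0, M, N)
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      rs <- (S * m - h):(S * m + h)
      cs <- (S * n - h):(S * n + h)
      vals <- X[rs[rs >= 1 & rs <= nrow(X)], cs[cs >= 1 & cs <= ncol(X)]]
      pad <- length(vals) < K * K
      Y[m, n] <- if (pad) max(vals, 0) else max(vals)
    }
  }
  Y
}

#' Global average pooling
#'
#' Collapses each channel to its spatial mean, producing the feature
#' vector handed to the fully connected head.
#'
#' @param inputs numeric array `(M, N, C)`.
#' @return Numeric vector of length `C`.
#' @export
global_avgpool <- function(inputs) {
  stopifnot(length(dim(inputs)) == 3L)
  apply(inputs, 3L, mean)
}

#' Fully connected layer forward pass
#'
#' Affine map `a = W x + b` followed by the configured activation: the
#' rectifier for hidden layers, identity for the scalar output unit.
#'
#' @param x input vector of length `M`.
#' @param W `N x M` weight matrix.
#' @param b length-`N` bias vector.
#' @param activation `"relu"` or `"identity"`.
#' @return Numeric vector of length `N`.
#' @export
fc_forward <- function(x, W, b, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(W) != length(x) || nrow(W) != length(b)) {
    stop("size mismatch: W is ", nrow(W), " x ", ncol(W),
         ", x has length ", length(x))
  }
  a <- drop(W %*% x + b)
  if (activation == "relu") pmax(a, 0) else a
}

#' Skip-path down-sampling
#'
#' Regular subsampling by the stride: `Y[m, n] = X[S*m, S*n]`.  With
#' `S = 1` the input is returned unchanged (the equal-size residual case).
#'
#' @param X numeric matrix.
#' @param S stride.
#' @return Numeric matrix of size `floor(dim(X) / S)`.
#' @export
downsample_skip <- function(X, S = 1L) {
  stopifnot(is.matrix(X), S >= 1L)
  if (S == 1L) return(X)
  X[S * seq_len(nrow(X) %/% S), S * seq_len(ncol(X) %/% S), drop = FALSE]
}

#' Residual addition
#'
#' Elementwise sum of the main path and the (already down-sampled) skip
#' path; the defining operation of a residual connection.
#'
#' @param main,skip numeric arrays of identical shape.
#' @return Their elementwise sum.
#' @export
residual_add <- function(main, skip) {
  if (!identical(dim(main), dim(skip))) {
    stop("shape mismatch between main and skip inputs")
  }
  main + skip
}
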