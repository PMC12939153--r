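# Statistical evaluation suite: error norms (E2, E1), goodness of fit
# (R2, C), and linear regression diagnostics (through-origin slope r,
# ordinary slope m and intercept b), computed on per-image mean estimated
# scores against per-image mean true scores.  Ideal values: E2 = E1 = 0,
# R2 = C = 1, r = m = 1, b = 0.

#' Mean estimated score over orientations
#'
#' The per-image estimate is the arithmetic mean of the network's scores
#' across the image's spatial orientations.
#'
#' @param scores numeric vector of per-orientation scores.
#' @return Their mean.
#' @export
mean_estimate <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  mean(scores)
}

#' Error norms
#'
#' Mean squared error `E2` and mean absolute error `E1` between true and
#' estimated per-image mean scores.
#'
#' @param true,est equal-length numeric vectors.
#' @return Named numeric `c(E2, E1)`.
#' @examples
#' error_norms(c(2, 4), c(3, 3))  # both 1
#' @export
error_norms <- function(true, est) {
  if (length(true) != length(est)) stop("length mismatch")
  if (length(true) == 0L) stop("empty inputs")
  c(E2 = mean((true - est)^2), E1 = mean(abs(true - est)))
}

#' Goodness-of-fit coefficients
#'
#' The coefficient of determination
#' `R2 = 1 - sum((true - est)^2) / sum((true - mean(true))^2)` and the
#' Pearson correlation `C` between true and estimated scores.
#'
#' @param true,est equal-length numeric vectors, `n >= 2`.
#' @return Named numeric `c(R2, C)`.
#' @export
goodness_of_fit <- function(true, est) {
  if (length(true) != length(est)) stop("length mismatch")
  n <- length(true)
  if (n < 2L) stop("need at least 2 samples")
  sst <- sum((true - mean(true))^2)
  if (sst == 0) stop("degenerate sample: true scores have zero variance")
  if (stats::var(est) == 0) stop("degenerate sample: estimates have zero variance")
  c(R2 = 1 - sum((true - est)^2) / sst, C = stats::cor(true, est))
}

#' Regression slopes and intercept
#'
#' Least-squares fits of estimated on true scores: the through-origin
#' slope `r` (intercept constrained to zero), and the ordinary slope `m`
#' and intercept `b`.
#'
#' @param true,est equal-length numeric vectors, `n >= 2`.
#' @return Named numeric `c(r, m, b)`.
#' @examples
#' regression_fits(c(1, 2, 3), c(2, 3, 5))  # r = 23/14, m = 3/2, b = 1/3
#' @export
regression_fits <- function(true, est) {
  if (length(true) != length(est)) stop("length mismatch")
  if (length(true) < 2L) stop("need at least 2 samples")
  if (sum(true^2) == 0) stop("singular fit: all true scores are zero")
  if (stats::var(true) == 0) stop("singular fit: true scores are constant")
  r <- sum(true * est) / sum(true^2)
  co <- stats::coef(stats::lm(est ~ true))
  c(r = r, m = unname(co["true"]), b = unname(co["(Intercept)"]))
}

#' Full metric report
#'
#' Aggregates all seven evaluation metrics plus the sample means and the
#' sample count into a `metric_report`, printed in the layout of the
#' summary tables this suite feeds.
#'
#' @param true,est equal-length numeric vectors of per-image mean true
#'   and estimated scores.
#' @return A list of class `metric_report` with elements `E2`, `E1`,
#'   `R2`, `C`, `r`, `m`, `b`, `mean_true`, `mean_est`, `n`.
#' @export
full_report <- function(true, est) {
  en <- error_norms(true, est)
  gf <- goodness_of_fit(true, est)
  rg <- regression_fits(true, est)
  structure(list(E2 = unname(en["E2"]), E1 = unname(en["E1"]),
                 R2 = unname(gf["R2"]), C = unname(gf["C"]),
                 r = unname(rg["r"]), m = unname(rg["m"]),
                 b = unname(rg["b"]),
                 mean_true = mean(true), mean_est = mean(est),
                 n = length(true)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("Metric report (n = %d)\n", x$n))
  v <- unlist(x[c("E2", "E1", "R2", "C", "r", "m", "b")])
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(E2 = x$E2, E1 = x$E1, R2 = x$R2, C = x$C,
             r = x$r, m = x$m, b = x$b, n = x$n)
}
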