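#' Preprocessing configuration
#'
#' Settings for converting raw product photographs into square,
#' background-free, centroid-centered network inputs.
#'
#' @param background_threshold integer in \[0, 255\]; pixels whose mean
#'   channel intensity falls strictly below it are recolored black.  The
#'   appropriate value depends on the acquisition setup, so no default is
#'   provided.
#' @param target_size side length in pixels of the square output canvas.
#'   Defaults to 6032, the full acquisition scale; much smaller values are
#'   perfectly usable for reduced-resolution runs.
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(background_threshold, target_size = 6032L) {
  stopifnot(length(background_threshold) == 1L,
            background_threshold >= 0, background_threshold <= 255,
            length(target_size) == 1L, target_size >= 1)
  structure(list(background_threshold = as.integer(background_threshold),
                 target_size = as.integer(target_size)),
            class = "prep_config")
}

#' Recolor background pixels black
#'
#' Applies a pixelwise intensity threshold: every pixel whose mean channel
#' intensity is strictly below `threshold` becomes (0, 0, 0); all other
#' pixels are left untouched.  The mean of the three channels is compared
#' because the grey-card imaging background is near-achromatic.
#'
#' @param img a [raster_image()].
#' @param threshold integer in \[0, 255\].
#' @return A [raster_image()] of the same size.
#' @examples
#' px <- array(200L, c(2, 2, 3)); px[1, 1, ] <- 10L
#' remove_background(raster_image(px), threshold = 100)
#' @export
remove_background <- function(img, threshold) {
  stopifnot(inherits(img, "raster_image"),
            threshold >= 0, threshold <= 255)
  px <- img$pixels
  below <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3 < threshold
  px[, , 1][below] <- 0L
  px[, , 2][below] <- 0L
  px[, , 3][below] <- 0L
  raster_image(px, id = img$id, orientation_tag = img$orientation_tag)
}

#' Centroid of the figure region
#'
#' Returns the unweighted mean (row, col) position of all non-black pixels
#' — the centroid of the figure (food-matrix) region after background
#' removal.  Unweighted, so illumination gradients across the figure do not
#' shift it.  Indices are 1-based.
#'
#' @param img a [raster_image()].
#' @return Numeric `c(row, col)`.
#' @export
figure_centroid <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  nb <- figure_mask(img)
  if (!any(nb)) stop("empty figure: image is entirely black")
  idx <- which(nb, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

# logical H x W mask of non-black pixels
figure_mask <- function(img) {
  px <- img$pixels
  px[, , 1] != 0L | px[, , 2] != 0L | px[, , 3] != 0L
}

#' Zero-pad to square and center the figure
#'
#' Embeds the image in a black `target_size` x `target_size` canvas,
#' translated so that the figure centroid (rounded half-away-from-zero)
#' lands on the canvas mid-point, index `target_size %/% 2 + 1`.  Figure
#' pixels are preserved bit-exactly; only black background may be cropped.
#' The operation is idempotent: a centered image passes through unchanged.
#'
#' @param img a [raster_image()] that has had its background removed.
#' @param cfg a [prep_config()].
#' @return A square [raster_image()] of side `cfg$target_size`.
#' @export
pad_and_center <- function(img, cfg) {
  stopifnot(inherits(img, "raster_image"), inherits(cfg, "prep_config"))
  n <- cfg$target_size
  nb <- figure_mask(img)
  if (!any(nb)) stop("empty figure: image is entirely black")
  idx <- which(nb, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  mid <- n %/% 2 + 1L
  # integer translation taking the rounded centroid onto the canvas mid-point
  off <- mid - round_half_away(ctr)
  r1 <- min(idx[, 1]) + off[1]; r2 <- max(idx[, 1]) + off[1]
  c1 <- min(idx[, 2]) + off[2]; c2 <- max(idx[, 2]) + off[2]
  if (r1 < 1 || c1 < 1 || r2 > n || c2 > n) {
    stop("target size too small: figure does not fit after centering")
  }
  out <- array(0L, c(n, n, 3L))
  # copy the part of the source grid that lands on the canvas
  src_r <- max(1L, 1L - off[1]):min(dim(img)[1], n - off[1])
  src_c <- max(1L, 1L - off[2]):min(dim(img)[2], n - off[2])
  out[src_r + off[1], src_c + off[2], ] <- img$pixels[src_r, src_c, ]
  raster_image(out, id = img$id, orientation_tag = img$orientation_tag)
}

#' Full preprocessing of one raw photograph
#'
#' Background removal followed by pad-and-center; the standard path from a
#' raw photograph to a network-ready square image.
#'
#' @inheritParams pad_and_center
#' @return A square [raster_image()].
#' @export
preprocess_image <- function(img, cfg) {
  pad_and_center(remove_background(img, cfg$background_threshold), cfg)
}
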