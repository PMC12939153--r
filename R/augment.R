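# Spatial orientation augmentation.
#
# Square images admit 8 lossless symmetries (4 right-angle rotations x
# optional mirror); these are pure index permutations, so pixel values are
# conserved exactly.  Synthetic stimuli additionally use a fine rotation
# set (default every 22.5 degrees, 32 orientations) with bilinear
# resampling and black fill outside the frame.

# one clockwise quarter-turn of a matrix
rot_cw_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_channels <- function(px, f) {
  ch <- lapply(1:3, function(k) f(px[, , k]))
  array(c(ch[[1]], ch[[2]], ch[[3]]), c(dim(ch[[1]]), 3L))
}

rotate_quarter <- function(img, quarters) {
  px <- img$pixels
  for (q in seq_len(quarters %% 4L)) px <- apply_channels(px, rot_cw_mat)
  px
}

mirror_lr <- function(px) apply_channels(px, function(m) m[, ncol(m):1, drop = FALSE])

#' The eight dihedral orientations of a square image
#'
#' Returns the four right-angle clockwise rotations (0, 90, 180, 270
#' degrees) of the image followed by the four rotations of its mirror
#' (left-right flipped) image.  All eight are pure index permutations —
#' no interpolation — so the pixel-value histogram is conserved exactly.
#' Orientation tags are `r000, r090, r180, r270, m000, m090, m180, m270`.
#'
#' @param img a square [raster_image()].
#' @return A list of 8 [raster_image()]s in the fixed tag order above.
#' @export
dihedral_orientations <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  d <- dim(img$pixels)
  if (d[1] != d[2]) stop("square required: image is ", d[1], " x ", d[2])
  base <- list(r = img$pixels, m = mirror_lr(img$pixels))
  out <- vector("list", 8L)
  i <- 0L
  for (fl in c("r", "m")) {
    px <- base[[fl]]
    for (q in 0:3) {
      i <- i + 1L
      out[[i]] <- raster_image(px, id = img$id,
                               orientation_tag = sprintf("%s%03d", fl, 90L * q))
      px <- apply_channels(px, rot_cw_mat)
    }
  }
  out
}

# bilinear rotation by `angle` degrees clockwise about the geometric image
# center; out-of-frame samples are black
rotate_bilinear <- function(px, angle) {
  h <- dim(px)[1]; w <- dim(px)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  dy <- rep(seq_len(h) - cy, times = w)
  dx <- rep(seq_len(w) - cx, each = h)
  sx <- co * dx + si * dy + cx
  sy <- -si * dx + co * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  out <- array(0, c(h, w, 3L))
  # gather with zero fill for the four bilinear neighbours
  gather <- function(ch, yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(h * w)
    v[ok] <- ch[cbind(yy[ok], xx[ok])]
    v
  }
  for (k in 1:3) {
    ch <- px[, , k]
    v <- (1 - fy) * (1 - fx) * gather(ch, y0,     x0) +
         (1 - fy) * fx       * gather(ch, y0,     x0 + 1) +
         fy       * (1 - fx) * gather(ch, y0 + 1, x0) +
         fy       * fx       * gather(ch, y0 + 1, x0 + 1)
    out[, , k] <- v
  }
  array(as.integer(round_half_away(out)), c(h, w, 3L))
}

#' Fine rotation orientation set
#'
#' Rotations of the image and of its mirror at regular angular intervals:
#' `360 / step_degrees` rotations each, i.e. 32 orientations at the default
#' 22.5-degree step.  Rotation is clockwise about the geometric image
#' center with bilinear interpolation and black fill; angles that are exact
#' multiples of 90 degrees take the lossless index-permutation path, so at
#' `step_degrees = 90` the output is pixel-identical to
#' [dihedral_orientations()].
#'
#' @param img a square [raster_image()].
#' @param step_degrees angular step; must divide 360.
#' @return A list of `2 * 360 / step_degrees` [raster_image()]s tagged
#'   `r000.0 ... m337.5`.
#' @export
fine_orientations <- function(img, step_degrees = 22.5) {
  stopifnot(inherits(img, "raster_image"))
  d <- dim(img$pixels)
  if (d[1] != d[2]) stop("square required: image is ", d[1], " x ", d[2])
  if (!isTRUE(all.equal(360 %% step_degrees, 0)) || step_degrees <= 0) {
    stop("invalid step: ", step_degrees, " does not divide 360")
  }
  n_rot <- as.integer(round(360 / step_degrees))
  base <- list(r = img$pixels, m = mirror_lr(img$pixels))
  out <- vector("list", 2L * n_rot)
  i <- 0L
  for (fl in c("r", "m")) {
    for (k in seq_len(n_rot) - 1L) {
      ang <- k * step_degrees
      px <- if (ang %% 90 == 0) {
        p <- base[[fl]]
        for (q in seq_len(ang %/% 90)) p <- apply_channels(p, rot_cw_mat)
        p
      } else {
        rotate_bilinear(base[[fl]], ang)
      }
      i <- i + 1L
      out[[i]] <- raster_image(px, id = img$id,
                               orientation_tag = sprintf("%s%05.1f", fl, ang))
    }
  }
  out
}
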