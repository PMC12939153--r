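#' Raster image container
#'
#' A `raster_image` holds an H x W x 3 array of integer pixel values in
#' \[0, 255\] together with provenance metadata: an image identifier and an
#' orientation tag (set by the augmentation functions).
#'
#' @param pixels numeric or integer array of dimension `c(H, W, 3)` with
#'   values in \[0, 255\].  A single-channel `H x W` matrix is replicated
#'   across the three channels.
#' @param id character image identifier.
#' @param orientation_tag character orientation label; `"r000"` denotes the
#'   unrotated original.
#'
#' @return An object of class `raster_image` with elements `pixels`
#'   (integer array), `id` and `orientation_tag`.
#' @examples
#' img <- raster_image(array(128L, c(4, 4, 3)), id = "ex")
#' dim(img)
#' @export
raster_image <- function(pixels, id = "img", orientation_tag = "r000") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, id = as.character(id),
         orientation_tag = as.character(orientation_tag)),
    class = "raster_image"
  )
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %s [%s]  %d x %d x %d, pixel range %d..%d\n",
              x$id, x$orientation_tag, d[1], d[2], d[3],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @describeIn raster_image display the image via [graphics::rasterImage()].
#' @param x,y a `raster_image`; `y` is ignored (plot method signature).
#' @param ... passed on to [graphics::plot()].
#' @export
plot.raster_image <- function(x, y, ...) {
  graphics::plot(0:1, 0:1, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = dim(x$pixels)[1] / dim(x$pixels)[2],
                 main = paste(x$id, x$orientation_tag), ...)
  graphics::rasterImage(x$pixels / 255, 0, 0, 1, 1)
}

#' Read an image file as a `raster_image`
#'
#' Supports PNG, TIFF and JPEG input.  Pixel intensities are rescaled to
#' integers in \[0, 255\]; greyscale and alpha-carrying images are promoted
#' or reduced to three channels.
#'
#' @param path file path; format inferred from the extension.
#' @param id image identifier, defaulting to the file name without extension.
#' @return A [raster_image()].
#' @export
read_image <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  raster_image(round(arr * 255), id = id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a `raster_image` to a PNG file
#'
#' PNG is the only supported output format: it is lossless, so preprocessing
#' guarantees (bit-exact figure preservation) survive a round trip to disk.
#'
#' @param img a [raster_image()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
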