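# RGBA image helpers. Images are plain H x W x 4 arrays with values in [0, 1];
# channel 4 is the alpha mask (0 = transparent background).

#' Construct an RGBA image
#'
#' Validates and returns an `H x W x 4` numeric array with values in
#' \eqn{[0, 1]}. Channel 4 is the alpha mask; `alpha = 0` marks transparent
#' background pixels.
#'
#' @param pixels numeric array, `H x W x 4`, values in `[0, 1]`.
#' @return the validated array, invisibly classed as `"rgba_image"`.
#' @export
rgba_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 4L)
    stop("an RGBA image must be an H x W x 4 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("RGBA values must lie in [0, 1]")
  class(pixels) <- c("rgba_image", class(pixels))
  pixels
}

#' Read / write transparent-background fruit images
#'
#' Thin wrappers over [png::readPNG()] / [png::writePNG()] that always return
#' or accept `H x W x 4` RGBA arrays. Grayscale or RGB input PNGs are expanded
#' with an opaque alpha channel.
#'
#' @param path file path of a PNG image.
#' @param image an RGBA array as returned by [rgba_image()].
#' @return `read_rgba()` returns an `H x W x 4` array; `write_rgba()` returns
#'   `path` invisibly.
#' @export
read_rgba <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 3L) x <- array(c(x, rep(1, prod(dim(x)[1:2]))), c(dim(x)[1:2], 4L))
  rgba_image(x[, , 1:4, drop = FALSE])
}

#' @rdname read_rgba
#' @export
write_rgba <- function(image, path) {
  png::writePNG(unclass(image), path)
  invisible(path)
}

#' Composite an RGBA image over a white background
#'
#' Transparent-background datasets carry their silhouette in the alpha
#' channel; all pixel-level computation in this package (encoding, losses,
#' descriptors) operates on the image composited over white so that the
#' background is deterministic.
#'
#' @param image an `H x W x 4` RGBA array.
#' @return an `H x W x 3` RGB array in `[0, 1]`.
#' @export
composite_white <- function(image) {
  a <- image[, , 4]
  out <- array(0, c(dim(image)[1:2], 3L))
  for (c in 1:3) out[, , c] <- image[, , c] * a + (1 - a)
  out
}

# ITU-R 601 luma weights, shared by grayscale conversion everywhere.
LUMA601 <- c(0.299, 0.587, 0.114)

#' Convert an image to grayscale (ITU-R 601 luma)
#'
#' RGBA input is composited over white first; RGB input is converted directly.
#'
#' @param image `H x W x 3` RGB or `H x W x 4` RGBA array.
#' @return an `H x W` matrix in `[0, 1]`.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (dim(image)[3] == 4L) image <- composite_white(image)
  LUMA601[1] * image[, , 1] + LUMA601[2] * image[, , 2] + LUMA601[3] * image[, , 3]
}

#' Foreground mask of an RGBA image
#'
#' @param image RGBA array.
#' @param threshold alpha value above which a pixel counts as foreground.
#' @return logical `H x W` matrix.
#' @export
alpha_mask <- function(image, threshold = 0.5) image[, , 4] > threshold

# Bilinear resize of a single-channel matrix (delegates to EBImage).
resize_bilinear <- function(m, H, W) {
  out <- EBImage::resize(EBImage::Image(m), w = H, h = W)
  matrix(EBImage::imageData(out), H, W)
}

# Moment-based eccentricity of a logical mask: sqrt(1 - lambda2/lambda1) of
# the foreground covariance eigenvalues. 0 for a disc, -> 1 for a line.
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  cv <- stats::cov(idx)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# Largest connected foreground component of a logical mask (EBImage::bwlabel).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(EBImage::imageData(lab), nrow(mask), ncol(mask))
  if (max(lab) == 0) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}
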