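# Multi-scale structural similarity (shape similarity surrogate).

#' MS-SSIM configuration
#'
#' Standard multi-scale SSIM with a Gaussian window (sd = 1.5) and the
#' canonical five per-scale exponents. When an image is too small for the
#' requested number of dyadic scales, the scale count is reduced so the
#' coarsest scale still fits the window, and the exponents are renormalized
#' to sum to one (a 64 x 64 image with an 11-pixel window uses 3 scales).
#'
#' @param window Gaussian window width in pixels (odd).
#' @param scales maximum number of dyadic scales.
#' @param scale_weights per-scale exponents, length `scales`.
#' @param C1,C2 stabilizing constants for the luminance and
#'   contrast/structure terms (dynamic range 1).
#' @return a list of class `"msssim_config"`.
#' @export
msssim_config <- function(window = 11L, scales = 5L,
                          scale_weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                          C1 = 0.01^2, C2 = 0.03^2) {
  if (length(scale_weights) != scales)
    stop("scale_weights length must equal scales")
  structure(list(window = as.integer(window), scales = as.integer(scales),
                 scale_weights = scale_weights, C1 = C1, C2 = C2),
            class = "msssim_config")
}

gaussian_window <- function(n, sigma = 1.5) {
  x <- seq_len(n) - (n + 1) / 2
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

msssim_nscales <- function(H, W, cfg) {
  m <- floor(log2(min(H, W) / cfg$window)) + 1
  if (m < 1) stop("image too small for the MS-SSIM window")
  min(cfg$scales, m)
}

# tape implementation; xn, yn are H x W (x 1) nodes on the same tape
ag_msssim <- function(xn, yn, cfg) {
  tape <- xn$tape
  d <- dim(as3d(xn$value))
  M <- msssim_nscales(d[1], d[2], cfg)
  w <- cfg$scale_weights[seq_len(M)]
  w <- w / sum(w)
  kern <- gaussian_window(cfg$window)
  wk <- ag_const(tape, matrix(as.numeric(kern), nrow = 1))
  b0 <- ag_const(tape, 0)
  blur <- function(z) ag_conv2d(z, wk, b0, cfg$window, cfg$window, 1L)
  out <- NULL
  for (j in seq_len(M)) {
    mux <- blur(xn); muy <- blur(yn)
    mux2 <- ag_mul(mux, mux); muy2 <- ag_mul(muy, muy)
    muxy <- ag_mul(mux, muy)
    sxx <- ag_sub(blur(ag_mul(xn, xn)), mux2)
    syy <- ag_sub(blur(ag_mul(yn, yn)), muy2)
    sxy <- ag_sub(blur(ag_mul(xn, yn)), muxy)
    cs <- ag_div(ag_adds(ag_muls(sxy, 2), cfg$C2),
                 ag_adds(ag_add(sxx, syy), cfg$C2))
    csbar <- ag_mean(cs)
    term <- ag_pow_s(ag_adds(ag_relu(csbar), 1e-8), w[j])
    out <- if (is.null(out)) term else ag_mul(out, term)
    if (j == M) {
      l <- ag_div(ag_adds(ag_muls(muxy, 2), cfg$C1),
                  ag_adds(ag_add(mux2, muy2), cfg$C1))
      lterm <- ag_pow_s(ag_adds(ag_relu(ag_mean(l)), 1e-8), w[M])
      out <- ag_mul(out, lterm)
    } else {
      xn <- ag_avgpool2(xn); yn <- ag_avgpool2(yn)
    }
  }
  out
}

#' Multi-scale structural similarity index
#'
#' `ms_ssim(x, x) = 1` for any valid image. Images are compared as grayscale
#' (RGBA inputs are composited over white and converted by ITU-R 601 luma).
#' At each scale the contrast/structure term is averaged over a Gaussian
#' sliding window; the luminance term enters at the coarsest scale only, and
#' the per-scale means are combined by the exponent weights.
#'
#' @param a,b images of identical size: `H x W` matrices, RGB or RGBA arrays.
#' @param cfg an [msssim_config()].
#' @return similarity, `<= 1`.
#' @export
ms_ssim <- function(a, b, cfg = msssim_config()) {
  ga <- to_gray(a); gb <- to_gray(b)
  if (!all(dim(ga) == dim(gb))) stop("images differ in size")
  tape <- ag_tape()
  ag_msssim(ag_const(tape, ga), ag_const(tape, gb), cfg)$value
}
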