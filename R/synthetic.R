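# Seeded generator of transparent-background pseudo-fruit domains differing in
# shape, colour and texture; stands in for the pear / pitaya / eggplant /
# cucumber transparent-background datasets so everything is testable offline.

#' Specification of a synthetic fruit domain
#'
#' A domain is a superellipse silhouette family with an aspect-ratio range,
#' a colour palette (RGB anchors plus jitter) and a procedural surface
#' texture rendered before alpha masking, so texture statistics are
#' mask-independent.
#'
#' @param shape `"round"`, `"oval"`, `"elongated"` or `"scaled-lobed"`.
#' @param aspect_range length-2 numeric in `[1, 6]`, major/minor axis ratio.
#' @param palette list of RGB anchor vectors (values in `[0, 1]`).
#' @param color_jitter per-channel jitter half-width.
#' @param texture `"smooth"`, `"stripes"`, `"dots"` or `"scales"`.
#' @param texture_freq cycles across the fruit.
#' @param texture_contrast modulation amplitude in `[0, 1]`.
#' @param size canvas size in pixels (square).
#' @return a list of class `"domain_spec"`.
#' @export
domain_spec <- function(shape = c("round", "oval", "elongated", "scaled-lobed"),
                        aspect_range = c(1, 1.1),
                        palette = list(c(0.9, 0.8, 0.3)),
                        color_jitter = 0.05,
                        texture = c("smooth", "stripes", "dots", "scales"),
                        texture_freq = 6, texture_contrast = 0.3,
                        size = 256L) {
  shape <- match.arg(shape)
  texture <- match.arg(texture)
  if (any(aspect_range < 1) || any(aspect_range > 6))
    stop("aspect_range must lie within [1, 6]")
  if (length(palette) == 0L) stop("palette must be non-empty")
  structure(list(shape = shape, aspect_range = aspect_range, palette = palette,
                 color_jitter = color_jitter, texture = texture,
                 texture_freq = texture_freq, texture_contrast = texture_contrast,
                 size = as.integer(size)),
            class = "domain_spec")
}

#' Draw one synthetic fruit image
#'
#' Renders an anti-aliased superellipse silhouette with aspect ratio drawn
#' from the domain's range, procedural texture modulating the base colour
#' inside the mask, and a transparent background. Foreground coverage is
#' kept within `[0.10, 0.60]` of the canvas. Consumes the current R random
#' stream: the same RNG state reproduces the same image.
#'
#' @param spec a [domain_spec()].
#' @return an `H x W x 4` RGBA array.
#' @export
make_fruit <- function(spec) {
  S <- spec$size
  aspect <- stats::runif(1, spec$aspect_range[1], spec$aspect_range[2])
  cov_hi <- min(0.55, pi * 0.47^2 / aspect)
  cov_lo <- max(0.11, min(0.14, 0.85 * cov_hi))
  coverage <- stats::runif(1, cov_lo, max(cov_hi, cov_lo + 0.005))
  ab <- coverage * S^2 / pi
  b <- sqrt(ab / aspect); a <- aspect * b
  theta <- if (spec$shape %in% c("elongated", "oval"))
    stats::runif(1, -pi / 12, pi / 12) else stats::runif(1, -pi, pi)
  m <- switch(spec$shape, round = 2, oval = 2, elongated = 2.6, `scaled-lobed` = 2)
  cx <- S / 2 + stats::runif(1, -S * 0.02, S * 0.02)
  cy <- S / 2 + stats::runif(1, -S * 0.02, S * 0.02)
  xs <- matrix(rep(seq_len(S) - cx, S), S, S)          # rows
  ys <- matrix(rep(seq_len(S) - cy, each = S), S, S)   # cols
  u <- cos(theta) * xs + sin(theta) * ys
  v <- -sin(theta) * xs + cos(theta) * ys
  d <- (abs(u / a)^m + abs(v / b)^m)^(1 / m)
  if (spec$shape == "scaled-lobed") {
    nl <- sample(6:9, 1)
    amp <- stats::runif(1, 0.04, 0.08)
    ph <- stats::runif(1, 0, 2 * pi)
    d <- d / (1 + amp * cos(nl * atan2(v, u) + ph))
  }
  # anti-alias over ~1.2 px: distance to the boundary along the ray through
  # each pixel is (1 - d) * r / d (r = pixel radius from the centre)
  r <- sqrt(u^2 + v^2)
  px_dist <- ifelse(d > 1e-9, (1 - d) * r / pmax(d, 1e-9), 10)
  alpha <- pmin(1, pmax(0, 0.5 + px_dist / 1.2))
  # procedural texture in [-1, 1], defined over the whole canvas (pre-alpha)
  fr <- spec$texture_freq * 2 * pi
  tex <- switch(spec$texture,
    smooth = 0.15 * (1 - d),
    stripes = sin(fr * v / (2 * b) + stats::runif(1, 0, 2 * pi)),
    dots = {
      g <- sin(fr * u / (2 * a)) * sin(fr * v / (2 * b))
      ifelse(g > 0.45, 1, -0.4)
    },
    scales = {
      g <- abs(sin(fr * u / (2 * a))) + abs(sin(fr * v / (2 * b) + pi / 4))
      2 * (g / 2)^1.5 - 1
    })
  anchor <- spec$palette[[sample.int(length(spec$palette), 1)]]
  base <- pmin(1, pmax(0, anchor + stats::runif(3, -1, 1) * spec$color_jitter))
  shade <- 1 - 0.25 * pmin(d, 1)^2
  out <- array(0, c(S, S, 4L))
  for (c in 1:3)
    out[, , c] <- pmin(1, pmax(0, base[c] * shade * (1 + spec$texture_contrast * tex)))
  out[, , 4] <- alpha
  rgba_image(out)
}

#' Draw a reproducible batch of fruits from one domain
#'
#' @param spec a [domain_spec()].
#' @param n number of images.
#' @param seed integer seed for the domain's private random stream (the
#'   global RNG state is restored afterwards).
#' @return list of `n` RGBA arrays.
#' @export
make_domain <- function(spec, n, seed = 1L) {
  if (n < 1L) stop("n must be at least 1")
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) make_fruit(spec))
}

#' The four reference fruit domains
#'
#' Fixed specifications emulating the study's source and target domains:
#' a round smooth yellow fruit (pear-like source), a round scaled magenta
#' fruit (pitaya-like), an elongated smooth purple fruit (eggplant-like,
#' aspect 2.5-4) and an elongated striped green fruit (cucumber-like,
#' aspect 3-6). Any two differ in at least one of shape, colour or texture.
#'
#' @param size canvas size in pixels.
#' @return named list of [domain_spec()] objects: `pear_like`,
#'   `pitaya_like`, `eggplant_like`, `cucumber_like`.
#' @export
default_domains <- function(size = 256L) {
  list(
    pear_like = domain_spec("round", c(1, 1.1),
                            palette = list(c(0.92, 0.82, 0.30), c(0.85, 0.78, 0.35)),
                            texture = "smooth", texture_contrast = 0.15, size = size),
    pitaya_like = domain_spec("scaled-lobed", c(1, 1.2),
                              palette = list(c(0.85, 0.10, 0.45), c(0.80, 0.15, 0.50)),
                              texture = "scales", texture_freq = 8,
                              texture_contrast = 0.45, size = size),
    eggplant_like = domain_spec("elongated", c(2.5, 4),
                                palette = list(c(0.30, 0.10, 0.45), c(0.25, 0.08, 0.40)),
                                texture = "smooth", texture_contrast = 0.15, size = size),
    cucumber_like = domain_spec("elongated", c(3, 6),
                                palette = list(c(0.20, 0.55, 0.20), c(0.25, 0.60, 0.18)),
                                texture = "stripes", texture_freq = 10,
                                texture_contrast = 0.35, size = size))
}
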