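# Local binary pattern texture descriptor, hard and differentiable-soft, and
# the texture loss comparing LBP maps by Pearson correlation.

#' LBP configuration
#'
#' Circular local binary pattern with `P` neighbours at the given radius,
#' sampled by bilinear interpolation, neighbour `p = 0` at angle 0 and
#' subsequent neighbours proceeding counter-clockwise. The default `P = 16`
#' is the neighbourhood size found to work best at the 256 x 256 working
#' resolution of the fruit datasets; `radius = 2` matches it. In `"soft"`
#' mode the hard sign `1[x >= 0]` is replaced by `sigmoid(x / temperature)`
#' so that the descriptor is differentiable and can serve as a training loss.
#'
#' @param P neighbour count (>= 4).
#' @param radius sampling radius in pixels (>= 1).
#' @param mode `"hard"` or `"soft"`.
#' @param temperature softness scale on `[0, 1]` intensities (soft mode).
#' @return a list of class `"lbp_config"`.
#' @export
lbp_config <- function(P = 16L, radius = 2L, mode = c("hard", "soft"),
                       temperature = 0.1) {
  mode <- match.arg(mode)
  if (P < 4L) stop("P must be at least 4")
  if (radius < 1L) stop("radius must be at least 1")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(P = as.integer(P), radius = radius, mode = mode,
                 temperature = temperature), class = "lbp_config")
}

# neighbour offsets (dy, dx) in row/col pixels; p = 0 at angle 0, CCW
lbp_offsets <- function(P, radius) {
  th <- 2 * pi * (seq_len(P) - 1L) / P
  cbind(dy = -radius * sin(th), dx = radius * cos(th))
}

#' LBP code of a single pixel
#'
#' `sum_p 2^p * s(i_p - i_c)` with `s(x) = 1[x >= 0]` (hard) or
#' `sigmoid(x / temperature)` (soft). `s(0) = 1`, so a pixel whose
#' neighbours all equal it codes to `2^P - 1`.
#'
#' @param center centre intensity in `[0, 1]`.
#' @param neighbors ordered neighbour intensities, length `P`.
#' @param cfg an [lbp_config()].
#' @return scalar code in `[0, 2^P - 1]`.
#' @export
lbp_code <- function(center, neighbors, cfg = lbp_config()) {
  if (length(neighbors) != cfg$P)
    stop("expected ", cfg$P, " neighbours, got ", length(neighbors))
  d <- neighbors - center
  s <- if (cfg$mode == "hard") as.numeric(d >= 0) else 1 / (1 + exp(-d / cfg$temperature))
  sum(2^(seq_len(cfg$P) - 1L) * s)
}

#' LBP code map of a grayscale image
#'
#' Per-pixel circular LBP codes; neighbours beyond the border are sampled
#' with edge replication, fractional positions by bilinear interpolation.
#'
#' @param image_gray `H x W` matrix in `[0, 1]`.
#' @param cfg an [lbp_config()].
#' @return `H x W` numeric code matrix of class `"lbp_map"`; exact integers
#'   in hard mode.
#' @export
lbp_map <- function(image_gray, cfg = lbp_config()) {
  if (min(dim(image_gray)) < 2 * cfg$radius + 1)
    stop("image too small for LBP radius ", cfg$radius)
  offs <- lbp_offsets(cfg$P, cfg$radius)
  codes <- matrix(0, nrow(image_gray), ncol(image_gray))
  for (p in seq_len(cfg$P)) {
    np <- bilinear_shift_plain(image_gray, offs[p, 1], offs[p, 2])
    d <- np - image_gray
    s <- if (cfg$mode == "hard") (d >= -1e-12) * 1 else 1 / (1 + exp(-d / cfg$temperature))
    codes <- codes + 2^(p - 1L) * s
  }
  structure(codes, class = c("lbp_map", class(codes)),
            border = "replicate", mode = cfg$mode)
}

# non-tape bilinear sample at fixed offset, replicate border
bilinear_shift_plain <- function(m, dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  wts <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  offs <- list(c(y0, x0), c(y0, x0 + 1), c(y0 + 1, x0), c(y0 + 1, x0 + 1))
  out <- matrix(0, nrow(m), ncol(m))
  for (k in which(wts > 1e-12))
    out <- out + wts[k] * shift_clamp(m, offs[[k]][1], offs[[k]][2])
  out
}

# tape version of lbp_map (soft mode) for the training graph
ag_lbp_map <- function(gnode, cfg) {
  offs <- lbp_offsets(cfg$P, cfg$radius)
  acc <- NULL
  for (p in seq_len(cfg$P)) {
    np <- ag_shift_bilinear(gnode, offs[p, 1], offs[p, 2])
    s <- ag_sigmoid(ag_muls(ag_sub(np, gnode), 1 / cfg$temperature))
    term <- ag_muls(s, 2^(p - 1L))
    acc <- if (is.null(acc)) term else ag_add(acc, term)
  }
  acc
}

#' Pearson correlation with degeneracy flag
#'
#' Sample Pearson correlation of two equal-length vectors. If either input
#' has zero variance the correlation is undefined; the function returns 0
#' and flags it with attribute `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length `>= 2`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) < 2L) stop("need at least two observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0)
    return(structure(0, degenerate = TRUE))
  structure(stats::cor(a, b), degenerate = FALSE)
}

# tape Pearson over two map nodes (small eps keeps the sqrt differentiable)
ag_pearson <- function(an, bn, eps = 1e-12) {
  am <- ag_mean(an); bm <- ag_mean(bn)
  ac <- ag_sub(an, am); bc <- ag_sub(bn, bm)
  cov <- ag_mean(ag_mul(ac, bc))
  va <- ag_mean(ag_mul(ac, ac)); vb <- ag_mean(ag_mul(bc, bc))
  ag_div(cov, ag_pow_s(ag_adds(ag_mul(va, vb), eps), 0.5))
}

#' Cross-cycle texture loss
#'
#' `L_texture = (1 - rho(LBP(G_ST(s)), LBP(t))) + (1 - rho(LBP(G_TS(t)),
#' LBP(s)))`, where `rho` is the Pearson correlation between the flattened
#' LBP code maps of the generated image and its cross-cycle real counterpart
#' (both converted to grayscale over white). Minimizing the loss maximizes
#' texture correlation. A degenerate (constant) map contributes `1 - 0 = 1`.
#'
#' @param gen_st generated target-domain image (RGBA or gray matrix).
#' @param real_t real target-domain image.
#' @param gen_ts generated source-domain image.
#' @param real_s real source-domain image.
#' @param cfg an [lbp_config()]; soft mode is used during training.
#' @return scalar in `[0, 4]`.
#' @export
texture_loss <- function(gen_st, real_t, gen_ts, real_s, cfg = lbp_config()) {
  imgs <- list(gen_st, real_t, gen_ts, real_s)
  dims <- lapply(imgs, function(x) dim(x)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all images must share the same H x W")
  g <- lapply(imgs, function(x) lbp_map(to_gray(x), cfg))
  (1 - as.numeric(pearson(g[[1]], g[[2]]))) +
    (1 - as.numeric(pearson(g[[3]], g[[4]])))
}
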