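# Shared fixtures: everything is generated in code, seeded, and small.

fx_domains <- function(size = 64L) default_domains(size = size)

fx_fruit <- function(which = "pear_like", seed = 1L, size = 64L) {
  make_domain(fx_domains(size)[[which]], 1L, seed = seed)[[1]]
}

# deterministic gray textures for texture tests
fx_stripes <- function(n = 32L, freq = 4, phase = 0) {
  outer(seq_len(n), seq_len(n), function(i, j) 0.5 + 0.4 * sin(freq * 2 * pi * j / n + phase))
}

fx_dots <- function(n = 32L, freq = 4) {
  outer(seq_len(n), seq_len(n), function(i, j)
    0.5 + 0.4 * sin(freq * 2 * pi * i / n) * sin(freq * 2 * pi * j / n))
}

# gray matrix -> opaque RGBA image
fx_gray_rgba <- function(g) {
  rgba_image(array(c(g, g, g, rep(1, length(g))), c(dim(g), 4L)))
}

fx_rand_rgba <- function(n = 32L, seed = 1L) {
  set.seed(seed)
  rgba_image(array(stats::runif(n * n * 4), c(n, n, 4L)))
}

# strip class/metadata from an LBP map, keeping only the code matrix
fx_codes <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# central-difference gradient of a scalar function of a numeric array
fx_numgrad <- function(f, x, eps = 1e-4) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-pixel LBP oracle (independent double loop; bilinear
# neighbour sampling written out longhand)
fx_lbp_oracle <- function(img, P, radius, soft = FALSE, tau = 0.1) {
  H <- nrow(img); W <- ncol(img)
  look <- function(y, x) img[min(max(y, 1), H), min(max(x, 1), W)]
  out <- matrix(0, H, W)
  th <- 2 * pi * (seq_len(P) - 1) / P
  for (i in seq_len(H)) for (j in seq_len(W)) {
    code <- 0
    for (p in seq_len(P)) {
      yy <- i - radius * sin(th[p]); xx <- j + radius * cos(th[p])
      y0 <- floor(yy); x0 <- floor(xx); fy <- yy - y0; fx <- xx - x0
      v <- 0
      w4 <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
      o4 <- list(c(y0, x0), c(y0, x0 + 1), c(y0 + 1, x0), c(y0 + 1, x0 + 1))
      for (k in which(w4 > 1e-12)) v <- v + w4[k] * look(o4[[k]][1], o4[[k]][2])
      d <- v - img[i, j]
      s <- if (soft) 1 / (1 + exp(-d / tau)) else as.numeric(d >= -1e-12)
      code <- code + 2^(p - 1) * s
    }
    out[i, j] <- code
  }
  out
}
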