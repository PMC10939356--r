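# Entropy-weight method: quantify per-sample shape/colour/texture descriptors
# for the pooled source + target samples and derive the dynamic loss weights
# (W_s, W_c, W_t). Indicators that vary more across samples carry more
# information, get lower entropy, and receive larger weight.

#' Shape descriptor: circularity of the foreground silhouette
#'
#' `4 * pi * A / P^2` of the largest connected foreground component, clipped
#' to `[0, 1]`. The perimeter is measured as the convex-hull perimeter of the
#' component's pixel squares (pixel centres offset by half a pixel), which is
#' exact for axis-aligned rectangles and within rasterization error of
#' `2*pi*r` for discs.
#'
#' @param mask logical (or 0/1) foreground matrix with at least one
#'   foreground pixel.
#' @return scalar in `[0, 1]`; 1 for a disc, small for elongated shapes.
#' @export
shape_descriptor <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  comp <- largest_component(mask)
  A <- sum(comp)
  idx <- which(comp, arr.ind = TRUE)
  pts <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  per <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1), , drop = FALSE])^2)))
  min(1, 4 * pi * A / per^2)
}

#' Colour descriptor: circular mean hue of the foreground
#'
#' Hue is an angle; the descriptor is the circular mean of the foreground
#' pixel hues mapped to `[0, 1)` (red = 0, green = 1/3, blue = 2/3).
#'
#' @param image RGBA (or RGB) array.
#' @param mask logical foreground matrix; defaults to the alpha mask.
#' @return scalar in `[0, 1)`.
#' @export
color_descriptor <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- alpha_mask(image)
  if (!any(mask)) stop("empty mask")
  r <- image[, , 1][mask]; g <- image[, , 2][mask]; b <- image[, , 3][mask]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  h <- hsv[1, ] * 2 * pi
  ang <- atan2(mean(sin(h)), mean(cos(h)))
  (ang / (2 * pi)) %% 1
}

#' Texture descriptor: LBP histogram entropy of the foreground
#'
#' Shannon entropy of the `P = 8`, radius-1 hard-LBP code histogram over the
#' foreground pixels, normalized by `log(256)` so a constant surface scores
#' 0 and a maximally diverse one scores 1.
#'
#' @param image RGBA (or RGB / gray) image.
#' @param mask logical foreground matrix; defaults to the alpha mask.
#' @return scalar in `[0, 1]`.
#' @export
texture_descriptor <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- alpha_mask(image)
  if (sum(mask) < 64) stop("need at least 64 foreground pixels")
  codes <- lbp_map(to_gray(image), lbp_config(P = 8L, radius = 1L, mode = "hard"))
  k <- round(unclass(codes)[mask])
  p <- tabulate(k + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(256)
}

#' Descriptor table for the entropy-weight method
#'
#' Computes the shape, colour and texture descriptors for every sample, then
#' min-max normalizes each column and shifts it by `epsilon` so no entry is
#' zero (the entropy computation takes logs). A column with no variation
#' stays constant (degenerate) and will receive weight 0.
#'
#' @param samples list of RGBA arrays, or list of `list(image =, mask =)`.
#' @param epsilon zero-shift added after normalization.
#' @return an `n x 3` matrix (columns `S`, `C`, `T`) of class
#'   `"descriptor_table"`, with the raw descriptor values in attribute `raw`.
#' @export
build_descriptor_table <- function(samples, epsilon = 1e-4) {
  if (length(samples) < 2L) stop("need at least two samples")
  raw <- t(vapply(samples, function(s) {
    if (is.list(s) && !is.null(s$image)) { img <- s$image; msk <- s$mask }
    else { img <- s; msk <- alpha_mask(img) }
    c(S = shape_descriptor(msk),
      C = color_descriptor(img, msk),
      T = texture_descriptor(img, msk))
  }, numeric(3)))
  Y <- apply(raw, 2, function(col) {
    rng <- range(col)
    if (rng[2] - rng[1] < 1e-12) rep(0, length(col)) else (col - rng[1]) / (rng[2] - rng[1])
  })
  Y <- Y + epsilon
  structure(Y, class = c("descriptor_table", class(Y)), raw = raw,
            epsilon = epsilon)
}

#' Specific weights of each sample within each indicator
#'
#' `P_ij = Y_ij / sum_i Y_ij`: each indicator column is normalized over the
#' samples so it forms a probability distribution.
#'
#' @param table a [build_descriptor_table()] result (or any `n x 3` matrix
#'   of positive values).
#' @return `n x 3` matrix with columns summing to 1.
#' @export
specific_weights <- function(table) {
  Y <- unclass(table)
  sweep(Y, 2, colSums(Y), "/")
}

#' Information entropy of each indicator
#'
#' `E_j = -(1/ln n) * sum_i P_ij * ln(P_ij)` with the convention
#' `0 * ln 0 = 0`. A uniform column has entropy 1; a one-hot column 0.
#'
#' @param P an `n x 3` specific-weight matrix (columns sum to 1).
#' @return length-3 vector in `[0, 1]`.
#' @export
column_entropy <- function(P) {
  n <- nrow(P)
  if (n < 2L) stop("entropy undefined for fewer than two samples")
  apply(P, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
}

#' Loss weights from indicator entropies
#'
#' `W_j = (1 - E_j) / sum_k (1 - E_k)`: indicators with lower entropy
#' (larger cross-sample dispersion) receive larger weight. If every
#' indicator is totally degenerate (`E_j = 1` for all `j`) the weights fall
#' back to the uniform triple.
#'
#' @param E length-3 entropy vector in `[0, 1]` (order shape, colour,
#'   texture).
#' @return a `"loss_weights"` object: named numeric `(W_s, W_c, W_t)`
#'   summing to 1.
#' @export
loss_weights <- function(E) {
  d <- 1 - E
  w <- if (sum(d) <= 0) rep(1 / 3, 3) else d / sum(d)
  structure(stats::setNames(as.numeric(w), c("W_s", "W_c", "W_t")),
            class = "loss_weights")
}

#' Entropy-weight pipeline: samples to loss weights
#'
#' Convenience wrapper running [build_descriptor_table()],
#' [specific_weights()], [column_entropy()] and [loss_weights()].
#'
#' @param samples list of RGBA arrays (typically the pooled source and
#'   target domain samples).
#' @return a `"loss_weights"` object with the descriptor table attached as
#'   attribute `table`.
#' @export
entropy_loss_weights <- function(samples) {
  tab <- build_descriptor_table(samples)
  w <- loss_weights(column_entropy(specific_weights(tab)))
  attr(w, "table") <- tab
  w
}

#' Loss-weight update schedule
#'
#' `static` builds the descriptor table once from the real source and target
#' samples; `per_epoch` rebuilds it at each epoch start over the real
#' samples plus up to `n_recent` most recent generated samples per domain,
#' so the balance adapts as the generators improve.
#'
#' @param source,target lists of real RGBA samples.
#' @param generated list with elements `source` and `target`: generated
#'   RGBA samples accumulated during training (may be empty).
#' @param policy `"static"` or `"per_epoch"`.
#' @param n_recent cap on generated samples per domain entering the table.
#' @return a `"loss_weights"` object.
#' @export
update_schedule <- function(source, target, generated = list(),
                            policy = c("static", "per_epoch"), n_recent = 16L) {
  policy <- match.arg(policy)
  if (length(source) == 0L || length(target) == 0L) stop("empty dataset")
  pool <- c(source, target)
  if (policy == "per_epoch") {
    for (dom in c("source", "target")) {
      gen <- generated[[dom]]
      if (length(gen) > 0L)
        pool <- c(pool, utils::tail(gen, n_recent))
    }
  }
  entropy_loss_weights(pool)
}

#' @export
print.loss_weights <- function(x, ...) {
  cat(sprintf("loss weights: W_s = %.4f  W_c = %.4f  W_t = %.4f\n",
              x[1], x[2], x[3]))
  invisible(x)
}
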