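# Latent-space phenotype feature extraction: guided back-propagation through a
# convolutional encoder yields a single-channel shape/texture saliency map that
# is fused with the RGB image into the 4-channel generator input.

#' Seeded toy convolutional encoder
#'
#' A small serial convolutional network (three blocks by default) with the
#' same interface as a pretrained deep encoder: it exposes its final
#' convolutional layer for saliency extraction. It is deterministic in its
#' seed, so every downstream computation is reproducible without downloading
#' pretrained weights. A pretrained backbone (e.g. a VGG-style network) can be
#' supplied instead through [conv_encoder()] with the same layer format.
#'
#' @param seed integer seed controlling the weight draw.
#' @param channels integer vector, output channels per conv block.
#' @param in_channels number of input channels (3 = RGB over white).
#' @return an object of class `"encoder_spec"`.
#' @export
toy_encoder <- function(seed = 1L, channels = c(8L, 16L, 16L), in_channels = 3L) {
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  layers <- list()
  cin <- in_channels
  for (k in seq_along(channels)) {
    cout <- channels[k]
    sd <- sqrt(2 / (9 * cin))
    layers[[k]] <- list(
      w = matrix(stats::rnorm(cout * 9 * cin, sd = sd), nrow = cout),
      b = rep(0, cout), kh = 3L, kw = 3L,
      stride = if (k == 2L) 2L else 1L, pad = 1L, padmode = "replicate",
      act = "relu")
    cin <- cout
  }
  conv_encoder(layers, in_channels)
}

#' Assemble an encoder from explicit convolution layers
#'
#' @param layers list of layers; each layer is a list with elements `w`
#'   (weight matrix, `Cout x (kh*kw*Cin)`, column index running over kernel
#'   rows, kernel columns, then input channels), `b`, `kh`, `kw`, `stride`,
#'   `pad`, `padmode` (`"zero"`, `"reflect"`, `"replicate"`) and `act`
#'   (`"relu"` or `"linear"`).
#' @param in_channels channels the first layer consumes (1 or 3).
#' @return an `"encoder_spec"` object. An empty `layers` list yields the
#'   identity encoder (the input itself is the final "conv layer").
#' @export
conv_encoder <- function(layers, in_channels = 3L) {
  structure(list(layers = layers, in_channels = in_channels),
            class = "encoder_spec")
}

#' Identity encoder (testing aid)
#'
#' @param in_channels channels of the input treated as activations.
#' @return an `"encoder_spec"` with no layers.
#' @export
identity_encoder <- function(in_channels = 1L) conv_encoder(list(), in_channels)

encoder_min_size <- function(encoder) {
  s <- 1L
  for (ly in encoder$layers) s <- s * ly$stride
  max(s, 1L) * 2L
}

# Forward an image (array or tape node) through the encoder; returns the
# final-conv-layer node. Used by both encode() and the training loop.
encoder_forward <- function(tape, xnode, encoder) {
  h <- xnode
  for (ly in encoder$layers) {
    h <- ag_pad(h, ly$pad, ly$padmode)
    w <- ag_const(tape, ly$w); b <- ag_const(tape, ly$b)
    h <- ag_conv2d(h, w, b, ly$kh, ly$kw, ly$stride)
    if (identical(ly$act, "relu")) h <- ag_relu(h)
  }
  h
}

#' Encode an image and expose its final convolutional activations
#'
#' The RGBA image is composited over white (alpha never enters the encoder)
#' and forwarded through the encoder. The scalar summary `y` of the deep
#' representation is the mean of the globally average-pooled final-conv
#' activations: translation is unsupervised, so no class logit exists and a
#' class-agnostic summary replaces it.
#'
#' @param image RGBA array (or an `H x W` matrix / `H x W x C` array for
#'   encoders with matching `in_channels`).
#' @param encoder an `"encoder_spec"`.
#' @return an object of class `"activation_stack"` with elements `conv`
#'   (`w x h x C` final-layer activations), `y` (scalar), and `grad`
#'   (unset until [backprop_y()] is called).
#' @export
encode <- function(image, encoder) {
  x <- encoder_input(image, encoder)
  if (min(dim(x)[1:2]) < encoder_min_size(encoder))
    stop("image is smaller than the encoder's minimum input size")
  tape <- ag_tape()
  xn <- ag_param(tape, x, "input")
  conv <- encoder_forward(tape, xn, encoder)
  y <- ag_mean(conv)
  structure(list(conv = conv$value, y = y$value, grad = NULL,
                 tape = tape, conv_node = conv, y_node = y, input_node = xn,
                 encoder = encoder),
            class = "activation_stack")
}

encoder_input <- function(image, encoder) {
  if (length(dim(image)) == 3L && dim(image)[3] == 4L) {
    x <- composite_white(image)
    if (encoder$in_channels == 1L) x <- to_gray(x)
  } else x <- image
  as3d(x)
}

#' Back-propagate the scalar summary to the final conv layer
#'
#' Populates `grad` with the raw (unguided) gradient of `y` with respect to
#' the final convolutional activations.
#'
#' @param stack an `"activation_stack"` from [encode()].
#' @return the stack with `grad` set; `input_grad` additionally holds the
#'   gradient of `y` with respect to the encoder input.
#' @export
backprop_y <- function(stack) {
  bw <- ag_backward(stack$y_node)
  g <- ag_grad_of(bw, stack$conv_node)
  stack$grad <- array(g, dim(stack$conv))
  stack$input_grad <- bw$params$input
  stack
}

#' Guided gradient filtering
#'
#' Limits back-propagation of negative gradients: entries of the gradient
#' below zero are replaced by zero, positive entries pass unchanged.
#'
#' @param stack an `"activation_stack"` whose `grad` has been populated by
#'   [backprop_y()].
#' @return the stack with `grad` guided (elementwise non-negative).
#' @export
guided_gradients <- function(stack) {
  if (is.null(stack$grad))
    stop("gradient unset: call backprop_y() before guided_gradients()")
  stack$grad <- pmax(stack$grad, 0)
  stack$guided <- TRUE
  stack
}

#' Per-channel saliency weights
#'
#' The weight of channel `c` is the spatial mean of the guided gradient over
#' that channel: `weight_c = (1/(w*h)) * sum_ij d y / d Conv_c[i, j]`.
#'
#' @param stack an `"activation_stack"` with guided gradients.
#' @return numeric vector of length `C`.
#' @export
channel_weights <- function(stack) {
  if (is.null(stack$grad) || !isTRUE(stack$guided))
    stop("guided gradients required: call backprop_y() and guided_gradients()")
  d <- dim(stack$grad)
  if (d[1] * d[2] == 0) stop("empty feature layer")
  apply(stack$grad, 3, mean)
}

#' Raw class-activation map
#'
#' `ReLU(sum_c weight_c * Conv_c)`: the weighted channel sum of the final
#' conv activations, clamped at zero.
#'
#' @param stack an `"activation_stack"`.
#' @param weights per-channel weights, length `C`.
#' @return a `w x h` matrix, elementwise `>= 0`.
#' @export
cam_map <- function(stack, weights) {
  d <- dim(stack$conv)
  if (length(weights) != d[3])
    stop("weight count (", length(weights), ") does not match channel count (", d[3], ")")
  m <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) m <- m + weights[c] * stack$conv[, , c]
  pmax(m, 0)
}

#' Shape/texture saliency feature map of a fruit image
#'
#' Full guided back-propagation pipeline: encode, back-propagate the scalar
#' summary, guide the gradients, weight the channels, clamp, min-max
#' normalize to \eqn{[0, 1]} (an all-constant raw map normalizes to all
#' zeros, not NaN) and bilinearly upsample to the image resolution.
#'
#' @param image RGBA array.
#' @param encoder an `"encoder_spec"`; see [toy_encoder()].
#' @return an `H x W` matrix in `[0, 1]` with attribute `source_resolution`
#'   giving the conv-layer size it was upsampled from.
#' @export
feature_map <- function(image, encoder) {
  stack <- guided_gradients(backprop_y(encode(image, encoder)))
  raw <- cam_map(stack, channel_weights(stack))
  rng <- range(raw)
  norm <- if (rng[2] - rng[1] < 1e-12) raw * 0 else (raw - rng[1]) / (rng[2] - rng[1])
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- if (all(dim(norm) == c(H, W))) norm else resize_bilinear(norm, H, W)
  out <- pmin(pmax(out, 0), 1)
  attr(out, "source_resolution") <- dim(norm)
  out
}

#' Fuse a feature map with the RGB image into a multimodal input
#'
#' Concatenates the white-composited RGB channels with the saliency map as a
#' fourth channel; the alpha mask is carried as metadata, never as a network
#' input.
#'
#' @param image RGBA array.
#' @param fmap `H x W` feature map in `[0, 1]` (same size as `image`).
#' @return an `H x W x 4` array of class `"multimodal_image"` with attribute
#'   `alpha`.
#' @export
fuse <- function(image, fmap) {
  if (!all(dim(image)[1:2] == dim(fmap)[1:2]))
    stop("image and feature map dimensions differ")
  rgb <- composite_white(image)
  out <- array(c(rgb, fmap), c(dim(image)[1:2], 4L))
  attr(out, "alpha") <- image[, , 4]
  class(out) <- "multimodal_image"
  out
}

#' @rdname fuse
#' @param fused a `"multimodal_image"`.
#' @return `split_fused()` returns `list(rgb = H x W x 3, fmap = H x W)`.
#' @export
split_fused <- function(fused) {
  x <- unclass(fused)
  list(rgb = x[, , 1:3, drop = FALSE], fmap = x[, , 4])
}

# save/restore the global RNG state (local seeded streams)
rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
rng_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
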