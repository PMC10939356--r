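# Guided back-propagation feature extraction.

test_that("encode exposes final-conv activations and their scalar mean", {
  # identity encoder: constant image passes through unchanged
  g <- matrix(0.5, 16, 16)
  st <- encode(g, identity_encoder(1L))
  expect_equal(as.numeric(st$conv), rep(0.5, 256))
  expect_equal(st$y, 0.5)

  # all-zero input through a bias-free ReLU encoder gives y = 0
  enc <- toy_encoder(seed = 2)
  st0 <- encode(array(0, c(16, 16, 3)), enc)
  expect_equal(st0$y, 0)

  # seeded toy encoder matches a straightforward independent forward pass
  set.seed(9)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  st <- encode(x, enc)
  ref <- x
  for (ly in enc$layers) {
    d <- dim(ref)
    idx <- guidedgan:::pad_indices(d[1], ly$pad, "replicate")
    idy <- guidedgan:::pad_indices(d[2], ly$pad, "replicate")
    padded <- ref[idx, idy, , drop = FALSE]
    Hp <- dim(padded)[1]; Wp <- dim(padded)[2]
    Ho <- (Hp - ly$kh) %/% ly$stride + 1L; Wo <- (Wp - ly$kw) %/% ly$stride + 1L
    out <- array(0, c(Ho, Wo, nrow(ly$w)))
    for (co in seq_len(nrow(ly$w))) {
      Wk <- array(ly$w[co, ], c(ly$kh, ly$kw, dim(padded)[3]))
      for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
        patch <- padded[(i - 1) * ly$stride + seq_len(ly$kh),
                        (j - 1) * ly$stride + seq_len(ly$kw), , drop = FALSE]
        out[i, j, co] <- sum(patch * Wk) + ly$b[co]
      }
    }
    ref <- pmax(out, 0)
  }
  expect_equal(st$conv, ref, tolerance = 1e-12)
  expect_equal(st$y, mean(ref), tolerance = 1e-12)
})

test_that("guided gradient filtering clamps negatives and needs backprop first", {
  st <- encode(matrix(0.5, 8, 8), identity_encoder(1L))
  expect_error(guided_gradients(st), "backprop_y")
  st$grad <- array(c(-1, 2, 0), c(1, 3, 1))
  st2 <- guided_gradients(st)
  expect_equal(as.numeric(st2$grad), c(0, 2, 0))
  st$grad <- array(-abs(rnorm(8)), c(2, 2, 2))
  expect_true(all(guided_gradients(st)$grad == 0))
})

test_that("analytic y-gradient matches central differences on a toy encoder", {
  enc <- toy_encoder(seed = 5, channels = c(6L, 8L))
  set.seed(11)
  x <- array(runif(12 * 12 * 3, 0.1, 0.9), c(12, 12, 3))
  st <- backprop_y(encode(x, enc))
  # gradient w.r.t. the final conv activations is the constant 1/(C*w*h)
  d <- dim(st$conv)
  expect_equal(st$grad, array(1 / prod(d), d), tolerance = 1e-12)
  # gradient w.r.t. the input, through all conv/ReLU layers
  num <- fx_numgrad(function(v) encode(array(v, dim(x)), enc)$y, x)
  denom <- pmax(abs(num), 1e-4)
  expect_lt(max(abs(st$input_grad - num) / denom), 1e-3)
  # guided filtering equals the finite-difference gradient with negatives zeroed
  st_g <- guided_gradients(st)
  expect_equal(st_g$grad, pmax(array(1 / prod(d), d), 0))
})

test_that("channel weights are spatial means of the guided gradients", {
  st <- encode(matrix(0.3, 10, 10), identity_encoder(1L))
  st <- guided_gradients(backprop_y(st))
  # y = mean(conv) for a single-channel identity encoder: raw grad 1/(w*h)
  expect_equal(channel_weights(st), 1 / 100, tolerance = 1e-12)
  # constant guided gradient g per channel -> weight g; zero grad -> 0
  st$grad <- array(rep(c(0.25, 0), each = 50), c(10, 5, 2))
  expect_equal(channel_weights(st), c(0.25, 0))
})

test_that("cam_map is the ReLU-clamped weighted channel sum", {
  st <- list(conv = array(c(rep(1, 12), rep(-1, 12)), c(3, 4, 2)))
  expect_equal(cam_map(st, c(0, 0)), matrix(0, 3, 4))
  expect_equal(cam_map(st, c(1, 1)), matrix(0, 3, 4)) # symmetric cancellation
  expect_error(cam_map(st, c(1, 1, 1)), "channel count")
  set.seed(3)
  st <- list(conv = array(rnorm(4 * 5 * 3), c(4, 5, 3)))
  w <- rnorm(3)
  oracle <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) {
    acc <- 0
    for (c in 1:3) acc <- acc + w[c] * st$conv[i, j, c]
    oracle[i, j] <- max(acc, 0)
  }
  expect_equal(cam_map(st, w), oracle, tolerance = 1e-12)
  expect_true(all(cam_map(st, w) >= 0))
})

test_that("feature_map is bounded, degenerate-safe and scale invariant", {
  enc <- toy_encoder(seed = 4)
  img <- fx_fruit("pitaya_like", seed = 2)
  fm <- feature_map(img, enc)
  expect_true(min(fm) >= 0 && max(fm) <= 1)
  expect_equal(dim(fm), dim(img)[1:2])

  # constant image through a bias-free encoder: degenerate all-zero map
  const <- rgba_image(array(c(rep(0.4, 24 * 24 * 3), rep(1, 24 * 24)), c(24, 24, 4)))
  expect_true(all(feature_map(const, enc) == 0))

  # multiplying final-layer activations by a positive scalar leaves the map
  # unchanged (min-max normalization removes scale)
  enc2 <- enc
  nl <- length(enc2$layers)
  enc2$layers[[nl]]$w <- enc2$layers[[nl]]$w * 3.7
  expect_equal(feature_map(img, enc), feature_map(img, enc2), tolerance = 1e-9)

  # discriminative signal: striped vs smooth fruit differ in mean foreground saliency
  smooth <- fx_fruit("pear_like", seed = 3)
  striped <- fx_fruit("cucumber_like", seed = 3)
  m1 <- mean(feature_map(smooth, enc)[alpha_mask(smooth)])
  m2 <- mean(feature_map(striped, enc)[alpha_mask(striped)])
  expect_gt(abs(m1 - m2), 0)
})

test_that("fuse concatenates and splits losslessly", {
  img <- fx_fruit("pear_like", seed = 6)
  fm <- feature_map(img, toy_encoder(1))
  mm <- fuse(img, fm)
  sp <- split_fused(mm)
  expect_identical(sp$rgb, composite_white(img))
  expect_identical(sp$fmap, matrix(as.numeric(fm), nrow(fm)))
  expect_equal(mean(unclass(mm)[, , 4]), mean(fm))
  expect_identical(attr(mm, "alpha"), img[, , 4])
  zf <- fuse(img, fm * 0)
  expect_true(all(unclass(zf)[, , 4] == 0))
  expect_error(fuse(img, matrix(0, 2, 2)), "dimension")
})
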