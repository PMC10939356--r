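# Phenotype descriptors and the entropy-weight method.

test_that("shape descriptor: circularity of disc and rectangle", {
  n <- 128
  xy <- expand.grid(seq_len(n), seq_len(n))
  disc <- matrix((xy[[1]] - 64.5)^2 + (xy[[2]] - 64.5)^2 <= 50^2, n, n)
  cs <- shape_descriptor(disc)
  expect_gte(cs, 0.95); expect_lte(cs, 1.0)
  rect <- matrix(FALSE, 128, 128)
  rect[10:19, 15:114] <- TRUE # 10 x 100 filled rectangle
  expect_equal(shape_descriptor(rect), 4 * pi * 1000 / 220^2, tolerance = 0.01)
  expect_error(shape_descriptor(matrix(FALSE, 8, 8)), "empty")
})

test_that("colour descriptor is the circular mean hue", {
  mk <- function(rgb) {
    arr <- array(0, c(10, 10, 4)); arr[, , 4] <- 1
    for (c in 1:3) arr[, , c] <- rgb[c]
    rgba_image(arr)
  }
  expect_equal(color_descriptor(mk(c(1, 0, 0))), 0)
  expect_equal(color_descriptor(mk(c(0, 1, 0))), 1 / 3, tolerance = 1e-9)
  # mixed foreground matches a direct circular-mean oracle
  set.seed(14)
  arr <- array(runif(12 * 12 * 4, 0.1, 0.9), c(12, 12, 4)); arr[, , 4] <- 1
  img <- rgba_image(arr)
  h <- apply(matrix(arr[, , 1:3], ncol = 3), 1, function(p)
    grDevices::rgb2hsv(p[1], p[2], p[3], maxColorValue = 1)[1])
  oracle <- (atan2(mean(sin(2 * pi * h)), mean(cos(2 * pi * h))) / (2 * pi)) %% 1
  expect_equal(color_descriptor(img), oracle, tolerance = 1e-9)
})

test_that("texture descriptor is normalized LBP histogram entropy", {
  flat <- fx_gray_rgba(matrix(0.5, 32, 32))
  expect_equal(texture_descriptor(flat), 0)
  striped <- fx_gray_rgba(fx_stripes(32, freq = 6))
  expect_gt(texture_descriptor(striped), texture_descriptor(flat))
  expect_error(texture_descriptor(fx_gray_rgba(matrix(0.5, 4, 4))), "64")
  # bounded by construction
  expect_lte(texture_descriptor(striped), 1)
})

test_that("descriptor table normalizes per column with the epsilon shift", {
  s1 <- fx_fruit("pear_like", seed = 1); s2 <- fx_fruit("cucumber_like", seed = 2)
  tab <- build_descriptor_table(list(s1, s2))
  eps <- 1e-4
  for (j in 1:3) expect_equal(sort(unclass(tab)[, j]), c(eps, 1 + eps), tolerance = 1e-12)
  # identical samples: all columns degenerate constants
  tab2 <- build_descriptor_table(list(s1, s1, s1))
  expect_true(all(unclass(tab2) == eps))
  expect_error(build_descriptor_table(list(s1)), "two samples")
  # seeded fixtures equal a column-wise normalization oracle
  s3 <- fx_fruit("pitaya_like", seed = 3)
  tab3 <- build_descriptor_table(list(s1, s2, s3))
  raw <- attr(tab3, "raw")
  for (j in 1:3) {
    cl <- raw[, j]
    expect_equal(unclass(tab3)[, j], (cl - min(cl)) / (max(cl) - min(cl)) + eps,
                 tolerance = 1e-12)
  }
})

test_that("specific weights, entropy, and loss weights follow the formulas", {
  Y <- cbind(c(2, 2, 2), c(1, 3, 2), c(1, 1, 4))
  P <- specific_weights(Y)
  expect_equal(colSums(P), rep(1, 3), tolerance = 1e-12)
  expect_equal(P[, 1], rep(1 / 3, 3))
  expect_equal(specific_weights(cbind(c(1, 3)))[, 1], c(0.25, 0.75))
  # hand-evaluated entropy for the (0.25, 0.75) column
  E <- column_entropy(cbind(c(0.25, 0.75), c(0.5, 0.5), c(1, 0)))
  expect_equal(E[1], -(1 / log(2)) * (0.25 * log(0.25) + 0.75 * log(0.75)),
               tolerance = 1e-12)
  expect_equal(E[1], 0.8112781, tolerance = 1e-6)
  expect_equal(E[2], 1)  # uniform column
  expect_equal(E[3], 0)  # one-hot column (0 * ln 0 = 0)
  expect_equal(as.numeric(loss_weights(c(0, 0, 0))), rep(1 / 3, 3))
  expect_equal(as.numeric(loss_weights(c(1, 1, 1))), rep(1 / 3, 3))
  expect_equal(as.numeric(loss_weights(c(0.5, 0.75, 1.0))), c(2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
})

test_that("end-to-end pipeline equals a loop-based recomputation", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(3:20, 1)
    Y <- matrix(runif(n * 3, 1e-4, 1), n, 3)
    W <- loss_weights(column_entropy(specific_weights(Y)))
    # brute force: explicit loops, no vectorization
    Pb <- matrix(0, n, 3); Eb <- numeric(3)
    for (j in 1:3) {
      cs <- 0
      for (i in 1:n) cs <- cs + Y[i, j]
      for (i in 1:n) Pb[i, j] <- Y[i, j] / cs
      acc <- 0
      for (i in 1:n) if (Pb[i, j] > 0) acc <- acc + Pb[i, j] * log(Pb[i, j])
      Eb[j] <- -acc / log(n)
    }
    dsum <- 0
    for (j in 1:3) dsum <- dsum + (1 - Eb[j])
    Wb <- (1 - Eb) / dsum
    expect_equal(as.numeric(W), Wb, tolerance = 1e-12)
    expect_equal(sum(W), 1, tolerance = 1e-12)
  }
})

test_that("dispersion drives the weights: constant columns get zero", {
  # column 3 one-hot (max dispersion), column 1 constant, column 2 mild
  Y <- cbind(rep(0.5, 8) + 1e-4,
             c(0.4, 0.6, 0.5, 0.45, 0.55, 0.5, 0.48, 0.52) + 1e-4,
             c(1, rep(0.001, 7)) + 1e-4)
  W <- loss_weights(column_entropy(specific_weights(Y)))
  expect_equal(W[[1]], 0, tolerance = 1e-12)
  expect_equal(which.max(as.numeric(W)), 3L)
  expect_equal(sum(W), 1, tolerance = 1e-9)
  expect_true(all(as.numeric(W) >= 0 & as.numeric(W) <= 1))
})

test_that("update schedule is static or adaptive as configured", {
  src <- make_domain(fx_domains()$pear_like, 3, seed = 5)
  tgt <- make_domain(fx_domains()$cucumber_like, 3, seed = 6)
  w1 <- update_schedule(src, tgt, policy = "static")
  w2 <- update_schedule(src, tgt, policy = "static")
  expect_identical(as.numeric(w1), as.numeric(w2))
  w3 <- update_schedule(src, tgt, list(), policy = "per_epoch")
  expect_identical(as.numeric(w1), as.numeric(w3)) # empty cache: same pool
  gen <- list(source = make_domain(fx_domains()$pitaya_like, 2, seed = 7),
              target = make_domain(fx_domains()$eggplant_like, 2, seed = 8))
  w4 <- update_schedule(src, tgt, gen, policy = "per_epoch")
  expect_false(identical(as.numeric(w1), as.numeric(w4)))
  expect_equal(sum(w4), 1, tolerance = 1e-9)
  expect_error(update_schedule(list(), tgt), "empty")
})
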