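# Local binary pattern descriptor: codes, maps, correlation, texture loss.

test_that("single-pixel LBP codes follow the sign convention", {
  cfg8 <- lbp_config(P = 8, radius = 1)
  # all neighbours equal the centre: s(0) = 1 for every bit
  expect_equal(lbp_code(0.5, rep(0.5, 8), cfg8), 2^8 - 1)
  expect_equal(lbp_code(0.2, rep(0.2, 16), lbp_config()), 2^16 - 1)
  # hand evaluation: neighbours (1..4, 6..9)/9 around centre 5/9 set the top 4 bits
  expect_equal(lbp_code(5 / 9, c(1:4, 6:9) / 9, cfg8), 240)
  expect_error(lbp_code(0.5, rep(0.5, 7), cfg8), "8 neighbours")
  # soft codes approach hard codes as temperature -> 0
  soft <- lbp_config(P = 8, radius = 1, mode = "soft", temperature = 1e-4)
  set.seed(42)
  for (rep in 1:20) {
    ctr <- runif(1, 0.2, 0.8)
    nb <- ctr + sample(c(-1, 1), 8, replace = TRUE) * runif(8, 0.05, 0.2)
    expect_lt(abs(lbp_code(ctr, nb, soft) - lbp_code(ctr, nb, cfg8)), 0.5)
  }
})

test_that("lbp_map equals the per-pixel brute-force oracle exactly", {
  cfg <- lbp_config(P = 8, radius = 1)
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(8:32, 1)
    img <- matrix(runif(n * n), n, n)
    expect_identical(fx_codes(lbp_map(img, cfg)), fx_lbp_oracle(img, 8, 1))
  }
  # P = 16, radius 2 (the working configuration) on a couple of instances
  cfg16 <- lbp_config()
  for (rep in 1:2) {
    img <- matrix(runif(16 * 16), 16)
    expect_identical(fx_codes(lbp_map(img, cfg16)), fx_lbp_oracle(img, 16, 2))
  }
})

test_that("lbp_map degenerate and invariance properties hold", {
  cfg <- lbp_config(P = 8, radius = 1)
  expect_true(all(lbp_map(matrix(0.37, 12, 12), cfg) == 255))
  expect_error(lbp_map(matrix(0.5, 2, 2), lbp_config()), "too small")
  # thresholding depends only on intensity differences
  set.seed(8)
  img <- matrix(runif(20 * 20, 0.1, 0.6), 20)
  expect_identical(fx_codes(lbp_map(img, cfg)), fx_codes(lbp_map(img + 0.2, cfg)))
  # soft converges to hard pointwise as temperature -> 0 (P = 4 keeps the
  # neighbours on the integer grid, and distinct values avoid ties)
  set.seed(9)
  img2 <- matrix(sample(seq_len(144)) / 160, 12)
  softmap <- lbp_map(img2, lbp_config(P = 4, radius = 1, mode = "soft",
                                      temperature = 1e-4))
  hardmap <- lbp_map(img2, lbp_config(P = 4, radius = 1))
  # interior only: border replication makes a pixel its own neighbour there
  # (difference exactly 0, where soft saturates to 1/2 by construction)
  expect_lt(max(abs(softmap[2:11, 2:11] - hardmap[2:11, 2:11])), 0.5)
})

test_that("pearson matches the textbook formula and flags degeneracy", {
  x <- c(1, 2, 4, 7)
  expect_equal(as.numeric(pearson(x, x)), 1)
  expect_equal(as.numeric(pearson(c(1, 2, 3), c(3, 2, 1))), -1)
  set.seed(12)
  a <- rnorm(50); b <- rnorm(50)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(as.numeric(pearson(a, b)), oracle, tolerance = 1e-12)
  d <- pearson(rep(1, 5), rnorm(5))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
  expect_error(pearson(1:3, 1:4), "length")
})

test_that("texture loss is zero at identity, two at degeneracy, ordered by similarity", {
  cfg <- lbp_config(P = 8, radius = 1)
  A <- fx_gray_rgba(fx_stripes(32))
  B <- fx_gray_rgba(fx_dots(32))
  expect_equal(texture_loss(A, A, B, B, cfg), 0)
  # degenerate constant maps contribute 1 - 0 each
  C <- fx_gray_rgba(matrix(0.5, 32, 32))
  expect_equal(texture_loss(C, C, C, C, cfg), 2)
  # striped vs dotted beats striped vs shifted-same-frequency stripes
  A2 <- fx_gray_rgba(fx_stripes(32, phase = 0.3))
  worse <- texture_loss(B, A, B, A, cfg)
  better <- texture_loss(A2, A, A2, A, cfg)
  expect_gt(worse, better)
  expect_true(worse >= 0 && worse <= 4)
})

test_that("soft-LBP map gradients agree with central differences", {
  cfg <- lbp_config(P = 8, radius = 1, mode = "soft", temperature = 0.1)
  set.seed(21)
  img <- matrix(runif(8 * 8, 0.2, 0.8), 8)
  tgt <- matrix(runif(8 * 8), 8)
  f <- function(v) {
    m <- guidedgan:::lbp_map(matrix(v, 8), cfg)
    mean((unclass(m) / 255 - tgt)^2)
  }
  tape <- guidedgan:::ag_tape()
  xn <- guidedgan:::ag_param(tape, img, "x")
  mn <- guidedgan:::ag_lbp_map(xn, cfg)
  diffn <- guidedgan:::ag_sub(guidedgan:::ag_muls(mn, 1 / 255),
                              guidedgan:::ag_const(tape, tgt))
  loss <- guidedgan:::ag_mean(guidedgan:::ag_mul(diffn, diffn))
  expect_equal(loss$value, f(img), tolerance = 1e-12)
  an <- guidedgan:::ag_backward(loss)$params$x
  num <- fx_numgrad(f, img)
  denom <- pmax(abs(num), 1e-6)
  expect_lt(max(abs(an - num) / denom), 1e-3)
})
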