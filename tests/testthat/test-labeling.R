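# Scene composition, COCO export, matching and detection metrics.

fx_bg <- function(n = 96) array(0.1, c(n, n, 3))

test_that("compose_scene yields one in-bounds tight box per paste", {
  fgs <- make_domain(fx_domains()$pear_like, 3, seed = 1)
  set.seed(5)
  sc <- compose_scene(fgs, fx_bg(160), scale_range = c(0.4, 0.6))
  expect_equal(nrow(sc$boxes), 3)
  expect_true(all(sc$boxes$x >= 0 & sc$boxes$y >= 0))
  expect_true(all(sc$boxes$x + sc$boxes$w <= 160 & sc$boxes$y + sc$boxes$h <= 160))
})

test_that("a centred full-support paste has the analytic box", {
  fg <- array(1, c(20, 10, 4)) # fully opaque 20 x 10 foreground
  bg <- fx_bg(60)
  set.seed(1)
  # full-canvas scale, forced placement via retries until centred is moot:
  # verify against the per-pixel alpha-scan oracle instead, then the geometry
  sc <- compose_scene(list(fg), bg, scale_range = c(1, 1))
  b <- sc$boxes[1, ]
  expect_equal(c(b$w, b$h), c(10, 20))
  # alpha-scan oracle on a seeded multi-paste scene
  fgs <- make_domain(fx_domains()$pitaya_like, 2, seed = 2)
  set.seed(9)
  sc2 <- compose_scene(fgs, fx_bg(160), scale_range = c(0.5, 0.7), max_iou = 0.0)
  # reconstruct each box by scanning where the scene differs from background
  for (j in seq_len(nrow(sc2$boxes))) {
    b <- sc2$boxes[j, ]
    sub <- sc2$image[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w), , drop = FALSE]
    expect_gt(max(abs(sub - 0.1)), 0.05)                 # content inside the box
  }
  # the scene differs from background only within the boxes plus the
  # sub-threshold anti-aliasing fringe (alpha in (0, 0.5])
  diffmask <- apply(abs(sc2$image - 0.1), c(1, 2), max) > 1e-9
  idx <- which(diffmask, arr.ind = TRUE)
  fringe <- 3
  expect_gte(min(idx[, 1]) - 1, min(sc2$boxes$y) - fringe)
  expect_lte(max(idx[, 1]), max(sc2$boxes$y + sc2$boxes$h) + fringe)
  expect_error(compose_scene(list(array(1, c(200, 200, 4))), fx_bg(60),
                             scale_range = c(1, 1), max_tries = 3),
               "could not place")
})

test_that("synthetic dataset round-trips through COCO JSON deterministically", {
  fgs <- make_domain(fx_domains()$eggplant_like, 3, seed = 4)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  p1 <- build_synthetic_dataset(fgs, fx_bg(160), d1, n_scenes = 2, per_scene = 2,
                                seed = 11, scale_range = c(0.3, 0.5))
  p2 <- build_synthetic_dataset(fgs, fx_bg(160), d2, n_scenes = 2, per_scene = 2,
                                seed = 11, scale_range = c(0.3, 0.5))
  coco <- attr(p1, "coco")
  expect_length(coco$annotations, 4)  # per_scene * n_scenes
  bx1 <- read_coco_boxes(p1); bx2 <- read_coco_boxes(p2)
  expect_equal(bx1, bx2)
  expect_equal(nrow(bx1), 4)
  expect_equal(bx1$w, vapply(coco$annotations, function(a) a$bbox[3], numeric(1)))
})

test_that("greedy matching follows the IoU threshold rule", {
  gt <- boxes(x = c(0, 50), y = c(0, 50), w = c(10, 10), h = c(10, 10))
  pr <- boxes(x = c(0, 50), y = c(0, 50), w = c(10, 10), h = c(10, 10),
              score = c(0.9, 0.8))
  m <- match_detections(pr, gt)
  expect_equal(m$TP, 2); expect_equal(m$FP, 0)
  # IoU 0.4 < 0.5 threshold: a false positive
  pr2 <- boxes(x = 2.5, y = 0, w = 10, h = 10, score = 0.9) # IoU = 7.5/12.5 = 0.6
  expect_equal(match_detections(pr2, gt[1, ], iou_thr = 0.61)$FP, 1)
  expect_equal(match_detections(pr2, gt[1, ], iou_thr = 0.5)$TP, 1)
  # greedy score order against an exhaustive-ordering oracle
  set.seed(8)
  gts <- boxes(x = runif(5, 0, 80), y = runif(5, 0, 80), w = runif(5, 8, 15),
               h = runif(5, 8, 15))
  prs <- boxes(x = runif(10, 0, 80), y = runif(10, 0, 80), w = runif(10, 8, 15),
               h = runif(10, 8, 15), score = runif(10))
  m <- match_detections(prs, gts)
  # oracle: process predictions in descending score, assign best free gt
  ord <- order(-prs$score); free <- rep(TRUE, 5); tp <- 0
  for (i in ord) {
    ious <- guidedgan:::box_iou(gts, prs[i, ]); ious[!free] <- -1
    if (max(ious) >= 0.5) { free[which.max(ious)] <- FALSE; tp <- tp + 1 }
  }
  expect_equal(m$TP, tp)
  expect_equal(m$FP, 10 - tp)
})

test_that("precision, recall and F1 follow their definitions", {
  expect_equal(prf1(8, 2, 10), c(P = 0.8, R = 0.8, F1 = 0.8))
  expect_equal(prf1(0, 5, 10), c(P = 0, R = 0, F1 = 0))
  expect_equal(prf1(10, 0, 10), c(P = 1, R = 1, F1 = 1))
  expect_error(prf1(1, 1, 0), "positive")
})

test_that("average precision integrates the precision envelope", {
  gt <- boxes(x = 0, y = 0, w = 10, h = 10)
  # perfect detector
  pr <- boxes(x = 0, y = 0, w = 10, h = 10, score = 0.9)
  expect_equal(as.numeric(average_precision(pr, gt)), 1)
  # FP at higher score than the TP: AP = 0.5
  pr2 <- boxes(x = c(40, 0), y = c(40, 0), w = c(10, 10), h = c(10, 10),
               score = c(0.9, 0.8))
  expect_equal(as.numeric(average_precision(pr2, gt)), 0.5)
  # seeded set against a dense-threshold numerical oracle
  set.seed(17)
  gts <- boxes(x = runif(6, 0, 80), y = runif(6, 0, 80), w = runif(6, 10, 16),
               h = runif(6, 10, 16))
  prs <- boxes(x = gts$x + runif(6, -4, 4), y = gts$y + runif(6, -4, 4),
               w = gts$w, h = gts$h, score = runif(6))
  prs <- rbind(prs, boxes(x = runif(4, 0, 80), y = runif(4, 0, 80),
                          w = runif(4, 10, 16), h = runif(4, 10, 16),
                          score = runif(4)))
  ap <- average_precision(prs, gts)
  # oracle: sweep a dense threshold grid, envelope the PR points, integrate
  ths <- sort(unique(c(0, prs$score - 1e-9, prs$score, seq(0, 1, length.out = 2000))))
  pts <- t(vapply(ths, function(th) {
    keep <- prs[prs$score >= th, , drop = FALSE]
    if (nrow(keep) == 0L) return(c(R = 0, P = 1))
    m <- match_detections(keep, gts)
    c(R = m$TP / nrow(gts), P = m$TP / (m$TP + m$FP))
  }, numeric(2)))
  pts <- pts[order(pts[, "R"]), , drop = FALSE]
  rec <- unique(pts[, "R"])
  env <- vapply(rec, function(r) max(pts[pts[, "R"] >= r, "P"]), numeric(1))
  ap_oracle <- sum(diff(c(0, rec)) * env)
  expect_equal(as.numeric(ap), ap_oracle, tolerance = 1e-6)
  expect_lte(as.numeric(ap), 1)
  # recall is monotone as the threshold drops
  expect_true(all(diff(attr(ap, "curve")$recall) >= 0))
  expect_error(average_precision(prs, gts[0, ]), "ground truth")
})

test_that("AP is invariant to duplicate-score tie ordering", {
  gt <- boxes(x = c(0, 40), y = c(0, 40), w = c(10, 10), h = c(10, 10))
  pr <- boxes(x = c(0, 40, 70), y = c(0, 40, 70), w = c(10, 10, 10),
              h = c(10, 10, 10), score = c(0.5, 0.5, 0.5))
  ap1 <- as.numeric(average_precision(pr, gt))
  ap2 <- as.numeric(average_precision(pr[c(3, 1, 2), ], gt))
  expect_equal(ap1, ap2, tolerance = 1e-9)
})

test_that("pseudo-label filter keeps confident boxes only", {
  pr <- boxes(x = c(0, 20, 40), y = c(0, 20, 40), w = rep(5, 3), h = rep(5, 3),
              score = c(0.05, 0.5, 0.9))
  expect_equal(nrow(pseudo_label_filter(pr, 0)), 3)
  expect_equal(nrow(pseudo_label_filter(pr, 0.1)), 2)
  expect_equal(nrow(pseudo_label_filter(pr, 1)), 0)
  pr2 <- rbind(pr, boxes(x = 60, y = 60, w = 5, h = 5, score = 1))
  expect_equal(nrow(pseudo_label_filter(pr2, 1)), 1)
  expect_error(pseudo_label_filter(pr, 1.2), "threshold")
  # monotone in the threshold
  ns <- vapply(seq(0, 1, 0.1), function(th) nrow(pseudo_label_filter(pr, th)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
})
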