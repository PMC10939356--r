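# Scene composition with bounding-box bookkeeping, COCO-style annotation
# export, a confidence-threshold pseudo-label hook, and detection metrics
# (precision, recall, F1, average precision).

#' Bounding boxes
#'
#' Boxes are rows of a data frame with 0-based, half-open pixel coordinates
#' `[x, x + w) x [y, y + h)` (`x` = column, `y` = row), an optional
#' confidence `score` in `[0, 1]` (`NA` for ground truth) and a `label`
#' category id.
#'
#' @param x,y,w,h numeric vectors of equal length.
#' @param score confidence, or `NA` for ground truth.
#' @param label category id.
#' @return a data frame of class `"gg_boxes"`.
#' @export
boxes <- function(x, y, w, h, score = NA_real_, label = 1L) {
  if (any(w <= 0) || any(h <= 0)) stop("box width and height must be positive")
  structure(data.frame(x = x, y = y, w = w, h = h, score = score, label = label),
            class = c("gg_boxes", "data.frame"))
}

box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

tight_box <- function(alpha, threshold = 0.5) {
  idx <- which(alpha > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  # rows are y (0-based), cols are x; half-open extents
  list(x = min(idx[, 2]) - 1, y = min(idx[, 1]) - 1,
       w = max(idx[, 2]) - min(idx[, 2]) + 1, h = max(idx[, 1]) - min(idx[, 1]) + 1)
}

#' Compose translated foregrounds into a labeled scene
#'
#' Pastes RGBA foregrounds onto an RGB background at rejection-sampled
#' positions (respecting a pairwise box-overlap cap), alpha-compositing each
#' paste and recording the tight bounding box of its alpha support. `k`
#' foregrounds yield exactly `k` boxes.
#'
#' @param foregrounds list of RGBA arrays.
#' @param background `H x W x 3` RGB array in `[0, 1]`.
#' @param scale_range per-paste uniform rescale factor range.
#' @param max_iou maximum pairwise IoU between pasted boxes.
#' @param max_tries rejection-sampling budget per foreground.
#' @return a list of class `"labeled_scene"`: `image` (RGB array), `boxes`
#'   (a [boxes()] frame), `provenance` (foreground indices).
#' @export
compose_scene <- function(foregrounds, background, scale_range = c(0.5, 1),
                          max_iou = 0.2, max_tries = 50L) {
  H <- dim(background)[1]; W <- dim(background)[2]
  scene <- background
  placed <- NULL
  pastes <- list()
  for (k in seq_along(foregrounds)) {
    fg <- foregrounds[[k]]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      sc <- stats::runif(1, scale_range[1], scale_range[2])
      fh <- max(2L, round(dim(fg)[1] * sc)); fw <- max(2L, round(dim(fg)[2] * sc))
      if (fh > H || fw > W) next
      fgs <- if (fh == dim(fg)[1] && fw == dim(fg)[2]) fg else {
        out <- array(0, c(fh, fw, 4L))
        for (c in 1:4) out[, , c] <- resize_bilinear(fg[, , c], fh, fw)
        out
      }
      bb <- tight_box(fgs[, , 4])
      if (is.null(bb)) next
      oy <- sample.int(H - fh + 1L, 1L) - 1L  # 0-based paste offset
      ox <- sample.int(W - fw + 1L, 1L) - 1L
      cand <- data.frame(x = bb$x + ox, y = bb$y + oy, w = bb$w, h = bb$h)
      if (!is.null(placed) && nrow(placed) > 0 &&
          any(box_iou(placed, cand) > max_iou)) next
      rows <- oy + seq_len(fh); cols <- ox + seq_len(fw)
      a <- fgs[, , 4]
      for (c in 1:3)
        scene[rows, cols, c] <- fgs[, , c] * a + scene[rows, cols, c] * (1 - a)
      # box from the pasted alpha support in scene coordinates
      sb <- tight_box(fgs[, , 4])
      cand <- data.frame(x = sb$x + ox, y = sb$y + oy, w = sb$w, h = sb$h)
      placed <- rbind(placed, cand)
      pastes[[length(pastes) + 1L]] <- list(alpha = a, ox = ox, oy = oy)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place foreground ", k, " within ", max_tries, " tries")
  }
  structure(list(image = scene,
                 boxes = boxes(placed$x, placed$y, placed$w, placed$h),
                 provenance = seq_along(foregrounds), pastes = pastes),
            class = "labeled_scene")
}

#' Build a synthetic detection dataset with COCO annotations
#'
#' Composes `n_scenes` scenes from translated foreground images and
#' backgrounds, writes them as PNGs and emits one COCO-format annotation
#' file (bbox `[x, y, w, h]`, category `"fruit"`). Fully reproducible under
#' the seed.
#'
#' @param foregrounds list of RGBA arrays (or a directory of RGBA PNGs).
#' @param backgrounds list of RGB arrays (or a directory); recycled.
#' @param out_dir output directory.
#' @param n_scenes number of scenes.
#' @param per_scene foregrounds pasted per scene (sampled with replacement).
#' @param seed integer seed.
#' @param ... passed to [compose_scene()].
#' @return path of the written annotation JSON, invisibly; the annotation
#'   list as attribute `coco`.
#' @export
build_synthetic_dataset <- function(foregrounds, backgrounds, out_dir,
                                    n_scenes = 10L, per_scene = 3L, seed = 1L, ...) {
  foregrounds <- as_image_list(foregrounds)
  if (is.character(backgrounds)) backgrounds <- as_image_list(backgrounds)
  if (is.array(backgrounds)) backgrounds <- list(backgrounds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(seed)
  images <- list(); annotations <- list(); ann_id <- 0L
  for (i in seq_len(n_scenes)) {
    bg <- backgrounds[[(i - 1L) %% length(backgrounds) + 1L]]
    if (length(dim(bg)) == 3L && dim(bg)[3] == 4L) bg <- composite_white(bg)
    fgs <- foregrounds[sample.int(length(foregrounds), per_scene, replace = TRUE)]
    scene <- compose_scene(fgs, bg, ...)
    fname <- sprintf("scene_%04d.png", i)
    png::writePNG(scene$image, file.path(out_dir, fname))
    images[[i]] <- list(id = i, file_name = fname,
                        height = dim(bg)[1], width = dim(bg)[2])
    for (j in seq_len(nrow(scene$boxes))) {
      ann_id <- ann_id + 1L
      b <- scene$boxes[j, ]
      annotations[[ann_id]] <- list(id = ann_id, image_id = i, category_id = 1L,
                                    bbox = c(b$x, b$y, b$w, b$h),
                                    area = b$w * b$h, iscrowd = 0L)
    }
  }
  coco <- list(images = images, annotations = annotations,
               categories = list(list(id = 1L, name = "fruit")))
  path <- file.path(out_dir, "annotations.json")
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  out <- invisible(path)
  attr(out, "coco") <- coco
  out
}

#' Read boxes from a COCO-format annotation or detection file
#'
#' @param path JSON file: either a COCO dataset (with `annotations`) or a
#'   COCO detection result array.
#' @return a [boxes()] frame with an `image_id` column.
#' @export
read_coco_boxes <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann <- if (is.list(j) && !is.null(j$annotations)) j$annotations else j
  bb <- do.call(rbind, lapply(ann$bbox, as.numeric))
  if (is.null(bb)) bb <- matrix(unlist(ann$bbox), ncol = 4, byrow = TRUE)
  out <- boxes(bb[, 1], bb[, 2], bb[, 3], bb[, 4],
               score = if (!is.null(ann$score)) ann$score else NA_real_,
               label = if (!is.null(ann$category_id)) ann$category_id else 1L)
  out$image_id <- ann$image_id
  out
}

#' Match detections to ground truth
#'
#' Predictions are sorted by descending score and greedily matched
#' one-to-one to the unmatched ground-truth box of highest IoU, provided
#' IoU >= `iou_thr`. Unmatched predictions count as false positives.
#'
#' @param preds,gts [boxes()] frames (predictions carry scores).
#' @param iou_thr IoU threshold in `(0, 1)`.
#' @return list with `TP`, `FP`, and `matches` (data frame of pred/gt row
#'   indices and IoU).
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  if (iou_thr <= 0 || iou_thr >= 1) stop("iou_thr must lie in (0, 1)")
  if (nrow(preds) == 0L)
    return(list(TP = 0L, FP = 0L, matches = data.frame(), tp_flags = logical(0)))
  ord <- order(-preds$score)
  used <- rep(FALSE, nrow(gts))
  tp_flags <- rep(FALSE, nrow(preds))
  matches <- list()
  for (i in ord) {
    if (nrow(gts) > 0L) {
      ious <- box_iou(gts, preds[i, ])
      ious[used] <- -1
      j <- which.max(ious)
      if (length(j) == 1L && ious[j] >= iou_thr) {
        used[j] <- TRUE
        tp_flags[i] <- TRUE
        matches[[length(matches) + 1L]] <- data.frame(pred = i, gt = j, iou = ious[j])
      }
    }
  }
  list(TP = sum(tp_flags), FP = sum(!tp_flags),
       matches = if (length(matches)) do.call(rbind, matches) else data.frame(),
       tp_flags = tp_flags)
}

#' Precision, recall, F1
#'
#' `P = TP / (TP + FP)`, `R = TP / GT`, `F1 = 2PR / (P + R)` (0 when
#' `P + R = 0`).
#'
#' @param TP,FP true / false positive counts.
#' @param GT ground-truth count (> 0).
#' @return named vector `c(P, R, F1)`.
#' @export
prf1 <- function(TP, FP, GT) {
  if (GT <= 0) stop("GT must be positive")
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- TP / GT
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

#' Average precision (area under the precision-recall curve)
#'
#' Predictions are swept in descending score order; at each rank the
#' precision/recall point is recorded, the precision envelope (running
#' maximum from the right) is applied, and the area is accumulated over all
#' recall increments (all-point interpolation).
#'
#' @param preds scored [boxes()] frame over a test set; optional `image_id`
#'   column scopes the matching per image.
#' @param gts ground-truth [boxes()] frame.
#' @param iou_thr IoU threshold for a correct detection.
#' @return AP in `[0, 1]`, with attribute `curve` (recall/precision frame).
#' @export
average_precision <- function(preds, gts, iou_thr = 0.5) {
  if (nrow(gts) == 0L) stop("no ground truth")
  ids <- unique(c(if (!is.null(preds$image_id)) preds$image_id else 1L,
                  if (!is.null(gts$image_id)) gts$image_id else 1L))
  flags <- list(); scores <- list()
  for (id in ids) {
    p <- if (!is.null(preds$image_id)) preds[preds$image_id == id, , drop = FALSE] else preds
    g <- if (!is.null(gts$image_id)) gts[gts$image_id == id, , drop = FALSE] else gts
    if (nrow(p) == 0L) next
    m <- match_detections(p, g, iou_thr)
    flags[[length(flags) + 1L]] <- m$tp_flags
    scores[[length(scores) + 1L]] <- p$score
  }
  tp <- unlist(flags); sc <- unlist(scores)
  nGT <- nrow(gts)
  if (length(tp) == 0L) return(structure(0, curve = data.frame(recall = 0, precision = 0)))
  ord <- order(-sc)
  tp <- tp[ord]; sc <- sc[ord]
  cumtp <- cumsum(tp); cumfp <- cumsum(!tp)
  # evaluate the curve only where the score strictly drops, so tied
  # detections enter together (threshold semantics; tie-order invariant)
  last <- which(c(sc[-1] < sc[-length(sc)], TRUE))
  cumtp <- cumtp[last]; cumfp <- cumfp[last]
  rec <- cumtp / nGT
  prec <- cumtp / (cumtp + cumfp)
  env <- rev(cummax(rev(prec)))
  ap <- sum(diff(c(0, rec)) * env)
  structure(ap, curve = data.frame(recall = rec, precision = prec, envelope = env))
}

#' Confidence-threshold pseudo-label hook
#'
#' Simplified stand-in for an adaptive pseudo-label self-learning loop:
#' keeps predictions whose confidence reaches the threshold (default 0.1,
#' the visualization confidence used in the study). The retained count is
#' monotonically non-increasing in the threshold. A full adaptive-threshold
#' method can be plugged in by passing any function `preds -> preds` where
#' this hook is consumed.
#'
#' @param preds scored [boxes()] frame.
#' @param threshold confidence cut in `[0, 1]`.
#' @return the filtered frame.
#' @export
pseudo_label_filter <- function(preds, threshold = 0.1) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  preds[preds$score >= threshold, , drop = FALSE]
}

#' Score label quality against ground truth
#'
#' @param preds,gts [boxes()] frames.
#' @param iou_thr IoU threshold.
#' @return a list of class `"metric_report"`: TP, FP, GT, P, R, F1, AP.
#' @export
evaluate_labels <- function(preds, gts, iou_thr = 0.5) {
  ids <- unique(c(if (!is.null(preds$image_id)) preds$image_id else 1L,
                  if (!is.null(gts$image_id)) gts$image_id else 1L))
  TP <- 0L; FP <- 0L
  for (id in ids) {
    p <- if (!is.null(preds$image_id)) preds[preds$image_id == id, , drop = FALSE] else preds
    g <- if (!is.null(gts$image_id)) gts[gts$image_id == id, , drop = FALSE] else gts
    m <- match_detections(p, g, iou_thr)
    TP <- TP + m$TP; FP <- FP + m$FP
  }
  pr <- prf1(TP, FP, nrow(gts))
  ap <- average_precision(preds, gts, iou_thr)
  structure(list(TP = TP, FP = FP, GT = nrow(gts),
                 P = pr[["P"]], R = pr[["R"]], F1 = pr[["F1"]],
                 AP = as.numeric(ap), curve = attr(ap, "curve")),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("detections: TP %d, FP %d, GT %d\n", x$TP, x$FP, x$GT))
  cat(sprintf("P %.3f  R %.3f  F1 %.3f  AP %.3f\n", x$P, x$R, x$F1, x$AP))
  invisible(x)
}
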