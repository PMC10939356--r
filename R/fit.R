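# Model fitting: the user-facing entry point and S3 methods.

as_image_list <- function(x, size = NULL) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no PNG images found in ", x)
    x <- lapply(files, read_rgba)
  }
  if (is.array(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L) stop("empty dataset")
  if (!is.null(size)) {
    ok <- vapply(x, function(im) all(dim(im)[1:2] == size), logical(1))
    if (!all(ok)) stop("all images must be ", size, " x ", size)
  }
  x
}

#' Fit the guided unpaired fruit translation model
#'
#' Trains the two-cycle translation model on two unpaired sets of
#' transparent-background fruit images. Each training iteration draws one
#' unpaired sample per domain, computes the guided-back-propagation saliency
#' maps, runs both domain cycles, and optimizes the entropy-weighted
#' multi-loss objective (shape: cross-cycle MS-SSIM; colour: cycle +
#' identity L1; texture: soft-LBP Pearson; plus the least-squares
#' adversarial term). The loss weights come from the entropy-weight method
#' applied to the pooled phenotype descriptors of the two domains.
#'
#' @param source,target lists of RGBA arrays, or directories of RGBA PNGs.
#' @param config a [gg_config()].
#' @param log_csv optional path; per-iteration losses and weights are
#'   appended there as CSV.
#' @return an object of class `"guided_gan"`: the trained model, the
#'   per-iteration `history` data frame, the loss weights used per epoch,
#'   and the configuration.
#' @export
guided_gan <- function(source, target, config = gg_config(), log_csv = NULL) {
  cfg <- config
  source <- as_image_list(source, cfg$image_size)
  target <- as_image_list(target, cfg$image_size)
  model <- build_guided_gan(cfg)
  old <- rng_snapshot(); on.exit(rng_restore(old))
  set.seed(cfg$seed + 1L)
  buffers <- list(t = new_buffer(cfg$buffer_size), s = new_buffer(cfg$buffer_size))
  weights <- update_schedule(source, target, policy = "static")
  history <- list()
  weight_rows <- list()
  gen_cache <- list(source = list(), target = list())
  n_iter_epoch <- max(length(source), length(target))
  total_epochs <- cfg$epochs_const + cfg$epochs_decay
  iter <- 0L
  for (epoch in seq_len(total_epochs) - 1L) {
    lr <- lr_schedule(epoch, cfg)
    if (cfg$weight_policy == "per_epoch")
      weights <- update_schedule(source, target, gen_cache, policy = "per_epoch")
    weight_rows[[length(weight_rows) + 1L]] <-
      data.frame(epoch = epoch, W_s = weights[1], W_c = weights[2], W_t = weights[3],
                 lr = lr, row.names = NULL)
    is_ <- sample(rep_len(sample.int(length(source)), n_iter_epoch))
    it_ <- sample(rep_len(sample.int(length(target)), n_iter_epoch))
    for (i in seq_len(n_iter_epoch)) {
      iter <- iter + 1L
      rep_ <- train_step(model, source[[is_[i]]], target[[it_[i]]], weights,
                         lr = lr, buffers = buffers)
      row <- cbind(data.frame(iter = iter, epoch = epoch, lr = lr),
                   as.data.frame(rep_))
      history[[iter]] <- row
      if (!is.null(log_csv))
        utils::write.table(row, log_csv, sep = ",", append = file.exists(log_csv),
                           col.names = !file.exists(log_csv), row.names = FALSE)
      if (iter >= cfg$max_iters) break
    }
    if (cfg$weight_policy == "per_epoch") {
      # refresh the generated-sample cache from the current generators
      gen_cache$target <- c(gen_cache$target, translate(model, source[[is_[1]]], "st"))
      gen_cache$source <- c(gen_cache$source, translate(model, target[[it_[1]]], "ts"))
    }
    if (is.finite(cfg$checkpoint_every) && !is.null(cfg$checkpoint_dir) &&
        (epoch + 1L) %% cfg$checkpoint_every == 0L)
      save_guided_gan(structure(list(model = model, config = cfg), class = "guided_gan"),
                      file.path(cfg$checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
    if (iter >= cfg$max_iters) break
  }
  history <- do.call(rbind, history)
  if (!all(is.finite(history$L_total))) stop("non-finite epoch mean loss")
  structure(list(model = model, config = cfg, history = history,
                 weights = weights, weight_history = do.call(rbind, weight_rows),
                 seed = cfg$seed),
            class = "guided_gan")
}

#' Save / restore a fitted model
#'
#' Checkpoints are single-file bundles embedding the parameters, optimizer
#' state, configuration and seed.
#'
#' @param object a `"guided_gan"` fit (or `"gg_model"`).
#' @param path file path (`.rds`).
#' @return `load_guided_gan()` returns the restored object.
#' @export
save_guided_gan <- function(object, path) {
  if (inherits(object, "guided_gan")) {
    object$model <- unclass_model(object$model)
  } else if (inherits(object, "gg_model")) object <- unclass_model(object)
  saveRDS(object, path)
  invisible(path)
}

unclass_model <- function(model) {
  model$ps <- list(params = model$ps$params, m = model$ps$m, v = model$ps$v,
                   tstep = model$ps$tstep)
  model
}

reclass_model <- function(model) {
  ps <- new_pstore()
  ps$params <- model$ps$params; ps$m <- model$ps$m; ps$v <- model$ps$v
  ps$tstep <- model$ps$tstep
  model$ps <- ps
  model
}

#' @rdname save_guided_gan
#' @export
load_guided_gan <- function(path) {
  object <- readRDS(path)
  if (inherits(object, "guided_gan")) object$model <- reclass_model(object$model)
  else if (inherits(object, "gg_model")) object <- reclass_model(object)
  object
}

#' @export
print.guided_gan <- function(x, ...) {
  cfg <- x$config
  cat("Guided unpaired fruit translation model\n")
  cat(sprintf("  image size %d, ngf %d, ndf %d, %d residual blocks\n",
              cfg$image_size, cfg$ngf, cfg$ndf, cfg$n_res))
  cat(sprintf("  %d training iterations, seed %d\n", nrow(x$history), x$seed))
  cat(sprintf("  loss weights: W_s = %.3f, W_c = %.3f, W_t = %.3f\n",
              x$weights[1], x$weights[2], x$weights[3]))
  if (nrow(x$history) > 0)
    cat(sprintf("  generator total loss: first %.4f, last %.4f\n",
                x$history$L_total[1], x$history$L_total[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.guided_gan <- function(object, ...) {
  h <- object$history
  comp <- c("L_adv_G", "L_shape", "L_color", "L_texture", "L_total")
  s <- data.frame(component = comp,
                  first = vapply(comp, function(k) h[[k]][1], numeric(1)),
                  last = vapply(comp, function(k) h[[k]][nrow(h)], numeric(1)),
                  mean = vapply(comp, function(k) mean(h[[k]]), numeric(1)),
                  row.names = NULL)
  structure(list(losses = s, weights = object$weights, config = object$config,
                 iterations = nrow(h)), class = "summary.guided_gan")
}

#' @export
print.summary.guided_gan <- function(x, ...) {
  cat(sprintf("Guided-GAN fit: %d iterations\n", x$iterations))
  print(x$losses, digits = 4)
  cat(sprintf("entropy loss weights: W_s = %.3f, W_c = %.3f, W_t = %.3f\n",
              x$weights[1], x$weights[2], x$weights[3]))
  invisible(x)
}

#' Translate new images with a fitted model
#'
#' @param object a fitted `"guided_gan"`.
#' @param newdata list of RGBA arrays (or one array); source-domain images
#'   for `direction = "st"`.
#' @param direction `"st"` or `"ts"`.
#' @param ... unused.
#' @return list of translated RGBA arrays.
#' @export
predict.guided_gan <- function(object, newdata, direction = "st", ...) {
  translate(object$model, newdata, direction)
}

#' Plot training trajectories
#'
#' Loss components per iteration (log scale where positive) and the
#' entropy-weight trajectory per epoch.
#'
#' @param x a fitted `"guided_gan"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.guided_gan <- function(x, ...) {
  h <- x$history
  comp <- c("L_total", "L_adv_G", "L_shape", "L_color", "L_texture")
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::matplot(h$iter, as.matrix(h[comp]), type = "l", lty = 1,
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", comp, col = seq_along(comp), lty = 1, cex = 0.7)
  wh <- x$weight_history
  graphics::matplot(wh$epoch, as.matrix(wh[c("W_s", "W_c", "W_t")]), type = "b",
                    pch = 1, lty = 1, xlab = "epoch", ylab = "weight",
                    ylim = c(0, 1))
  graphics::legend("topright", c("W_s", "W_c", "W_t"), col = 1:3, lty = 1, cex = 0.7)
  invisible(x)
}
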