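# Training loop for the segmentation objective: estimate the binary mask
# minimising the configured loss over the annotated training set, with
# augmentation on the training stream only, per-epoch validation IoU/F1,
# best-checkpoint selection by validation IoU and early stopping.

#' Configuration of one segmentation model / training run
#'
#' The unit of the model-selection grid: an encoder x decoder pair, a
#' loss, an augmentation recipe and the scalar hyperparameters.
#'
#' @param encoder one of [encoder_names()].
#' @param decoder one of [decoder_names()].
#' @param loss one of [loss_names()].
#' @param recipe augmentation recipe string (see [parse_recipe()]),
#'   applied to the training stream; validation only resizes.
#' @param pretrained request ImageNet-pretrained encoder weights (not
#'   bundled; building such a config errors).
#' @param lr,epochs,batch_size Adam learning rate, maximum epochs, and
#'   gradient-accumulation batch size.
#' @param threshold probability binarization threshold in (0, 1).
#' @param stroke_width mask rasterization brush, px.
#' @param patience early-stopping patience (epochs without validation IoU
#'   improvement); `Inf` disables early stopping.
#' @param seed integer seed governing initialisation, shuffling and
#'   augmentation.
#' @return an object of class `model_config`.
#' @export
model_config <- function(encoder = "tiny", decoder = "unet",
                         loss = "dice", recipe = "RS256+RF",
                         pretrained = FALSE, lr = 1e-3, epochs = 15L,
                         batch_size = 2L, threshold = 0.5,
                         stroke_width = 2, patience = 5L, seed = 1L) {
  if (!encoder %in% encoder_names()) {
    stop_trichoseg("unknown encoder '", encoder,
                   "'; registered encoders: ",
                   paste(encoder_names(), collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  if (!decoder %in% decoder_names()) {
    stop_trichoseg("unknown decoder '", decoder,
                   "'; registered decoders: ",
                   paste(decoder_names(), collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  if (!loss %in% loss_names()) {
    stop_trichoseg("unknown loss '", loss, "'; registered losses: ",
                   paste(loss_names(), collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  if (threshold <= 0 || threshold >= 1) {
    stop_trichoseg("threshold must lie strictly in (0, 1)",
                   class = "trichoseg_validation_error")
  }
  parse_recipe(recipe)  # validates tokens
  structure(list(encoder = encoder, decoder = decoder, loss = loss,
                 recipe = recipe, pretrained = pretrained, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 threshold = threshold, stroke_width = stroke_width,
                 patience = patience, seed = as.integer(seed)),
            class = "model_config")
}

# Final deterministic geometry of a recipe: the size after the last
# size-bearing token, or NULL if the recipe never resizes.
recipe_final_size <- function(recipe) {
  if (is.character(recipe)) recipe <- parse_recipe(recipe)
  size <- NULL
  for (st in recipe$steps) if (!is.null(st$size)) size <- st$size
  size
}

snapshot_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}

# Resize a record to `size` and rasterize its ground truth there.
prepare_eval_pair <- function(record, size, stroke_width) {
  img <- record$pixels
  if (!isTRUE(all(dim(img)[1:2] == size))) {
    img <- resize_bilinear(img, size)
  }
  spl <- lapply(record$splines, transform_spline, target_size = size)
  list(image = img, mask = rasterize(spl, size, stroke_width))
}

#' Train a segmentation model
#'
#' Optimizes the configured loss with Adam (gradient accumulation over
#' `batch_size` images), applying the augmentation recipe to the training
#' stream only; validation images are resized (RS) to the recipe's final
#' size with masks rasterized there, never interpolated. The checkpoint
#' with the best validation IoU is kept and restored into the returned
#' model. Deterministic given `cfg$seed` up to floating-point ordering.
#'
#' @param cfg a [model_config()].
#' @param train_set,val_set lists of [annotated_image()] with pixel data.
#' @param quiet suppress per-epoch progress.
#' @return an object of class `train_report`: `epochs` (data.frame of
#'   `epoch`, `train_loss`, `val_iou`, `val_f1`), `best_epoch`,
#'   `best_val_iou`, and `model` (weights of the best epoch).
#' @export
train_segmenter <- function(cfg, train_set, val_set, quiet = TRUE) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(train_set) == 0) {
    stop_trichoseg("empty training set", class = "trichoseg_validation_error")
  }
  model <- build_model(cfg)
  size <- recipe_final_size(cfg$recipe) %||% dim(train_set[[1]]$pixels)[1:2]
  if (any(size %% model$stride != 0)) {
    stop_trichoseg("recipe size ", size[1], "x", size[2], " is not a ",
                   "multiple of the model stride ", model$stride,
                   class = "trichoseg_validation_error")
  }
  # per-dataset channel statistics (no pretrained weights, so no fixed
  # ImageNet statistics)
  sub <- train_set[seq_len(min(16, length(train_set)))]
  px <- vapply(sub, function(r) {
    c(colMeans(matrix(r$pixels, ncol = 3)),
      apply(matrix(r$pixels, ncol = 3), 2, stats::sd))
  }, numeric(6))
  model$norm <- list(mean = rowMeans(px)[1:3],
                     sd = pmax(rowMeans(px)[4:6], 0.05))
  recipe <- parse_recipe(cfg$recipe)
  val_pairs <- lapply(val_set, prepare_eval_pair, size = size,
                      stroke_width = cfg$stroke_width)
  n <- length(train_set)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_iou = numeric(), val_f1 = numeric())
  best <- list(iou = -Inf, epoch = 0L, snap = NULL)
  step_t <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "shuffle", epoch), sample.int(n))
    epoch_loss <- 0
    nn_zero_grads(model$params)
    in_batch <- 0L
    for (k in seq_along(ord)) {
      rec <- train_set[[ord[k]]]
      aug <- apply_recipe(recipe, rec, stroke_width = cfg$stroke_width,
                          seed = derive_seed(cfg$seed, "aug", epoch, ord[k]))
      target <- sparse_decode(aug$mask)
      fw <- model_forward(model, aug$image)
      epoch_loss <- epoch_loss + compute_loss(fw$prob, target, cfg$loss)
      gp <- loss_grad(fw$prob, target, cfg$loss)
      nn_backward(fw$tape, fw$node, array(gp, dim(fw$node$value)))
      in_batch <- in_batch + 1L
      if (in_batch == cfg$batch_size || k == n) {
        step_t <- step_t + 1L
        nn_adam_step(model$params, lr = cfg$lr, t = step_t,
                     scale = 1 / in_batch)
        nn_zero_grads(model$params)
        in_batch <- 0L
      }
    }
    ev <- vapply(val_pairs, function(vp) {
      pm <- predict_mask(model, vp$image, cfg$threshold)
      c(iou(pm, vp$mask), f1_score(pm, vp$mask, warn = FALSE)[["f1"]])
    }, numeric(2))
    val_iou <- if (length(val_pairs)) mean(ev[1, ]) else NA_real_
    val_f1 <- if (length(val_pairs)) mean(ev[2, ]) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / n,
                                   val_iou = val_iou, val_f1 = val_f1))
    if (!quiet) {
      message(sprintf("epoch %d: loss %.4f, val IoU %.4f, val F1 %.4f",
                      epoch, epoch_loss / n, val_iou, val_f1))
    }
    if (is.na(val_iou) || val_iou > best$iou) {
      best <- list(iou = if (is.na(val_iou)) -Inf else val_iou,
                   epoch = epoch, snap = snapshot_params(model$params))
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  if (!is.null(best$snap)) restore_params(model$params, best$snap)
  structure(list(epochs = hist, best_epoch = best$epoch,
                 best_val_iou = if (is.finite(best$iou)) best$iou else NA,
                 model = model),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report: %d epochs, best epoch %d (val IoU %.4f)>\n",
              nrow(x$epochs), x$best_epoch, x$best_val_iou))
  invisible(x)
}

#' Predict a sparse trichome mask for one image
#'
#' @param model a trained [build_model()] model.
#' @param image H x W x 3 array at a size compatible with the model
#'   stride.
#' @param threshold probability threshold; pixels with probability
#'   strictly greater are foreground.
#' @return a [sparse_mask()].
#' @export
predict_mask <- function(model, image, threshold = NULL) {
  stopifnot(inherits(model, "trichoseg_model"))
  threshold <- threshold %||% model$config$threshold
  prob <- model_forward(model, image)$prob
  sparse_encode((prob > threshold) * 1L)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full [model_config()] plus weights and input
#' statistics, so a loaded checkpoint reproduces predictions exactly.
#'
#' @param model a `trichoseg_model`.
#' @param path checkpoint file path.
#' @return `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               weights = snapshot_params(model$params),
               norm = model$norm), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop_trichoseg("checkpoint not found: ", path,
                   class = "trichoseg_io_error")
  }
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config)
  model <- build_model(cfg)
  restore_params(model$params, ck$weights)
  model$norm <- ck$norm
  model
}
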