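# Modular encoder x decoder segmentation networks. Any registered
# feature extractor composes with any registered segmentation head. The
# full-size encoder names follow the families evaluated for trichome
# segmentation (VGG19-bn, ResNet18/50, SE-ResNet50, RegNetX-064,
# EfficientNet-B5); they are implemented natively at their published
# stage depths and widths, with two documented simplifications: grouped /
# depthwise convolutions are realised as dense convolutions, and no
# ImageNet-pretrained weights are bundled (requesting them errors). The
# "tiny" encoder (3 convolution blocks) exists so that training and tests
# run in seconds on one CPU.

CH_CAP <- 64L  # decoder channel cap keeps desk-scale heads small

#' Names of the registered feature extractors / segmentation modules
#'
#' @return character vector of registry names.
#' @export
encoder_names <- function() {
  c("tiny", "vgg19bn", "resnet18", "resnet50", "se_resnet50",
    "regnetx064", "effnet_b5")
}

#' @rdname encoder_names
#' @export
decoder_names <- function() c("unet", "unetpp", "deeplabv3", "linknet",
                              "manet")

#' @rdname encoder_names
#' @export
loss_names <- function() c("bce", "dice", "jaccard", "focal")

# ---- shared layer builders -------------------------------------------------

layer_conv <- function(cin, cout, k = 3L, stride = 1L, dil = 1L,
                       bn = FALSE, act = TRUE, name = "conv") {
  force(stride); force(act)  # loop variables must not be captured lazily
  pad <- as.integer(dil * (k - 1) / 2)
  prm <- nn_conv_param(k, k, cin, cout, name)
  bnp <- if (bn) nn_bn_param(cout, paste0(name, ".bn"))
  params <- c(list(prm$w, prm$b), if (bn) list(bnp$gamma, bnp$beta))
  fwd <- function(tp, x) {
    y <- op_conv(tp, x, prm, stride = stride, pad = pad, dil = dil)
    if (bn) y <- op_bn(tp, y, bnp)
    if (act) y <- op_relu(tp, y)
    y
  }
  list(params = params, fwd = fwd, cout = cout)
}

layer_seq <- function(...) {
  layers <- list(...)
  list(params = unlist(lapply(layers, `[[`, "params")),
       fwd = function(tp, x) {
         for (l in layers) x <- l$fwd(tp, x)
         x
       })
}

layer_se <- function(c, reduction = 8L, name = "se") {
  cmid <- max(4L, c %/% reduction)
  fc1 <- nn_dense_param(c, cmid, paste0(name, ".fc1"))
  fc2 <- nn_dense_param(cmid, c, paste0(name, ".fc2"))
  list(params = list(fc1$w, fc1$b, fc2$w, fc2$b),
       fwd = function(tp, x) {
         s <- op_global_avg(tp, x)
         s <- op_relu_vec(tp, op_dense(tp, s, fc1))
         s <- op_sigmoid_vec(tp, op_dense(tp, s, fc2))
         op_scale_channels(tp, x, s)
       })
}

# residual block; kind "basic" (two 3x3) or "bottleneck" (1-3-1, mid =
# cout/4), optional squeeze-and-excitation
layer_resblock <- function(cin, cout, stride = 1L, kind = "basic",
                           se = FALSE, name = "res") {
  if (kind == "basic") {
    main <- layer_seq(
      layer_conv(cin, cout, 3L, stride, bn = TRUE, name = paste0(name, ".1")),
      layer_conv(cout, cout, 3L, bn = TRUE, act = FALSE,
                 name = paste0(name, ".2")))
  } else {
    mid <- max(4L, cout %/% 4L)
    main <- layer_seq(
      layer_conv(cin, mid, 1L, bn = TRUE, name = paste0(name, ".1")),
      layer_conv(mid, mid, 3L, stride, bn = TRUE, name = paste0(name, ".2")),
      layer_conv(mid, cout, 1L, bn = TRUE, act = FALSE,
                 name = paste0(name, ".3")))
  }
  seb <- if (se) layer_se(cout, name = paste0(name, ".se"))
  proj <- if (cin != cout || stride != 1L) {
    layer_conv(cin, cout, 1L, stride, bn = TRUE, act = FALSE,
               name = paste0(name, ".proj"))
  }
  params <- c(main$params, if (se) seb$params, if (!is.null(proj)) proj$params)
  list(params = params, cout = cout,
       fwd = function(tp, x) {
         y <- main$fwd(tp, x)
         if (se) y <- seb$fwd(tp, y)
         sk <- if (is.null(proj)) x else proj$fwd(tp, x)
         op_relu(tp, op_add(tp, y, sk))
       })
}

# ---- encoders --------------------------------------------------------------

encoder_specs <- function() {
  list(
    tiny = list(kind = "plain", stem = 6L, widths = c(12L, 24L)),
    vgg19bn = list(kind = "vgg", widths = c(64L, 128L, 256L, 512L, 512L),
                   convs = c(2L, 2L, 4L, 4L, 4L)),
    resnet18 = list(kind = "resnet", block = "basic",
                    depths = c(2L, 2L, 2L, 2L),
                    widths = c(64L, 128L, 256L, 512L), se = FALSE),
    resnet50 = list(kind = "resnet", block = "bottleneck",
                    depths = c(3L, 4L, 6L, 3L),
                    widths = c(256L, 512L, 1024L, 2048L), se = FALSE),
    se_resnet50 = list(kind = "resnet", block = "bottleneck",
                       depths = c(3L, 4L, 6L, 3L),
                       widths = c(256L, 512L, 1024L, 2048L), se = TRUE),
    regnetx064 = list(kind = "resnet", block = "bottleneck",
                      depths = c(2L, 4L, 10L, 1L),
                      widths = c(168L, 392L, 784L, 1624L), se = FALSE),
    effnet_b5 = list(kind = "resnet", block = "bottleneck",
                     depths = c(3L, 5L, 7L, 5L),
                     widths = c(40L, 64L, 176L, 512L), se = TRUE))
}

build_encoder <- function(name) {
  spec <- encoder_specs()[[name]]
  if (is.null(spec)) {
    stop_trichoseg("unknown encoder '", name, "'; registered encoders: ",
                   paste(encoder_names(), collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  if (spec$kind == "plain") {
    stem <- layer_conv(3L, spec$stem, 3L, name = "enc.stem")
    stages <- list()
    cin <- spec$stem
    for (i in seq_along(spec$widths)) {
      stages[[i]] <- layer_conv(cin, spec$widths[i], 3L,
                                name = sprintf("enc.s%d", i))
      cin <- spec$widths[i]
    }
    channels <- c(spec$stem, spec$widths)
    scales <- 2^(0:length(spec$widths))
    params <- c(stem$params, unlist(lapply(stages, `[[`, "params")))
    fwd <- function(tp, x) {
      f <- list(stem$fwd(tp, x))
      for (i in seq_along(stages)) {
        f[[i + 1]] <- stages[[i]]$fwd(tp, op_maxpool2(tp, f[[i]]))
      }
      f
    }
  } else if (spec$kind == "vgg") {
    stages <- list()
    cin <- 3L
    for (i in seq_along(spec$widths)) {
      blocks <- list()
      for (j in seq_len(spec$convs[i])) {
        blocks[[j]] <- layer_conv(cin, spec$widths[i], 3L, bn = TRUE,
                                  name = sprintf("enc.s%d.%d", i, j))
        cin <- spec$widths[i]
      }
      stages[[i]] <- do.call(layer_seq, blocks)
    }
    channels <- spec$widths
    scales <- 2^(seq_along(spec$widths) - 1)
    params <- unlist(lapply(stages, `[[`, "params"))
    fwd <- function(tp, x) {
      f <- list()
      for (i in seq_along(stages)) {
        if (i > 1) x <- op_maxpool2(tp, x)
        x <- stages[[i]]$fwd(tp, x)
        f[[i]] <- x
      }
      f
    }
  } else {  # resnet-style
    stem <- layer_conv(3L, 64L, 7L, stride = 2L, bn = TRUE,
                       name = "enc.stem")
    stages <- list()
    cin <- 64L
    for (i in seq_along(spec$widths)) {
      blocks <- list()
      for (j in seq_len(spec$depths[i])) {
        stride <- if (j == 1L && i > 1L) 2L else 1L
        blocks[[j]] <- layer_resblock(cin, spec$widths[i], stride,
                                      spec$block, spec$se,
                                      sprintf("enc.s%d.%d", i, j))
        cin <- spec$widths[i]
      }
      stages[[i]] <- do.call(layer_seq, blocks)
    }
    channels <- c(64L, spec$widths)
    scales <- c(2, 4, 8, 16, 32)
    params <- c(stem$params, unlist(lapply(stages, `[[`, "params")))
    fwd <- function(tp, x) {
      f <- list(stem$fwd(tp, x))
      x <- op_maxpool2(tp, f[[1]])
      for (i in seq_along(stages)) {
        x <- stages[[i]]$fwd(tp, x)
        f[[i + 1]] <- x
      }
      f
    }
  }
  list(name = name, params = params, fwd = fwd, channels = channels,
       scales = scales, stride = max(scales))
}

# ---- decoders --------------------------------------------------------------

# Each decoder consumes the encoder pyramid (shallow -> deep) and emits a
# 1-channel logit map at the scale of the shallowest feature.
build_decoder <- function(name, enc) {
  ch <- pmin(CH_CAP, enc$channels)
  L <- length(enc$channels)
  switch(name,
    unet = {
      blocks <- list()
      prev <- enc$channels[L]
      for (i in seq(L - 1, 1)) {
        blocks[[i]] <- layer_conv(prev + enc$channels[i], ch[i], 3L,
                                  name = sprintf("dec.u%d", i))
        prev <- ch[i]
      }
      head <- layer_conv(ch[1], 1L, 1L, act = FALSE, name = "dec.head")
      list(params = c(unlist(lapply(blocks, `[[`, "params")), head$params),
           fwd = function(tp, f) {
             x <- f[[L]]
             for (i in seq(L - 1, 1)) {
               x <- op_upsample_nearest(tp, x,
                                        enc$scales[i + 1] %/% enc$scales[i])
               x <- blocks[[i]]$fwd(tp, op_concat(tp, list(x, f[[i]])))
             }
             head$fwd(tp, x)
           })
    },
    manet = {
      blocks <- list(); attn <- list()
      prev <- enc$channels[L]
      for (i in seq(L - 1, 1)) {
        cat_ch <- prev + enc$channels[i]
        attn[[i]] <- layer_se(cat_ch, name = sprintf("dec.att%d", i))
        blocks[[i]] <- layer_conv(cat_ch, ch[i], 3L,
                                  name = sprintf("dec.m%d", i))
        prev <- ch[i]
      }
      head <- layer_conv(ch[1], 1L, 1L, act = FALSE, name = "dec.head")
      list(params = c(unlist(lapply(attn, `[[`, "params")),
                      unlist(lapply(blocks, `[[`, "params")), head$params),
           fwd = function(tp, f) {
             x <- f[[L]]
             for (i in seq(L - 1, 1)) {
               x <- op_upsample_nearest(tp, x,
                                        enc$scales[i + 1] %/% enc$scales[i])
               x <- op_concat(tp, list(x, f[[i]]))
               x <- attn[[i]]$fwd(tp, x)
               x <- blocks[[i]]$fwd(tp, x)
             }
             head$fwd(tp, x)
           })
    },
    linknet = {
      projs <- list(); blocks <- list()
      prev <- enc$channels[L]
      for (i in seq(L - 1, 1)) {
        projs[[i]] <- layer_conv(prev, enc$channels[i], 1L, act = FALSE,
                                 name = sprintf("dec.p%d", i))
        blocks[[i]] <- layer_conv(enc$channels[i], ch[i], 3L,
                                  name = sprintf("dec.l%d", i))
        prev <- ch[i]
      }
      head <- layer_conv(ch[1], 1L, 1L, act = FALSE, name = "dec.head")
      list(params = c(unlist(lapply(projs, `[[`, "params")),
                      unlist(lapply(blocks, `[[`, "params")), head$params),
           fwd = function(tp, f) {
             x <- f[[L]]
             for (i in seq(L - 1, 1)) {
               x <- op_upsample_nearest(tp, x,
                                        enc$scales[i + 1] %/% enc$scales[i])
               x <- projs[[i]]$fwd(tp, x)
               x <- op_add(tp, x, f[[i]])
               x <- blocks[[i]]$fwd(tp, x)
             }
             head$fwd(tp, x)
           })
    },
    unetpp = {
      # nested dense skip pathways X[i][j]; channels capped
      chn <- function(i, j) if (j == 0) enc$channels[i] else ch[i]
      blocks <- list()
      for (j in seq_len(L - 1)) {
        for (i in seq_len(L - j)) {
          cin <- sum(vapply(0:(j - 1), function(jj) chn(i, jj), numeric(1))) +
            chn(i + 1, j - 1)
          blocks[[paste(i, j)]] <-
            layer_conv(cin, ch[i], 3L, name = sprintf("dec.n%d.%d", i, j))
        }
      }
      head <- layer_conv(ch[1], 1L, 1L, act = FALSE, name = "dec.head")
      list(params = c(unlist(lapply(blocks, `[[`, "params")), head$params),
           fwd = function(tp, f) {
             X <- list()
             for (i in seq_len(L)) X[[paste(i, 0)]] <- f[[i]]
             for (j in seq_len(L - 1)) {
               for (i in seq_len(L - j)) {
                 up <- op_upsample_nearest(
                   tp, X[[paste(i + 1, j - 1)]],
                   enc$scales[i + 1] %/% enc$scales[i])
                 prevs <- lapply(0:(j - 1), function(jj) X[[paste(i, jj)]])
                 xin <- op_concat(tp, c(prevs, list(up)))
                 X[[paste(i, j)]] <- blocks[[paste(i, j)]]$fwd(tp, xin)
               }
             }
             head$fwd(tp, X[[paste(1, L - 1)]])
           })
    },
    deeplabv3 = {
      c0 <- min(CH_CAP, 64L)
      cL <- enc$channels[L]
      b1 <- layer_conv(cL, c0, 1L, name = "dec.aspp1")
      b2 <- layer_conv(cL, c0, 3L, dil = 2L, name = "dec.aspp2")
      b3 <- layer_conv(cL, c0, 3L, dil = 4L, name = "dec.aspp3")
      fcp <- nn_dense_param(cL, c0, "dec.aspp.pool")
      fuse <- layer_conv(4L * c0, c0, 1L, name = "dec.fuse")
      refine <- layer_conv(c0, c0, 3L, name = "dec.refine")
      head <- layer_conv(c0, 1L, 1L, act = FALSE, name = "dec.head")
      list(params = c(b1$params, b2$params, b3$params,
                      list(fcp$w, fcp$b), fuse$params, refine$params,
                      head$params),
           fwd = function(tp, f) {
             x <- f[[L]]
             hw <- dim(x$value)[1:2]
             p <- op_relu_vec(tp, op_dense(tp, op_global_avg(tp, x), fcp))
             x <- op_concat(tp, list(b1$fwd(tp, x), b2$fwd(tp, x),
                                     b3$fwd(tp, x), op_broadcast(tp, p, hw)))
             x <- fuse$fwd(tp, x)
             x <- op_upsample_nearest(tp, x, enc$scales[L] %/% enc$scales[1])
             head$fwd(tp, refine$fwd(tp, x))
           })
    },
    stop_trichoseg("unknown decoder '", name, "'; registered decoders: ",
                   paste(decoder_names(), collapse = ", "),
                   class = "trichoseg_registry_error"))
}

#' Assemble a segmentation model from registered components
#'
#' The model maps an H x W x 3 image to an H x W per-pixel foreground
#' probability; any registered encoder composes with any registered
#' decoder. H and W must be multiples of the model stride (the deepest
#' downsampling factor: 4 for `tiny`, 16 for `vgg19bn`, 32 for the
#' residual families). Weights are initialised randomly (He) under the
#' config seed; `pretrained = TRUE` is refused because no ImageNet
#' weights are bundled with the package.
#'
#' @param cfg a [model_config()].
#' @return an object of class `trichoseg_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  if (isTRUE(cfg$pretrained)) {
    stop_trichoseg("pretrained encoder weights are not bundled with this ",
                   "package; build with pretrained = FALSE",
                   class = "trichoseg_registry_error")
  }
  if (!cfg$decoder %in% decoder_names()) {
    stop_trichoseg("unknown decoder '", cfg$decoder,
                   "'; registered decoders: ",
                   paste(decoder_names(), collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  with_seed(derive_seed(cfg$seed, "init", cfg$encoder, cfg$decoder), {
    enc <- build_encoder(cfg$encoder)
    dec <- build_decoder(cfg$decoder, enc)
  })
  # trichome foreground is sparse (a few percent of pixels); start the
  # head at the background prior so early epochs are not spent unlearning
  # a 50% foreground rate
  for (p in dec$params) {
    if (endsWith(p$name, "dec.head.b")) p$value[] <- -3
  }
  model <- list(
    config = cfg, encoder = enc, decoder = dec,
    params = c(enc$params, dec$params),
    stride = enc$stride,
    # per-channel input standardisation; replaced by the training-set
    # statistics in train_segmenter()
    norm = list(mean = c(0.5, 0.5, 0.5), sd = c(0.25, 0.25, 0.25)))
  class(model) <- "trichoseg_model"
  model
}

#' @export
print.trichoseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<trichoseg_model %s-%s: %s parameters, stride %d>\n",
              x$config$encoder, x$config$decoder,
              format(np, big.mark = ","), x$stride))
  invisible(x)
}

# Forward pass: returns the probability map (H x W matrix) and, if a tape
# is supplied, the probability node for backprop.
model_forward <- function(model, img, tape = NULL) {
  tp <- tape %||% nn_tape()
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) {
    stop_trichoseg("model input must be H x W x 3",
                   class = "trichoseg_validation_error")
  }
  if (d[1] %% model$stride != 0 || d[2] %% model$stride != 0) {
    stop_trichoseg("input ", d[1], "x", d[2], " is not a multiple of the ",
                   "model stride ", model$stride,
                   class = "trichoseg_validation_error")
  }
  x <- img
  for (ch in 1:3) {
    x[, , ch] <- (x[, , ch] - model$norm$mean[ch]) / model$norm$sd[ch]
  }
  xin <- op_input(tp, x)
  feats <- model$encoder$fwd(tp, xin)
  logits <- model$decoder$fwd(tp, feats)
  if (model$encoder$scales[1] > 1) {
    logits <- op_upsample_nearest(tp, logits, model$encoder$scales[1])
  }
  prob <- op_sigmoid(tp, logits)
  list(prob = prob$value[, , 1], node = prob, tape = tp)
}
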