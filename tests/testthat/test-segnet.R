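# Segmentation networks, losses, training loop.

test_that("tiny-unet maps a 64x64 image to a probability map in [0,1]", {
  m <- build_model(model_config(recipe = "RS64"))
  img <- withr::with_seed(1, array(runif(64 * 64 * 3), c(64, 64, 3)))
  fw <- model_forward(m, img)
  expect_equal(dim(fw$prob), c(64, 64))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  expect_error(model_forward(m, array(0.5, c(30, 30, 3))),
               class = "trichoseg_validation_error")
})

test_that("registry errors name the offending component", {
  expect_error(model_config(decoder = "segformer"), "segformer",
               class = "trichoseg_registry_error")
  expect_error(model_config(encoder = "alexnet"), "alexnet",
               class = "trichoseg_registry_error")
  expect_error(model_config(loss = "hinge"), "hinge",
               class = "trichoseg_registry_error")
  expect_error(model_config(threshold = 1.2),
               class = "trichoseg_validation_error")
  expect_error(build_model(model_config(pretrained = TRUE)),
               class = "trichoseg_registry_error")
})

test_that("all 30 full-size encoder x decoder pairs are constructible", {
  full <- setdiff(encoder_names(), "tiny")
  pairs <- expand.grid(enc = full, dec = decoder_names(),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(pairs), 30)
  for (i in seq_len(nrow(pairs))) {
    m <- build_model(model_config(encoder = pairs$enc[i],
                                  decoder = pairs$dec[i],
                                  recipe = "RS64"))
    expect_s3_class(m, "trichoseg_model")
    expect_gt(length(m$params), 0)
    rm(m)
  }
})

test_that("every registered pair runs one forward/backward step at 64x64", {
  img <- withr::with_seed(2, array(runif(64 * 64 * 3), c(64, 64, 3)))
  target <- withr::with_seed(3, matrix(rbinom(64 * 64, 1, 0.1), 64))
  pairs <- expand.grid(enc = encoder_names(), dec = decoder_names(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    m <- build_model(model_config(encoder = pairs$enc[i],
                                  decoder = pairs$dec[i], recipe = "RS64"))
    fw <- model_forward(m, img)
    expect_equal(dim(fw$prob), c(64, 64))
    gp <- loss_grad(matrix(fw$prob, 64), target, "dice")
    nn_backward(fw$tape, fw$node, array(gp, dim(fw$node$value)))
    grads <- vapply(m$params, function(p) !is.null(p$grad), logical(1))
    expect_gt(mean(grads), 0.9)
    rm(m, fw)
  }
})

test_that("losses take their closed-form values at reference points", {
  g <- withr::with_seed(7, matrix(rbinom(256, 1, 0.3), 16))
  # perfect binary prediction: dice and jaccard are 0 (eps-consistent)
  expect_equal(compute_loss(g, g, "dice"), 0)
  expect_equal(compute_loss(g, g, "jaccard"), 0)
  # uniform 0.5 prediction: BCE is ln 2 regardless of the target
  expect_equal(compute_loss(matrix(0.5, 16, 16), g, "bce"), log(2),
               tolerance = 1e-9)
  # all-background, all-zero prediction: focal is 0 (up to the clamp)
  z <- matrix(0, 16, 16)
  expect_lt(compute_loss(z, z, "focal"), 1e-10)
  expect_error(compute_loss(matrix(2, 4, 4), matrix(1, 4, 4), "bce"),
               class = "trichoseg_validation_error")
})

test_that("dice/jaccard losses satisfy J = D/(2-D) up to eps effects", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- 48
      p <- matrix(rbinom(n * n, 1, runif(1, 0.05, 0.5)), n)
      g <- matrix(rbinom(n * n, 1, runif(1, 0.05, 0.5)), n)
      D <- 1 - compute_loss(p, g, "dice")
      J <- 1 - compute_loss(p, g, "jaccard")
      # eps = 1 smoothing perturbs both scores by O(1/|mask|), an
      # absolute (not relative) effect
      expect_lt(abs(J - D / (2 - D)), 0.02)
    }
  })
})

test_that("analytic loss gradients match finite differences", {
  withr::with_seed(41, {
    p <- matrix(runif(64, 0.1, 0.9), 8)
    g <- matrix(rbinom(64, 1, 0.4), 8)
    for (kind in loss_names()) {
      gr <- loss_grad(p, g, kind)
      for (i in c(1, 17, 64)) {
        eps <- 1e-6
        pp <- p; pp[i] <- p[i] + eps
        pm <- p; pm[i] <- p[i] - eps
        num <- (compute_loss(pp, g, kind) - compute_loss(pm, g, kind)) /
          (2 * eps)
        expect_equal(gr[i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("training bookkeeping: one epoch on four images", {
  fx <- fixture_train_val(n_train = 4, n_val = 2)
  cfg <- model_config(recipe = "RS64+RF", epochs = 1, seed = 5)
  rpt <- train_segmenter(cfg, fx$train, fx$val)
  expect_s3_class(rpt, "train_report")
  expect_equal(nrow(rpt$epochs), 1)
  expect_true(is.finite(rpt$epochs$val_iou))
  expect_error(train_segmenter(cfg, list(), fx$val),
               class = "trichoseg_validation_error")
})

test_that("training improves validation IoU on the small fixture", {
  fx <- fixture_train_val(n_train = 10, n_val = 4, mean_hairs = 10)
  cfg <- model_config(recipe = "RS64+RF", epochs = 4, seed = 21)
  rpt <- train_segmenter(cfg, fx$train, fx$val)
  expect_gte(rpt$epochs$val_iou[nrow(rpt$epochs)], rpt$epochs$val_iou[1])
  expect_gt(rpt$best_val_iou, 0.1)
})

test_that("predict_mask applies strict threshold semantics", {
  fx <- fixture_train_val(n_train = 2, n_val = 0)
  cfg <- model_config(recipe = "RS64", epochs = 1, seed = 2)
  rpt <- train_segmenter(cfg, fx$train, list())
  img <- fx$train[[1]]$pixels
  pm99 <- predict_mask(rpt$model, img, threshold = 1 - 1e-9)
  expect_equal(nrow(pm99$foreground), 0)
  prob <- model_forward(rpt$model, img)$prob
  pm50 <- predict_mask(rpt$model, img, threshold = 0.5)
  expect_equal(nrow(pm50$foreground), sum(prob > 0.5))
  expect_error(predict_mask(rpt$model, array(0.5, c(10, 10, 3))),
               class = "trichoseg_validation_error")
})

test_that("checkpoints round trip exactly", {
  fx <- fixture_train_val(n_train = 2, n_val = 1)
  cfg <- model_config(recipe = "RS64", epochs = 1, seed = 9)
  rpt <- train_segmenter(cfg, fx$train, fx$val)
  fp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(rpt$model, fp)
  m2 <- load_checkpoint(fp)
  img <- fx$train[[1]]$pixels
  expect_identical(model_forward(rpt$model, img)$prob,
                   model_forward(m2, img)$prob)
  expect_error(load_checkpoint("no/such/file.rds"),
               class = "trichoseg_io_error")
})

test_that("training is exactly reproducible for the same seed", {
  fx <- fixture_train_val(n_train = 4, n_val = 2)
  cfg <- model_config(recipe = "RS64+RF", epochs = 2, seed = 13)
  r1 <- train_segmenter(cfg, fx$train, fx$val)
  r2 <- train_segmenter(cfg, fx$train, fx$val)
  expect_identical(r1$epochs, r2$epochs)
})
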