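# Paired image/annotation augmentation.

test_that("recipe strings parse to ordered steps and round trip", {
  r <- parse_recipe("RS768+RF")
  expect_length(r$steps, 2)
  expect_equal(r$steps[[1]]$op, "RS")
  expect_equal(r$steps[[1]]$size, c(768, 768))
  expect_equal(r$steps[[2]]$op, "RF")
  expect_equal(format(parse_recipe("RC1536+RS1024+RF")),
               "RC1536+RS1024+RF")
  expect_length(parse_recipe("RF")$steps, 1)
  expect_length(parse_recipe("")$steps, 0)
  expect_error(parse_recipe("RS99x"), "RS99x",
               class = "trichoseg_parse_error")
})

test_that("the empty recipe is the identity", {
  fx <- fixture_train_val(n_train = 1, n_val = 0)
  rec <- fx$train[[1]]
  out <- apply_recipe("", rec, stroke_width = 2, seed = 9)
  expect_identical(out$image, rec$pixels)
  expect_identical(out$mask$foreground,
                   rasterize(rec$splines, rec$size, 2)$foreground)
})

test_that("double flip equals rotating the unflipped mask by 180 degrees", {
  fx <- fixture_train_val(n_train = 1, n_val = 0)
  rec <- fx$train[[1]]
  base <- apply_recipe("", rec, stroke_width = 2, seed = 1)
  # find a seed where both coins come up heads
  seed_both <- NULL
  for (s in 1:50) {
    hit <- with_seed(s, c(runif(1) < 0.5, runif(1) < 0.5))
    if (all(hit)) { seed_both <- s; break }
  }
  expect_false(is.null(seed_both))
  flipped <- apply_recipe("RF", rec, stroke_width = 2, seed = seed_both)
  expect_identical(flipped$mask$foreground,
                   flip_mask(base$mask, vertical = TRUE,
                             horizontal = TRUE)$foreground)
  expect_identical(flipped$image,
                   rec$pixels[rev(seq_len(64)), rev(seq_len(64)), ])
})

test_that("RS halves the mask area when the side halves (width fixed)", {
  spec <- synthetic_spec(image_size = c(128, 128),
                         hair_count = list(mean = 12, dispersion = Inf),
                         hair_length_px = list(mean = 40, sd = 8))
  rec <- generate_image(spec, 61)
  full <- apply_recipe("", rec, stroke_width = 2, seed = 1)
  half <- apply_recipe("RS64", rec, stroke_width = 2, seed = 1)
  expect_equal(dim(half$image)[1:2], c(64, 64))
  ratio <- nrow(half$mask$foreground) / nrow(full$mask$foreground)
  # stroke width is fixed in pixels while lengths halve
  expect_gt(ratio, 0.5 * 0.6)
  expect_lt(ratio, 0.5 * 1.4)
})

test_that("RC crops are in bounds, clip splines, and oversize crops error", {
  fx <- fixture_train_val(n_train = 1, n_val = 0, size = c(64, 64))
  rec <- fx$train[[1]]
  out <- apply_recipe("RC32", rec, stroke_width = 2, seed = 4)
  expect_equal(dim(out$image)[1:2], c(32, 32))
  expect_equal(out$mask$shape, c(32L, 32L))
  for (s in out$splines) {
    expect_true(all(s$points[, 1] > -1 & s$points[, 1] < 32))
  }
  expect_error(apply_recipe("RC128", rec, seed = 1),
               class = "trichoseg_validation_error")
})

test_that("cropped masks agree with crops of the full mask away from borders", {
  # interior pixels of the crop window must match the directly cropped
  # full-resolution mask (border pixels may differ by the brush radius)
  fx <- fixture_train_val(n_train = 1, n_val = 0, size = c(64, 64),
                          mean_hairs = 12)
  rec <- fx$train[[1]]
  full <- sparse_decode(rasterize(rec$splines, rec$size, 2))
  out <- with_seed(17, {
    r0 <- sample.int(64 - 32 + 1, 1) - 1L
    c0 <- sample.int(64 - 32 + 1, 1) - 1L
    list(aug = apply_recipe("RC32", rec, stroke_width = 2, seed = 17),
         r0 = r0, c0 = c0)
  })
  direct <- full[out$r0 + seq_len(32), out$c0 + seq_len(32)]
  got <- sparse_decode(out$aug$mask)
  interior <- 3:30
  expect_equal(got[interior, interior], direct[interior, interior])
})

test_that("identical (recipe, record, seed) give identical outputs", {
  fx <- fixture_train_val(n_train = 1, n_val = 0)
  rec <- fx$train[[1]]
  a <- apply_recipe("RC48+RS32+RF", rec, stroke_width = 2, seed = 12)
  b <- apply_recipe("RC48+RS32+RF", rec, stroke_width = 2, seed = 12)
  expect_identical(a$image, b$image)
  expect_identical(a$mask$foreground, b$mask$foreground)
})

test_that("geometry-before-raster avoids the broken-hair artifact", {
  # long thin diagonal hairs rendered at 128, downscaled to 32:
  # nearest-neighbour mask resizing (the deliberately wrong oracle)
  # fragments them; re-rasterizing transformed splines does not
  spl <- withr::with_seed(3, lapply(1:6, function(i) {
    a <- c(runif(1, 2, 40), runif(1, 2, 40))
    b <- a + c(runif(1, 60, 80), runif(1, 60, 80))
    spline_annotation(rbind(a, (a + b) / 2 + runif(2, -4, 4), b),
                      c(128, 128), id = paste0("h", i))
  }))
  right <- rasterize(lapply(spl, transform_spline, target_size = c(32, 32)),
                     c(32, 32), stroke_width = 1)
  wrong <- sparse_encode(
    resize_nearest(sparse_decode(rasterize(spl, c(128, 128), 1)),
                   c(32, 32)))
  expect_gte(mask_components(wrong), mask_components(right))
  # re-rasterized hairs stay whole: no more pieces than hairs
  expect_lte(mask_components(right), 6)
})
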