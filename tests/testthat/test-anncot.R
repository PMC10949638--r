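# Annotation data model and I/O.

test_that("spline construction and validation enforce the invariants", {
  expect_error(spline_annotation(matrix(c(1, 2), 1, 2), c(16, 16)),
               class = "trichoseg_validation_error")
  expect_error(spline_annotation(rbind(c(0, 0), c(5, 5)), c(0, 16)),
               class = "trichoseg_validation_error")
  # up to 5% outside is legal (edge trichomes), beyond is not
  expect_silent(spline_annotation(rbind(c(-0.7, 0), c(5, 5)), c(16, 16)))
  expect_error(spline_annotation(rbind(c(-2, 0), c(5, 5)), c(16, 16)),
               class = "trichoseg_validation_error")
})

test_that("transform_spline scales per axis and composes", {
  s <- spline_annotation(rbind(c(100, 200), c(960, 1280)), c(1920, 2560))
  t1 <- transform_spline(s, c(768, 768))
  expect_equal(t1$points[1, ], c(100 * 768 / 1920, 200 * 768 / 2560))
  expect_equal(t1$points[1, ], c(40, 60))
  expect_equal(t1$reference_size, c(768, 768))
  # identity and inverse composition
  expect_equal(transform_spline(s, c(1920, 2560))$points, s$points)
  back <- transform_spline(transform_spline(s, c(3840, 5120)),
                           c(1920, 2560))
  expect_equal(back$points, s$points, tolerance = 1e-12)
  expect_equal(nrow(t1$points), nrow(s$points))
})

test_that("rasterize draws a straight 2-point spline as its Bresenham line", {
  s <- spline_annotation(rbind(c(0, 0), c(0, 10)), c(16, 16))
  m <- rasterize(list(s), c(16, 16), stroke_width = 1)
  # oracle: horizontal line through row 0, cols 0..10
  expect_equal(m$foreground,
               cbind(rep(0L, 11), 0:10))
  # diagonal line: exactly the diagonal pixels
  d <- spline_annotation(rbind(c(2, 2), c(9, 9)), c(16, 16))
  md <- rasterize(list(d), c(16, 16), stroke_width = 1)
  expect_equal(md$foreground, cbind(2:9, 2:9))
})

test_that("rasterize is a set union: duplicates add nothing, empty is empty", {
  s <- spline_annotation(rbind(c(3, 1), c(8, 12)), c(16, 16))
  one <- rasterize(list(s), c(16, 16), 2)
  two <- rasterize(list(s, s), c(16, 16), 2)
  expect_identical(one$foreground, two$foreground)
  expect_identical(nrow(rasterize(list(), c(16, 16))$foreground), 0L)
})

test_that("curve interpolation passes through every control point", {
  spl <- fixture_splines()
  for (s in spl) {
    sm <- sample_spline(s)
    for (k in seq_len(nrow(s$points))) {
      dmin <- min(sqrt(rowSums((sm - matrix(s$points[k, ], nrow(sm), 2,
                                            byrow = TRUE))^2)))
      expect_lt(dmin, 1e-8)
    }
  }
})

test_that("sparse encode/decode is the identity on binary rasters", {
  expect_equal(nrow(sparse_encode(matrix(0, 768, 768) * 0)$foreground), 0)
  d <- matrix(0L, 8, 8); d[2, 3] <- 1L; d[4, 5] <- 1L
  expect_equal(sparse_encode(d)$foreground, cbind(c(1L, 3L), c(2L, 4L)))
  withr::with_seed(5, {
    for (i in 1:10) {
      d <- matrix(rbinom(64 * 64, 1, runif(1, 0, 0.5)), 64, 64)
      expect_identical(sparse_decode(sparse_encode(d)),
                       matrix(as.integer(d), 64, 64))
    }
  })
  expect_error(sparse_encode(matrix(c(0, 2), 2, 2)),
               class = "trichoseg_validation_error")
})

test_that("mask CSV and PNG round trips are exact", {
  m <- withr::with_seed(8, random_sparse_mask(c(24, 17), 0.2))
  fp <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(m, fp)
  expect_identical(read_mask_csv(fp)$foreground, m$foreground)
  fpng <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, fpng)
  expect_identical(read_mask_png(fpng)$foreground, m$foreground)
})

test_that("annotation JSON round trips through read_annotations", {
  dir <- fixture_dataset_dir()
  recs <- read_annotations(dir)
  expect_length(recs, 2)
  n_splines <- vapply(recs, function(r) length(r$splines), numeric(1))
  orig <- jsonlite::fromJSON(file.path(dir, "annotations.json"),
                             simplifyVector = FALSE)
  expect_equal(sum(n_splines),
               sum(vapply(orig$images, function(i) length(i$splines),
                          numeric(1))))
  gts <- vapply(recs, function(r) r$meta$genotype, character(1))
  expect_setequal(gts, c("a", "b"))
  # unannotated images present in the directory become empty records
  png::writePNG(array(0.5, c(64, 64, 3)), file.path(dir, "extra.png"))
  recs2 <- read_annotations(dir)
  expect_length(recs2, 3)
  extra <- recs2[[which(vapply(recs2, function(r) r$meta$image_id,
                               character(1)) == "extra.png")]]
  expect_length(extra$splines, 0)
})

test_that("read_annotations flags missing files, bad sizes, bad splines", {
  dir <- withr::local_tempdir()
  png::writePNG(array(0.4, c(8, 8, 3)), file.path(dir, "ok.png"))
  write_doc <- function(images) {
    jsonlite::write_json(list(images = images),
                         file.path(dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_doc(list(list(file = "gone.png", height = 8, width = 8,
                      splines = list())))
  expect_error(read_annotations(dir), "gone.png",
               class = "trichoseg_io_error")
  write_doc(list(list(file = "ok.png", height = 16, width = 8,
                      splines = list())))
  expect_error(read_annotations(dir), class = "trichoseg_validation_error")
  write_doc(list(list(file = "ok.png", height = 8, width = 8,
                      splines = list(list(id = "s1",
                                          points = list(c(1, 1)))))))
  expect_error(read_annotations(dir), class = "trichoseg_validation_error")
  writeLines("{not json", file.path(dir, "annotations.json"))
  expect_error(read_annotations(dir), class = "trichoseg_io_error")
})

test_that("split_dataset follows floor/floor/remainder and partitions", {
  recs <- lapply(seq_len(10), function(i) {
    annotated_image(NULL, size = c(4, 4),
                    meta = list(image_id = as.character(i)))
  })
  sp <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(vapply(sp, length, numeric(1)),
               c(train = 8, val = 1, test = 1))
  ids <- function(part) vapply(part, function(r) r$meta$image_id,
                               character(1))
  all_ids <- c(ids(sp$train), ids(sp$val), ids(sp$test))
  expect_setequal(all_ids, as.character(1:10))
  expect_equal(length(all_ids), length(unique(all_ids)))
  # all-train degenerate fractions
  sp1 <- split_dataset(recs, c(1, 0, 0), seed = 3)
  expect_length(sp1$train, 10)
  # determinism
  sp2 <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_error(split_dataset(recs, c(0.5, 0.2, 0.2)),
               class = "trichoseg_validation_error")
})

test_that("split sizes always sum to N (property)", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(1:400, 1)
      f1 <- runif(1); f2 <- runif(1, 0, 1 - f1)
      fr <- c(f1, f2, 1 - f1 - f2)
      sp <- split_dataset(as.list(seq_len(n)), fr, seed = i)
      expect_equal(sum(lengths(sp)), n)
      expect_equal(length(sp$train), floor(fr[1] * n))
      expect_equal(length(sp$val), floor(fr[2] * n))
    }
  })
})

test_that("stratified splits balance per stratum and warn on tiny strata", {
  recs <- c(
    lapply(1:40, function(i) annotated_image(
      NULL, size = c(4, 4), meta = list(image_id = paste0("a", i),
                                        ghs = "3"))),
    lapply(1:20, function(i) annotated_image(
      NULL, size = c(4, 4), meta = list(image_id = paste0("b", i),
                                        ghs = "4"))))
  sp <- split_dataset(recs, c(0.65, 0.15, 0.20), seed = 2,
                      stratify_by = "ghs")
  cls <- function(part) table(vapply(part, function(r) r$meta$ghs,
                                     character(1)))
  expect_equal(unname(cls(sp$train)[["3"]]), 26)  # floor(0.65*40)
  expect_equal(unname(cls(sp$train)[["4"]]), 13)  # floor(0.65*20)
  tiny <- lapply(1:2, function(i) annotated_image(
    NULL, size = c(4, 4), meta = list(image_id = paste0("c", i),
                                      ghs = "5")))
  expect_warning(sp2 <- split_dataset(c(recs, tiny), seed = 2,
                                      stratify_by = "ghs"),
                 "fewer than 3")
  expect_true(all(paste0("c", 1:2) %in%
                    vapply(sp2$train, function(r) r$meta$image_id,
                           character(1))))
})

test_that("GHS labels are ordered and reject unknown values", {
  expect_error(ghs_label("6"), class = "trichoseg_validation_error")
  lv <- ghs_label(c("3/4", "1", "5+"))
  expect_true(lv[2] < lv[1] && lv[1] < lv[3])
  expect_equal(levels(lv), ghs_levels())
})

test_that("shape is preserved across a 2x rasterization scale (IoU >= 0.6)", {
  spl <- fixture_splines()
  direct <- rasterize(spl, c(64, 64), stroke_width = 2)
  spl2 <- lapply(spl, transform_spline, target_size = c(128, 128))
  hi <- rasterize(spl2, c(128, 128), stroke_width = 4)
  down <- box_downsample2(sparse_decode(hi))
  re <- sparse_encode((down >= 0.5) * 1L)
  expect_gte(iou(re, direct), 0.6)
})
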