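# Shared fixtures, all generated in code at test time.

# A deterministic set of thin, curved "hair" splines on a 64 x 64 canvas,
# used by the rendering/shape-preservation tests.
fixture_splines <- function(size = c(64, 64), n = 8, seed = 424) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- c(runif(1, 4, size[1] - 5), runif(1, 4, size[2] - 5))
      th <- runif(1, 0, 2 * pi)
      len <- runif(1, 18, 34)
      b <- a + len * c(cos(th), sin(th))
      b <- pmin(pmax(b, 1), size - 2)
      mid <- (a + b) / 2 + runif(2, -3, 3)
      spline_annotation(rbind(a, mid, b), size, id = sprintf("fx%02d", i))
    })
  })
}

random_sparse_mask <- function(shape = c(32, 32), p = 0.15) {
  sparse_encode(matrix(rbinom(prod(shape), 1, p), shape[1], shape[2]))
}

# Small annotated dataset written to disk in the JSON dialect.
fixture_dataset_dir <- function(dir = withr::local_tempdir(.local_envir =
                                  parent.frame())) {
  spec <- synthetic_spec(image_size = c(64, 64),
                         hair_count = list(mean = 6, dispersion = 8),
                         hair_length_px = list(mean = 18, sd = 5))
  recs <- list(
    generate_image(spec, 101, meta = list(genotype = "a", ghs = "3",
                                          image_id = "img_a.png")),
    generate_image(spec, 102, meta = list(genotype = "b", ghs = "4",
                                          image_id = "img_b.png")))
  write_annotations(recs, dir)
  dir
}

# Tiny training fixture: panel of two densities at a small resolution.
fixture_train_val <- function(n_train = 6, n_val = 2, size = c(64, 64),
                              mean_hairs = 8, seed = 777) {
  spec <- synthetic_spec(image_size = size,
                         hair_count = list(mean = mean_hairs, dispersion = 8),
                         hair_length_px = list(mean = 20, sd = 6))
  list(train = lapply(seq_len(n_train), function(i) {
         generate_image(spec, derive_seed(seed, "tr", i))
       }),
       val = lapply(seq_len(n_val), function(i) {
         generate_image(spec, derive_seed(seed, "va", i))
       }))
}
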