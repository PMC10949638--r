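# Metrics, LTS, aggregation, ranking.

# Brute-force oracle: dense pixel-set enumeration, independent of the
# sparse-set implementation.
oracle_metrics <- function(p, g) {
  P <- which(sparse_decode(p) == 1)
  G <- which(sparse_decode(g) == 1)
  i <- length(intersect(P, G)); u <- length(union(P, G))
  iou <- if (u == 0) 1 else i / u
  prec <- if (length(P) == 0) 0 else i / length(P)
  rec <- if (length(G) == 0) 0 else i / length(G)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(iou = iou, f1 = f1, precision = prec, recall = rec,
       lts_p = 1000 * length(P) / length(sparse_decode(p)))
}

test_that("iou and f1 match hand-enumerated band masks", {
  # P = rows 0-1, G = rows 1-2 of a 4x4: |P|=|G|=8, overlap 4, union 12
  P <- sparse_encode(rbind(matrix(1, 2, 4), matrix(0, 2, 4)))
  G <- sparse_encode(rbind(matrix(0, 1, 4), matrix(1, 2, 4),
                           matrix(0, 1, 4)))
  expect_equal(iou(P, G), 1 / 3)
  f <- f1_score(P, G)
  expect_equal(unname(f), c(0.5, 0.5, 0.5))
  expect_equal(iou(P, P), 1.0)
  expect_equal(unname(f1_score(P, P)), c(1, 1, 1))
  # disjoint
  Q <- sparse_encode(rbind(matrix(0, 2, 4), matrix(1, 2, 4)))
  expect_equal(iou(P, Q), 0)
  # degenerate conventions
  E <- sparse_mask(c(4, 4))
  expect_equal(iou(E, E), 1.0)
  expect_warning(fe <- f1_score(E, P), "precision")
  expect_equal(fe[["f1"]], 0)
  expect_error(iou(P, sparse_mask(c(5, 4))),
               class = "trichoseg_validation_error")
})

test_that("metrics agree with the brute-force oracle on random masks", {
  withr::with_seed(202, {
    for (i in 1:40) {
      p <- random_sparse_mask(c(32, 32), runif(1, 0, 0.4))
      g <- random_sparse_mask(c(32, 32), runif(1, 0, 0.4))
      o <- oracle_metrics(p, g)
      expect_equal(iou(p, g), o$iou)
      f <- f1_score(p, g, warn = FALSE)
      expect_equal(f[["f1"]], o$f1)
      expect_equal(f[["precision"]], o$precision)
      # identities: F1 = 2*IoU/(1+IoU), IoU <= F1
      expect_equal(f[["f1"]], 2 * o$iou / (1 + o$iou), tolerance = 1e-12)
      expect_lte(o$iou, f[["f1"]])
    }
  })
})

test_that("lts is the scaled foreground fraction with exact invariants", {
  expect_equal(lts(sparse_mask(c(768, 768)))$lts, 0)
  full <- sparse_encode(matrix(1, 16, 16))
  expect_equal(lts(full)$lts, 1000)
  m <- withr::with_seed(4, random_sparse_mask(c(768, 768), 0.005))
  r <- lts(m)
  expect_equal(r$lts, 1000 * r$n_fg / (768 * 768))
  # the worked example: 3072 fg pixels at 768x768
  expect_equal(1000 * 3072 / (768 * 768), 5.208333, tolerance = 1e-6)
  # exact scale equivariance under 2x nearest-neighbour upsampling
  dm <- sparse_decode(m)
  up <- sparse_encode(dm[rep(seq_len(768), each = 2),
                         rep(seq_len(768), each = 2)])
  expect_identical(lts(up)$lts, r$lts)
})

test_that("score_batch in oracle mode scores rasterized truth", {
  pan <- list(
    synthetic_genotype("lo", synthetic_spec(
      image_size = c(64, 64), hair_count = list(mean = 3, dispersion = 8),
      hair_length_px = list(mean = 14, sd = 4)), "2"),
    synthetic_genotype("hi", synthetic_spec(
      image_size = c(64, 64), hair_count = list(mean = 20, dispersion = 8),
      hair_length_px = list(mean = 14, sd = 4)), "4+"))
  recs <- generate_panel(pan, 4, seed = 31,
                         meta = list(environment = "GH"))
  tab <- score_batch(records = recs, oracle = TRUE)
  expect_s3_class(tab, "score_table")
  expect_equal(nrow(tab), 8)
  expect_equal(tab$lts[1],
               lts(rasterize(recs[[1]]$splines, recs[[1]]$size, 2))$lts)
  ag <- aggregate_scores(tab, "genotype")
  expect_lt(ag$mean[ag$genotype == "lo"], ag$mean[ag$genotype == "hi"])
  expect_equal(nrow(score_batch(records = list(), oracle = TRUE)), 0)
})

test_that("aggregate_scores matches hand-computed group statistics", {
  tab <- data.frame(
    image_id = paste0("i", 1:6), genotype = c("a", "a", "a", "b", "b", "b"),
    ghs = "3", leaf = "L3", environment = c("GH", "GH", "GH", "FD", "FD",
                                            "FD"),
    year = "Y1", position = "First", n_fg = 0,
    lts = c(2, 4, 6, 10, 10, 10))
  ag <- aggregate_scores(tab, "genotype")
  expect_equal(ag$mean, c(4, 10))
  expect_equal(ag$sd, c(2, 0))
  expect_equal(ag$n, c(3L, 3L))
  # t-interval: 4 +/- qt(.975, 2) * 2/sqrt(3)
  expect_equal(ag$ci_hi[1], 4 + stats::qt(0.975, 2) * 2 / sqrt(3))
  one <- aggregate_scores(tab, "ghs")
  expect_equal(one$mean, mean(tab$lts))
  expect_error(aggregate_scores(tab, "nope"),
               class = "trichoseg_validation_error")
  # n = 1 groups have no sd
  expect_true(is.na(aggregate_scores(tab[1, ], "genotype")$sd))
})

test_that("flag_ghs_dips detects a constructed dip at class 4", {
  tab <- data.frame(
    image_id = paste0("i", 1:8),
    genotype = "x", leaf = "L3", environment = "GH", year = "Y1",
    position = "First", n_fg = 0,
    ghs = rep(c("3", "3/4", "4", "4/4+"), each = 2),
    lts = c(3, 3, 6, 6, 4, 4, 8, 8))
  dips <- flag_ghs_dips(tab)
  expect_equal(nrow(dips), 1)
  expect_equal(dips$from, "3/4")
  expect_equal(dips$to, "4")
  # monotone table flags nothing
  tab$lts <- rep(c(1, 2, 3, 4), each = 2)
  expect_equal(nrow(flag_ghs_dips(tab)), 0)
})

test_that("rank_genotypes orders by mean with stable name tie-breaks", {
  tab <- data.frame(
    image_id = paste0("i", 1:6),
    genotype = c("g1", "g1", "g2", "g2", "g3", "g3"),
    ghs = c("3", "3", "4", "4", "2", "2"), leaf = "L3",
    environment = "GH", year = "Y1", position = "First", n_fg = 0,
    lts = c(5, 5, 1, 1, 3, 3))
  rk <- rank_genotypes(tab, within = "GH")
  expect_equal(rk$genotype, c("g2", "g3", "g1"))
  expect_equal(rk$mean_lts, c(1, 3, 5))
  expect_equal(rk$ghs, c("4", "2", "3"))
  # tie on mean: name order, stable
  tab$lts <- c(2, 2, 2, 2, 9, 9)
  rk2 <- rank_genotypes(tab)
  expect_equal(rk2$genotype, c("g1", "g2", "g3"))
  expect_error(rank_genotypes(tab, within = "FD"),
               class = "trichoseg_validation_error")
})

test_that("rank_correlation reproduces closed-form Spearman values", {
  a <- data.frame(genotype = c("w", "x", "y", "z"))
  expect_equal(rank_correlation(a, a), 1.0)
  expect_equal(rank_correlation(a, a[4:1, , drop = FALSE]), -1.0)
  # one adjacent swap on 4 items: 1 - 6*2/(4*15) = 0.8
  b <- data.frame(genotype = c("w", "x", "z", "y"))
  expect_equal(rank_correlation(a, b), 0.8)
  expect_error(rank_correlation(a, data.frame(genotype = c("p", "q"))),
               class = "trichoseg_validation_error")
})
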