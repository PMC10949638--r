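# Quantification: segmentation metrics (IoU, F1), the Leaf Trichome
# Score, batch scoring, aggregation across phenotyping metadata and
# LTS-based genotype ranking.

check_same_shape <- function(p, g) {
  if (!identical(p$shape, g$shape)) {
    stop_trichoseg("mask shapes differ: ",
                   paste(p$shape, collapse = "x"), " vs ",
                   paste(g$shape, collapse = "x"),
                   class = "trichoseg_validation_error")
  }
}

#' Intersection over union of two masks
#'
#' `|P intersect G| / |P union G|` on the foreground pixel sets. When both
#' masks are empty the masks agree perfectly and the IoU is defined as
#' 1.0.
#'
#' @param p,g [sparse_mask()]s of equal shape (prediction, ground truth).
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(p, g) {
  check_same_shape(p, g)
  np <- mask_area(p); ng <- mask_area(g)
  if (np == 0 && ng == 0) return(1.0)
  ni <- length(intersect(mask_keys(p), mask_keys(g)))
  ni / (np + ng - ni)
}

#' F1 score (Dice), precision and recall of a predicted mask
#'
#' `precision = |P ∩ G| / |P|`, `recall = |P ∩ G| / |G|`, F1 their
#' harmonic mean. An empty prediction has precision 0 and an empty ground
#' truth has recall 0 (with a warning); F1 is 0 when precision and recall
#' are both 0.
#'
#' @param p,g [sparse_mask()]s of equal shape.
#' @param warn warn on the degenerate empty-side cases.
#' @return named numeric vector `(f1, precision, recall)`.
#' @export
f1_score <- function(p, g, warn = TRUE) {
  check_same_shape(p, g)
  np <- mask_area(p); ng <- mask_area(g)
  ni <- length(intersect(mask_keys(p), mask_keys(g)))
  if (np == 0 && warn) warning("empty prediction: precision defined as 0",
                               call. = FALSE)
  if (ng == 0 && warn) warning("empty ground truth: recall defined as 0",
                               call. = FALSE)
  precision <- if (np == 0) 0 else ni / np
  recall <- if (ng == 0) 0 else ni / ng
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(f1 = f1, precision = precision, recall = recall)
}

#' Leaf Trichome Score of a segmentation mask
#'
#' `LTS = 1000 * N_S / N_T` where `N_S` is the number of pixels
#' segmented as trichome and `N_T` the total pixel count of the image.
#' The factor 1000 scales the sparse trichome fraction to an
#' interpretable range: 0 (glabrous) up to 1000 (all foreground). LTS is
#' exactly invariant under integer nearest-neighbour upscaling of the
#' mask, so the working resolution is benign for a fixed pipeline.
#'
#' @param m a [sparse_mask()] with positive total pixel count.
#' @return an object of class `lts_result`: `n_fg`, `n_total`, `lts`.
#' @export
lts <- function(m) {
  stopifnot(inherits(m, "sparse_mask"))
  n_total <- as.numeric(m$shape[1]) * m$shape[2]
  if (n_total <= 0) {
    stop_trichoseg("mask has zero total pixel count",
                   class = "trichoseg_validation_error")
  }
  structure(list(n_fg = mask_area(m), n_total = n_total,
                 lts = 1000 * mask_area(m) / n_total),
            class = "lts_result")
}

#' @export
print.lts_result <- function(x, ...) {
  cat(sprintf("<lts_result: %d / %g pixels, LTS = %.4f>\n",
              x$n_fg, x$n_total, x$lts))
  invisible(x)
}

#' Evaluate a model against ground-truth annotations
#'
#' @param model a trained model.
#' @param records list of [annotated_image()] with splines.
#' @param working_size evaluation resolution `(H, W)`; defaults to the
#'   final size of the model's recipe.
#' @param threshold binarization threshold (default from the config).
#' @param stroke_width ground-truth rasterization brush, px.
#' @return data.frame with one row per image (`image_id`, `iou`, `f1`,
#'   `precision`, `recall`) and attribute `means` with the column means.
#' @export
evaluate_segmentation <- function(model, records, working_size = NULL,
                                  threshold = NULL, stroke_width = 2) {
  working_size <- working_size %||%
    (recipe_final_size(model$config$recipe) %||% dim(records[[1]]$pixels)[1:2])
  rows <- lapply(records, function(rec) {
    vp <- prepare_eval_pair(rec, working_size, stroke_width)
    pm <- predict_mask(model, vp$image, threshold)
    f <- f1_score(pm, vp$mask, warn = FALSE)
    data.frame(image_id = rec$meta$image_id, iou = iou(pm, vp$mask),
               f1 = f[["f1"]], precision = f[["precision"]],
               recall = f[["recall"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, -1, drop = FALSE])
  out
}

#' Score a batch of images with the Leaf Trichome Score
#'
#' Each image is resized to the working size, segmented, and its LTS
#' computed at that resolution; phenotyping metadata is copied through.
#' With `oracle = TRUE` the model is bypassed and the rasterized
#' ground-truth annotations are scored instead (human-annotation LTS).
#'
#' @param model a trained model (ignored in oracle mode).
#' @param records list of [annotated_image()].
#' @param working_size `(H, W)` scoring resolution; defaults to the
#'   model recipe's final size (or native size in oracle mode).
#' @param threshold binarization threshold.
#' @param oracle score rasterized ground truth instead of predictions.
#' @param stroke_width rasterization brush for oracle masks, px.
#' @return a `score_table` data.frame: `image_id`, `genotype`, `ghs`,
#'   `leaf`, `environment`, `year`, `position`, `n_fg`, `lts`. Unreadable
#'   records are collected in attribute `failures`, the run continues.
#' @export
score_batch <- function(model = NULL, records, working_size = NULL,
                        threshold = NULL, oracle = FALSE,
                        stroke_width = 2) {
  if (!oracle) stopifnot(inherits(model, "trichoseg_model"))
  working_size <- working_size %||% (
    if (oracle) NULL else recipe_final_size(model$config$recipe))
  rows <- list(); failures <- character(0)
  for (rec in records) {
    res <- tryCatch({
      size <- working_size %||% rec$size
      m <- if (oracle) {
        spl <- lapply(rec$splines, transform_spline, target_size = size)
        rasterize(spl, size, stroke_width)
      } else {
        vp <- prepare_eval_pair(rec, size, stroke_width)
        predict_mask(model, vp$image, threshold)
      }
      sc <- lts(m)
      data.frame(image_id = rec$meta$image_id %||% NA,
                 genotype = rec$meta$genotype %||% NA,
                 ghs = as.character(rec$meta$ghs %||% NA),
                 leaf = rec$meta$leaf %||% NA,
                 environment = rec$meta$environment %||% NA,
                 year = rec$meta$year %||% NA,
                 position = rec$meta$position %||% NA,
                 n_fg = sc$n_fg, lts = sc$lts,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, paste0(rec$meta$image_id %||% "?", ": ", res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(image_id = character(), genotype = character(),
               ghs = character(), leaf = character(),
               environment = character(), year = character(),
               position = character(), n_fg = numeric(), lts = numeric())
  }
  class(out) <- c("score_table", class(out))
  attr(out, "failures") <- failures
  out
}

#' Aggregate LTS scores over metadata groups
#'
#' Arithmetic group means with t-interval 95% confidence bounds (the
#' median is reported alongside); groups of a single image report no sd.
#'
#' @param table a `score_table` from [score_batch()].
#' @param by character vector of grouping columns (e.g. `c("genotype")`,
#'   `c("ghs", "environment")`).
#' @param value column to aggregate (default `"lts"`).
#' @return data.frame with the group keys plus `n`, `mean`, `median`,
#'   `sd`, `ci_lo`, `ci_hi`.
#' @export
aggregate_scores <- function(table, by, value = "lts") {
  missing_keys <- setdiff(c(by, value), names(table))
  if (length(missing_keys) > 0) {
    stop_trichoseg("unknown column(s): ", paste(missing_keys, collapse = ", "),
                   class = "trichoseg_validation_error")
  }
  key <- interaction(table[by], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    v <- table[[value]][key == lv]
    ks <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    half <- if (n >= 2) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    out <- as.data.frame(as.list(stats::setNames(ks, by)),
                         stringsAsFactors = FALSE)
    out$n <- n
    out$mean <- mean(v)
    out$median <- stats::median(v)
    out$sd <- s
    out$ci_lo <- mean(v) - half
    out$ci_hi <- mean(v) + half
    out
  })
  do.call(rbind, rows)
}

#' Flag non-monotone adjacent class means on the ordinal GHS scale
#'
#' The breeder scale is ordinal, but mean LTS need not increase from one
#' class to the next (a dip at class "4" is the canonical example).
#' Returns the adjacent class pairs where the mean decreases.
#'
#' @param table a `score_table` with a `ghs` column.
#' @return data.frame of offending transitions (`from`, `to`,
#'   `mean_from`, `mean_to`); zero rows when means are monotone.
#' @export
flag_ghs_dips <- function(table) {
  ag <- aggregate_scores(table, "ghs")
  ag <- ag[order(match(ag$ghs, ghs_levels())), ]
  n <- nrow(ag)
  if (n < 2) {
    return(data.frame(from = character(), to = character(),
                      mean_from = numeric(), mean_to = numeric()))
  }
  dips <- which(diff(ag$mean) < 0)
  data.frame(from = ag$ghs[dips], to = ag$ghs[dips + 1],
             mean_from = ag$mean[dips], mean_to = ag$mean[dips + 1])
}

#' Rank genotypes by mean LTS within an environment
#'
#' @param table a `score_table`.
#' @param within environment to rank in (`"GH"`, `"FD"`), or NULL for all
#'   rows.
#' @param statistic `"mean"` (default) or `"median"` per-genotype
#'   summary.
#' @return data.frame ordered by ascending summary LTS with columns
#'   `rank`, `genotype`, `mean_lts`, `n`, `ghs`; ties broken by genotype
#'   name (stable across runs).
#' @export
rank_genotypes <- function(table, within = NULL, statistic = "mean") {
  rows <- if (is.null(within)) table else {
    table[table$environment == within, , drop = FALSE]
  }
  if (nrow(rows) == 0) {
    stop_trichoseg("no rows selected",
                   class = "trichoseg_validation_error")
  }
  ag <- aggregate_scores(rows, "genotype")
  stat <- if (statistic == "median") ag$median else ag$mean
  ghs_of <- vapply(ag$genotype, function(g) {
    v <- unique(as.character(rows$ghs[rows$genotype == g]))
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA_character_
  }, character(1))
  o <- order(stat, ag$genotype)
  data.frame(rank = seq_along(o), genotype = ag$genotype[o],
             mean_lts = stat[o], n = ag$n[o], ghs = unname(ghs_of[o]),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation between two rankings
#'
#' Standard Spearman's rho on the rank positions with average ranks for
#' ties.
#'
#' @param ranking_a,ranking_b data.frames with a `genotype` column whose
#'   row order is the ranking (e.g. from [rank_genotypes()]), or named
#'   numeric vectors of scores.
#' @return scalar rho in `[-1, 1]`.
#' @export
rank_correlation <- function(ranking_a, ranking_b) {
  pos <- function(r) {
    if (is.data.frame(r)) {
      stats::setNames(seq_len(nrow(r)), r$genotype)
    } else {
      stats::setNames(rank(r, ties.method = "average"), names(r))
    }
  }
  a <- pos(ranking_a); b <- pos(ranking_b)
  common <- intersect(names(a), names(b))
  if (length(common) == 0 || length(common) < length(a) ||
      length(common) < length(b)) {
    stop_trichoseg("rankings must cover the same item set",
                   class = "trichoseg_validation_error")
  }
  stats::cor(a[common], b[common], method = "spearman")
}
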