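# Binary segmentation losses on probability rasters. Smoothing epsilon of
# 1.0 in the Dice and Jaccard losses; focal gamma = 2, unweighted.

LOSS_EPS <- 1.0
FOCAL_GAMMA <- 2
P_CLAMP <- 1e-7

#' Compute a segmentation loss
#'
#' * `bce`: mean pixelwise binary cross-entropy.
#' * `dice`: `1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, the
#'   soft Sorensen-Dice loss (eps = 1); robust to the heavy
#'   trichome/background class imbalance.
#' * `jaccard`: `1 - (sum(p*g) + eps) / (sum(p) + sum(g) - sum(p*g) + eps)`.
#' * `focal`: mean of `-(1 - p_t)^2 * log(p_t)`, down-weighting easy
#'   pixels.
#'
#' @param pred numeric raster of foreground probabilities in `[0, 1]`.
#' @param target binary raster of the same shape.
#' @param kind one of [loss_names()].
#' @return scalar loss.
#' @export
compute_loss <- function(pred, target, kind = "dice") {
  pred <- as.numeric(pred); target <- as.numeric(target)
  if (length(pred) != length(target)) {
    stop_trichoseg("pred and target shapes differ",
                   class = "trichoseg_validation_error")
  }
  if (any(pred < 0) || any(pred > 1)) {
    stop_trichoseg("pred must lie in [0, 1]",
                   class = "trichoseg_validation_error")
  }
  p <- pmin(pmax(pred, P_CLAMP), 1 - P_CLAMP)
  g <- target
  switch(kind,
    bce = -mean(g * log(p) + (1 - g) * log(1 - p)),
    dice = {
      s <- sum(pred * g)
      1 - (2 * s + LOSS_EPS) / (sum(pred) + sum(g) + LOSS_EPS)
    },
    jaccard = {
      s <- sum(pred * g)
      u <- sum(pred) + sum(g) - s
      1 - (s + LOSS_EPS) / (u + LOSS_EPS)
    },
    focal = {
      pt <- g * p + (1 - g) * (1 - p)
      mean(-(1 - pt)^FOCAL_GAMMA * log(pt))
    },
    stop_trichoseg("unknown loss '", kind, "'; registered losses: ",
                   paste(loss_names(), collapse = ", "),
                   class = "trichoseg_registry_error"))
}

# Analytic gradient of the loss w.r.t. the probability raster; seeds the
# network backward pass.
loss_grad <- function(pred, target, kind = "dice") {
  p <- pmin(pmax(pred, P_CLAMP), 1 - P_CLAMP)
  g <- target
  n <- length(p)
  out <- switch(kind,
    bce = (p - g) / (p * (1 - p)) / n,
    dice = {
      s <- sum(pred * g); den <- sum(pred) + sum(g) + LOSS_EPS
      -(2 * g * den - (2 * s + LOSS_EPS)) / den^2
    },
    jaccard = {
      s <- sum(pred * g); u <- sum(pred) + sum(g) - s + LOSS_EPS
      -(g * u - (s + LOSS_EPS) * (1 - g)) / u^2
    },
    focal = {
      pt <- g * p + (1 - g) * (1 - p)
      dpt <- 2 * (1 - pt) * log(pt) - (1 - pt)^FOCAL_GAMMA / pt
      dpt * (2 * g - 1) / n
    })
  array(out, dim(pred) %||% length(pred))
}
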