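# Paired image/annotation augmentation. Geometry is applied to the spline
# control points and the mask is rasterized once, after all geometric
# steps, at the final resolution ("geometry before raster"): masks are
# never interpolated, which avoids breaking long thin annotations apart or
# merging neighbouring ones -- the artifacts that make mask-space resizing
# unusable for hair-like structures.

#' Parse a compact augmentation recipe string
#'
#' Recipes are '+'-separated tokens: `RS<n>` (bilinear resize of the image
#' to n x n, splines transformed), `RC<n>` (one random n x n crop),
#' `RF` (independent Bernoulli(0.5) vertical and horizontal flips).
#' Examples: `"RS768+RF"`, `"RC1536+RS1024+RF"`. Token order is honoured.
#'
#' @param text recipe string; `""` is the empty (identity) recipe.
#' @return an object of class `augment_recipe`.
#' @export
parse_recipe <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  steps <- list()
  if (nzchar(text)) {
    for (tok in strsplit(text, "+", fixed = TRUE)[[1]]) {
      if (tok == "RF") {
        steps[[length(steps) + 1]] <- list(op = "RF")
      } else if (grepl("^RS[0-9]+$", tok)) {
        n <- as.integer(sub("^RS", "", tok))
        steps[[length(steps) + 1]] <- list(op = "RS", size = c(n, n))
      } else if (grepl("^RC[0-9]+$", tok)) {
        n <- as.integer(sub("^RC", "", tok))
        steps[[length(steps) + 1]] <- list(op = "RC", size = c(n, n))
      } else {
        stop_trichoseg("unknown augmentation token: '", tok, "'",
                       class = "trichoseg_parse_error")
      }
    }
  }
  structure(list(steps = steps, text = text), class = "augment_recipe")
}

#' @export
format.augment_recipe <- function(x, ...) {
  if (length(x$steps) == 0) return("")
  paste(vapply(x$steps, function(s) {
    if (s$op == "RF") "RF" else paste0(s$op, s$size[1])
  }, character(1)), collapse = "+")
}

#' @export
print.augment_recipe <- function(x, ...) {
  cat(sprintf("<augment_recipe '%s'>\n", format(x)))
  invisible(x)
}

flip_image <- function(img, vertical = FALSE, horizontal = FALSE) {
  if (vertical) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (horizontal) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  img
}

# Mirror spline control points; with pixel centers at integers the mirror
# axis is (extent - 1) / 2, so r' = (H - 1) - r.
flip_splines <- function(splines, size, vertical, horizontal) {
  lapply(splines, function(s) {
    p <- s$points
    if (vertical) p[, 1] <- (size[1] - 1) - p[, 1]
    if (horizontal) p[, 2] <- (size[2] - 1) - p[, 2]
    structure(list(points = p, reference_size = as.numeric(size), id = s$id),
              class = "spline_annotation")
  })
}

# Clip splines to a crop window [r0, r0+h) x [c0, c0+w) in continuous
# coordinates: the curve is densely re-sampled, split into maximal inside
# runs, and each run of >= 2 samples becomes a polyline annotation. This
# keeps partial (edge) trichomes, as human annotators do.
crop_splines <- function(splines, r0, c0, size) {
  out <- list()
  for (s in splines) {
    sm <- sample_spline(s)
    rr <- sm[, 1] - r0; cc <- sm[, 2] - c0
    inside <- rr > -0.5 & rr < size[1] - 0.5 & cc > -0.5 & cc < size[2] - 0.5
    if (!any(inside)) next
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    part <- 0
    for (k in seq_along(runs$values)) {
      if (!runs$values[k] || runs$lengths[k] < 2) next
      part <- part + 1
      idx <- seq(starts[k], ends[k])
      # thin the dense samples back to a manageable polyline
      keep <- unique(c(seq(1, length(idx), by = 4), length(idx)))
      pts <- cbind(rr[idx][keep], cc[idx][keep])
      if (nrow(pts) < 2) next
      out[[length(out) + 1]] <- structure(
        list(points = pts, reference_size = as.numeric(size),
             id = if (part == 1) s$id else paste0(s$id, "_", part)),
        class = "spline_annotation")
    }
  }
  out
}

#' Apply an augmentation recipe to an annotated image
#'
#' Steps are applied in token order to the image and the spline
#' annotations jointly; the segmentation mask is rasterized once at the
#' final geometry. `RS` resizes the image bilinearly and transforms the
#' splines (mask interpolation is never used). `RC` picks one crop window
#' uniformly over valid top-left corners; splines are clipped in
#' continuous coordinates, keeping partial trichomes. `RF` applies
#' independent vertical and horizontal coin-flip mirrors to both.
#' Deterministic given `seed`.
#'
#' @param recipe an [augment_recipe()][parse_recipe] or recipe string.
#' @param record an [annotated_image()] with splines at image resolution.
#' @param stroke_width rasterization brush diameter, px.
#' @param seed integer seed for the random steps.
#' @return list with `image` (H x W x 3 array), `mask` (a
#'   [sparse_mask()]), and `splines` (the transformed annotations).
#' @export
apply_recipe <- function(recipe, record, stroke_width = 2, seed = 1L) {
  if (is.character(recipe)) recipe <- parse_recipe(recipe)
  stopifnot(inherits(recipe, "augment_recipe"),
            inherits(record, "annotated_image"))
  img <- record$pixels
  if (is.null(img)) {
    stop_trichoseg("apply_recipe needs pixel data",
                   class = "trichoseg_validation_error")
  }
  splines <- record$splines
  size <- dim(img)[1:2]
  with_seed(seed, {
    for (st in recipe$steps) {
      if (st$op == "RS") {
        img <- resize_bilinear(img, st$size)
        splines <- lapply(splines, transform_spline,
                          target_size = st$size)
        size <- st$size
      } else if (st$op == "RC") {
        if (st$size[1] > size[1] || st$size[2] > size[2]) {
          stop_trichoseg("RC", st$size[1], " crop exceeds current image ",
                         "size ", size[1], "x", size[2],
                         class = "trichoseg_validation_error")
        }
        r0 <- sample.int(size[1] - st$size[1] + 1L, 1) - 1L
        c0 <- sample.int(size[2] - st$size[2] + 1L, 1) - 1L
        img <- img[r0 + seq_len(st$size[1]), c0 + seq_len(st$size[2]), ,
                   drop = FALSE]
        splines <- crop_splines(splines, r0, c0, st$size)
        size <- st$size
      } else if (st$op == "RF") {
        fv <- runif(1) < 0.5
        fh <- runif(1) < 0.5
        img <- flip_image(img, fv, fh)
        splines <- flip_splines(splines, size, fv, fh)
      }
    }
    list(image = img,
         mask = rasterize(splines, size, stroke_width = stroke_width),
         splines = splines)
  })
}
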