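# Core annotation data model: spline trichome annotations, sparse binary
# masks, the ordinal genotype hairiness scale, and annotated image records.

#' The genotype hairiness score (GHS) scale
#'
#' Ordinal categories used by breeders to score leaf hairiness, from
#' glabrous ("1") to pilose ("5+"). The scale is non-linear: no arithmetic
#' is ever performed on labels, only ordering.
#'
#' @return character vector of the nine ordered levels.
#' @export
ghs_levels <- function() c("1", "2", "3", "3/4", "4", "4/4+", "4+", "5", "5+")

#' Construct a GHS label
#'
#' @param value character scalar (or vector), one of [ghs_levels()].
#' @return an ordered factor on the GHS scale.
#' @export
ghs_label <- function(value) {
  value <- as.character(value)
  bad <- setdiff(value[!is.na(value)], ghs_levels())
  if (length(bad) > 0) {
    stop_trichoseg("unknown GHS label(s): ", paste(bad, collapse = ", "),
                   class = "trichoseg_validation_error")
  }
  factor(value, levels = ghs_levels(), ordered = TRUE)
}

#' A trichome annotated as an ordered set of spline control points
#'
#' Control points are continuous 0-based `(row, col)` coordinates placed by
#' an annotator along one trichome, interpreted at a reference image
#' resolution. Points may lie up to `tol` (default 5%) outside the image:
#' trichomes crossing the image border are annotated past the edge and the
#' rasterizer clips.
#'
#' @param points numeric n x 2 matrix of (row, col) control points, n >= 2.
#' @param reference_size integer `(H, W)` the coordinates refer to.
#' @param id opaque annotation identifier.
#' @param tol allowed out-of-bounds fraction of the image extent.
#' @return an object of class `spline_annotation`.
#' @export
spline_annotation <- function(points, reference_size, id = "",
                              tol = 0.05) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2 || nrow(points) < 2) {
    stop_trichoseg("a spline needs an n x 2 numeric matrix with >= 2 ",
                   "control points (annotation '", id, "')",
                   class = "trichoseg_validation_error")
  }
  reference_size <- as.numeric(reference_size)
  if (length(reference_size) != 2 || any(reference_size <= 0)) {
    stop_trichoseg("reference_size must be two positive extents",
                   class = "trichoseg_validation_error")
  }
  H <- reference_size[1]; W <- reference_size[2]
  if (any(points[, 1] < -tol * H) || any(points[, 1] > (1 + tol) * H) ||
      any(points[, 2] < -tol * W) || any(points[, 2] > (1 + tol) * W)) {
    stop_trichoseg("control points of annotation '", id, "' lie more than ",
                   round(tol * 100), "% outside the reference image",
                   class = "trichoseg_validation_error")
  }
  structure(
    list(points = unname(points), reference_size = reference_size, id = id),
    class = "spline_annotation")
}

#' @export
print.spline_annotation <- function(x, ...) {
  cat(sprintf("<spline_annotation '%s': %d control points at %g x %g>\n",
              x$id, nrow(x$points), x$reference_size[1], x$reference_size[2]))
  invisible(x)
}

#' Rescale a spline annotation to a new image resolution
#'
#' Each control point is scaled per axis by the ratio of the target to the
#' reference extent; the shape of the interpolated curve is preserved at
#' any resolution (that is the point of storing splines, not masks).
#'
#' @param s a [spline_annotation()].
#' @param target_size `(H', W')` positive extents.
#' @return the transformed `spline_annotation` with
#'   `reference_size == target_size`.
#' @export
transform_spline <- function(s, target_size) {
  stopifnot(inherits(s, "spline_annotation"))
  target_size <- as.numeric(target_size)
  if (length(target_size) != 2 || any(target_size <= 0)) {
    stop_trichoseg("target_size must be two positive extents",
                   class = "trichoseg_validation_error")
  }
  sc <- target_size / s$reference_size
  pts <- cbind(s$points[, 1] * sc[1], s$points[, 2] * sc[2])
  structure(list(points = pts, reference_size = target_size, id = s$id),
            class = "spline_annotation")
}

#' Sparse binary segmentation mask
#'
#' Trichome masks are overwhelmingly background, so only the (row, col)
#' indices of foreground pixels are stored. Indices are 0-based to match
#' the continuous annotation coordinates; [sparse_decode()] converts to a
#' dense 0/1 matrix.
#'
#' @param shape integer `(H, W)`.
#' @param foreground integer n x 2 matrix of 0-based (row, col) foreground
#'   pixel indices; duplicates are removed.
#' @return an object of class `sparse_mask`.
#' @export
sparse_mask <- function(shape, foreground = matrix(integer(), 0, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape <= 0)) {
    stop_trichoseg("mask shape must be two positive extents",
                   class = "trichoseg_validation_error")
  }
  fg <- matrix(as.integer(foreground), ncol = 2)
  if (nrow(fg) > 0) {
    if (any(fg[, 1] < 0) || any(fg[, 1] >= shape[1]) ||
        any(fg[, 2] < 0) || any(fg[, 2] >= shape[2])) {
      stop_trichoseg("foreground indices out of bounds for ",
                     shape[1], " x ", shape[2], " mask",
                     class = "trichoseg_validation_error")
    }
    fg <- fg[!duplicated(fg[, 1] + as.numeric(shape[1]) * fg[, 2]), ,
             drop = FALSE]
    o <- order(fg[, 2], fg[, 1])
    fg <- fg[o, , drop = FALSE]
  }
  structure(list(shape = shape, foreground = fg), class = "sparse_mask")
}

#' @export
print.sparse_mask <- function(x, ...) {
  cat(sprintf("<sparse_mask %d x %d: %d foreground pixels>\n",
              x$shape[1], x$shape[2], nrow(x$foreground)))
  invisible(x)
}

#' Encode a dense binary raster as a sparse mask
#'
#' @param dense numeric/logical H x W matrix with values in {0, 1}.
#' @return a [sparse_mask()]; `sparse_decode(sparse_encode(x))` is the
#'   identity for every binary raster.
#' @export
sparse_encode <- function(dense) {
  dense <- as.matrix(dense)
  v <- as.numeric(dense)
  if (!all(v %in% c(0, 1))) {
    stop_trichoseg("sparse_encode expects a 0/1 raster",
                   class = "trichoseg_validation_error")
  }
  idx <- which(dense != 0, arr.ind = TRUE)
  sparse_mask(dim(dense), cbind(idx[, 1] - 1L, idx[, 2] - 1L))
}

#' Decode a sparse mask to a dense 0/1 matrix
#'
#' @param m a [sparse_mask()].
#' @return integer H x W matrix of 0/1.
#' @export
sparse_decode <- function(m) {
  stopifnot(inherits(m, "sparse_mask"))
  out <- matrix(0L, m$shape[1], m$shape[2])
  if (nrow(m$foreground) > 0) {
    out[m$foreground[, 1] + 1L +
          as.numeric(m$shape[1]) * m$foreground[, 2]] <- 1L
  }
  out
}

# Number of foreground pixels.
mask_area <- function(m) nrow(m$foreground)

# 0-based linear keys of the foreground set (row + H * col).
mask_keys <- function(m) {
  if (nrow(m$foreground) == 0) return(numeric(0))
  m$foreground[, 1] + as.numeric(m$shape[1]) * m$foreground[, 2]
}

#' Flip a sparse mask vertically and/or horizontally
#'
#' @param m a [sparse_mask()].
#' @param vertical,horizontal flip rows / columns.
#' @return the flipped `sparse_mask`.
#' @export
flip_mask <- function(m, vertical = FALSE, horizontal = FALSE) {
  fg <- m$foreground
  if (nrow(fg) > 0) {
    if (vertical) fg[, 1] <- m$shape[1] - 1L - fg[, 1]
    if (horizontal) fg[, 2] <- m$shape[2] - 1L - fg[, 2]
  }
  sparse_mask(m$shape, fg)
}

#' An image together with its trichome annotations and metadata
#'
#' @param pixels H x W x 3 numeric array in `[0, 1]` (RGB), or NULL for
#'   annotation-only records.
#' @param splines list of [spline_annotation()]s, all with
#'   `reference_size == dim(pixels)[1:2]`.
#' @param meta named list of phenotyping metadata: `genotype`, `ghs`
#'   (a GHS label or NA), `leaf` ("L3"/"L4"), `environment` ("GH"/"FD"),
#'   `year`, `position` ("First"/"Middle"/"Last"/"Blade"), `image_id`.
#' @param size `(H, W)`; required if `pixels` is NULL.
#' @return an object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, splines = list(), meta = list(),
                            size = NULL) {
  if (!is.null(pixels)) {
    stopifnot(is.numeric(pixels), length(dim(pixels)) == 3)
    size <- dim(pixels)[1:2]
  } else if (is.null(size)) {
    stop_trichoseg("annotation-only records need an explicit size",
                   class = "trichoseg_validation_error")
  }
  size <- as.integer(size)
  for (s in splines) {
    stopifnot(inherits(s, "spline_annotation"))
    if (!isTRUE(all(abs(s$reference_size - size) < 1e-9))) {
      stop_trichoseg("spline '", s$id, "' has reference_size ",
                     paste(s$reference_size, collapse = "x"),
                     " but the image is ", paste(size, collapse = "x"),
                     class = "trichoseg_validation_error")
    }
  }
  defaults <- list(genotype = NA_character_, ghs = NA_character_,
                   leaf = NA_character_, environment = NA_character_,
                   year = NA_character_, position = NA_character_,
                   image_id = NA_character_)
  meta <- utils::modifyList(defaults, meta[!vapply(meta, is.null, TRUE)])
  structure(list(pixels = pixels, splines = splines, meta = meta,
                 size = size),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %s: %d x %d, %d splines, genotype=%s>\n",
              x$meta$image_id, x$size[1], x$size[2], length(x$splines),
              x$meta$genotype))
  invisible(x)
}
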