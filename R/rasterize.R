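# Spline rasterization: centripetal Catmull-Rom interpolation through the
# annotator-placed control points, dense sampling (>= 2 samples per pixel
# of arc length), nearest-pixel rounding and a disc brush of diameter
# stroke_width. Deterministic.

# Evaluate one centripetal Catmull-Rom segment (Barry-Goldman pyramid)
# for parameter values tq in [t2, t3]. p0..p3 are length-2 points.
cr_segment <- function(p0, p1, p2, p3, n_samples, alpha = 0.5) {
  knot <- function(ti, pa, pb) ti + sum((pb - pa)^2)^(alpha / 2)
  t0 <- 0
  t1 <- knot(t0, p0, p1)
  t2 <- knot(t1, p1, p2)
  t3 <- knot(t2, p2, p3)
  # Degenerate spacings (coincident points) fall back to uniform knots.
  if (t1 - t0 < 1e-12 || t2 - t1 < 1e-12 || t3 - t2 < 1e-12) {
    t0 <- 0; t1 <- 1; t2 <- 2; t3 <- 3
  }
  # the curve between the two inner control points spans t in [t1, t2]
  tq <- seq(t1, t2, length.out = n_samples)
  lerp <- function(a, b, ta, tb) {
    w <- (tq - ta) / (tb - ta)
    cbind(a[, 1] * (1 - w) + b[, 1] * w, a[, 2] * (1 - w) + b[, 2] * w)
  }
  rep_pt <- function(p) matrix(p, n_samples, 2, byrow = TRUE)
  a1 <- lerp(rep_pt(p0), rep_pt(p1), t0, t1)
  a2 <- lerp(rep_pt(p1), rep_pt(p2), t1, t2)
  a3 <- lerp(rep_pt(p2), rep_pt(p3), t2, t3)
  b1 <- lerp(a1, a2, t0, t2)
  b2 <- lerp(a2, a3, t1, t3)
  lerp(b1, b2, t1, t2)
}

#' Densely sample the interpolated curve of a spline annotation
#'
#' Centripetal Catmull-Rom interpolation through the control points
#' (passes through every point, no overshoot); two control points give the
#' straight segment between them. End segments use reflected phantom
#' points. At least `samples_per_px` samples per pixel of arc length.
#'
#' @param s a [spline_annotation()].
#' @param samples_per_px sampling density along the curve.
#' @return m x 2 matrix of continuous (row, col) samples.
#' @export
sample_spline <- function(s, samples_per_px = 2) {
  pts <- s$points
  # collapse exactly repeated consecutive control points
  if (nrow(pts) > 2) {
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n < 2) return(pts)
  seg_len <- sqrt(rowSums(diff(pts)^2))
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    p1 <- pts[i, ]; p2 <- pts[i + 1, ]
    p0 <- if (i > 1) pts[i - 1, ] else 2 * p1 - p2
    p3 <- if (i + 2 <= n) pts[i + 2, ] else 2 * p2 - p1
    m <- max(2L, ceiling(samples_per_px * 1.5 * seg_len[i]) + 1L)
    seg <- cr_segment(p0, p1, p2, p3, m)
    out[[i]] <- if (i < n - 1) seg[-m, , drop = FALSE] else seg
  }
  do.call(rbind, out)
}

#' Rasterize spline annotations into a sparse binary mask
#'
#' The union over splines of the interpolated curve drawn with a disc
#' brush of diameter `stroke_width` pixels, rounded to the nearest pixel
#' and clipped to the mask bounds. Two identical splines produce the same
#' mask as one (set union); an empty spline list is an empty mask.
#'
#' @param splines list of [spline_annotation()]s already transformed to
#'   `size`.
#' @param size `(H, W)` of the output mask.
#' @param stroke_width brush diameter in pixels (>= 1); the default 2 px
#'   matches trichomes that are one or two pixels wide at the working
#'   resolution.
#' @return a [sparse_mask()].
#' @export
rasterize <- function(splines, size, stroke_width = 2) {
  size <- as.integer(size)
  stopifnot(length(size) == 2, all(size > 0), stroke_width >= 1)
  if (length(splines) == 0) return(sparse_mask(size))
  H <- size[1]; W <- size[2]
  rad <- stroke_width / 2
  k <- ceiling(rad)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  keys <- numeric(0)
  for (s in splines) {
    if (!isTRUE(all(abs(s$reference_size - size) < 1e-9))) {
      stop_trichoseg("spline '", s$id, "' must be transformed to the mask ",
                     "size before rasterization",
                     class = "trichoseg_validation_error")
    }
    sm <- sample_spline(s)
    # a pixel is painted when its center lies within rad of a curve
    # sample (subpixel-aware disc, so the drawn width tracks
    # stroke_width); the nearest pixel to every sample is always painted
    # to keep single-pixel strokes connected
    rr <- round(sm[, 1]); cc <- round(sm[, 2])
    fr <- rr - sm[, 1]; fc <- cc - sm[, 2]
    n_off <- nrow(off)
    rr2 <- rep(off$dr, times = length(rr)) + rep(rr, each = n_off)
    cc2 <- rep(off$dc, times = length(cc)) + rep(cc, each = n_off)
    d2 <- (rep(off$dr, times = length(rr)) + rep(fr, each = n_off))^2 +
      (rep(off$dc, times = length(cc)) + rep(fc, each = n_off))^2
    center <- rep(off$dr == 0 & off$dc == 0, times = length(rr))
    ok <- (d2 <= rad^2 + 1e-9 | center) &
      rr2 >= 0 & rr2 < H & cc2 >= 0 & cc2 < W
    keys <- c(keys, unique(rr2[ok] + as.numeric(H) * cc2[ok]))
  }
  keys <- unique(keys)
  sparse_mask(size, cbind(as.integer(keys %% H), as.integer(keys %/% H)))
}

#' Count 8-connected foreground components of a sparse mask
#'
#' Used to detect the "broken hair" artifact of mask-space resizing: a
#' long thin annotation that interpolation breaks into pieces shows up as
#' extra components.
#'
#' @param m a [sparse_mask()].
#' @return integer component count.
#' @export
mask_components <- function(m) {
  stopifnot(inherits(m, "sparse_mask"))
  n <- nrow(m$foreground)
  if (n == 0) return(0L)
  H <- as.numeric(m$shape[1])
  keys <- m$foreground[, 1] + (H + 2) * m$foreground[, 2]
  ord <- order(keys)
  keys <- keys[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- c(-1, 1, -(H + 2), (H + 2), -(H + 2) - 1, -(H + 2) + 1,
            (H + 2) - 1, (H + 2) + 1)
  for (d in offs) {
    j <- match(keys + d, keys)
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
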