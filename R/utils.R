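# Shared internal helpers: seed derivation, local RNG scoping, image
# resampling. Coordinate convention (used package-wide, stated once):
# continuous (row, col) coordinates are 0-based with pixel centers at
# integer positions, so pixel (0,0) of an H x W raster covers the unit
# square centered at (0, 0) and valid centers span [0, H-1] x [0, W-1].
# Scaling an annotation from size (H, W) to (H', W') multiplies rows by
# H'/H and cols by W'/W. Rasterization rounds to the nearest integer
# (half-to-even, as base round()) and clips to bounds.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and arbitrary labels
#'
#' Splitmix-style integer hashing so that per-image / per-cell seed streams
#' are independent of generation order. All arithmetic stays below 2^31.
#'
#' @param seed integer parent seed.
#' @param ... further components (numbers or strings) identifying the child
#'   stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  comps <- list(...)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  mix <- function(h, x) {
    # 16807 is the Lehmer multiplier; keep products < 2^53 by splitting.
    x <- as.numeric(x) %% m
    h <- (h * 48271 + x + 11) %% m
    h <- (h * 16807 + 2531011) %% m
    h
  }
  for (cm in comps) {
    if (is.character(cm)) {
      for (code in utf8ToInt(paste(cm, collapse = "\x1f"))) h <- mix(h, code)
    } else {
      for (v in as.numeric(cm)) h <- mix(h, floor(v * 1021) %% m)
    }
  }
  as.integer(h %% (m - 1))
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Bilinear resize of an H x W (x C) numeric array to target (Ht, Wt).
# Inverse mapping r_src = r_dst * H / Ht keeps image resizing consistent
# with the multiplicative spline transform.
resize_bilinear <- function(img, target_size) {
  d <- dim(img)
  if (length(d) == 2L) img <- array(img, c(d, 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  Ht <- as.integer(target_size[1]); Wt <- as.integer(target_size[2])
  rs <- (seq_len(Ht) - 1) * H / Ht
  cs <- (seq_len(Wt) - 1) * W / Wt
  r0 <- pmin(pmax(floor(rs), 0), H - 1); r1 <- pmin(r0 + 1, H - 1)
  c0 <- pmin(pmax(floor(cs), 0), W - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- rs - floor(rs); fc <- cs - floor(cs)
  out <- array(0, c(Ht, Wt, C))
  for (ch in seq_len(C)) {
    m <- img[, , ch]
    a <- m[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - fr, 1 - fc) +
      m[r1 + 1, c0 + 1, drop = FALSE] * outer(fr, 1 - fc) +
      m[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - fr, fc) +
      m[r1 + 1, c1 + 1, drop = FALSE] * outer(fr, fc)
    out[, , ch] <- a
  }
  if (length(d) == 2L) out[, , 1] else out
}

# Nearest-neighbour resize (used as the deliberately artifact-prone mask
# oracle in tests and never in the main pipeline).
resize_nearest <- function(img, target_size) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  Ht <- as.integer(target_size[1]); Wt <- as.integer(target_size[2])
  ri <- pmin(pmax(round((seq_len(Ht) - 1) * H / Ht), 0), H - 1) + 1
  ci <- pmin(pmax(round((seq_len(Wt) - 1) * W / Wt), 0), W - 1) + 1
  if (length(d) == 2L) img[ri, ci] else img[ri, ci, , drop = FALSE]
}

# 2x box downsample of a matrix (average of 2x2 blocks).
box_downsample2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
      m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
}

stop_trichoseg <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "trichoseg_error")))
}
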