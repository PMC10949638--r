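# Procedural generator of leaf-like images with exact ground-truth
# trichome splines. Emulates the statistical structure of annotated leaf
# microscopy: a green textured background with radial vignetting, a bright
# horizontal midvein band spanning the image left to right, and thin
# bright curvilinear hairs whose count/length/width/curvature follow
# configurable per-genotype distributions. Hairs are brighter than the
# background (white trichomes on a green leaf).

#' Specification of a synthetic leaf image distribution
#'
#' Defaults are sized for desk scale (256 x 256 px) so that a training
#' epoch takes seconds on one CPU; full-size 2560 x 1920 generation is
#' supported by passing `image_size`.
#'
#' @param image_size `(H, W)` in pixels.
#' @param hair_count list `(mean, dispersion)`: per-image trichome count,
#'   negative binomial with that mean and size (dispersion) parameter;
#'   `dispersion = Inf` gives Poisson counts.
#' @param hair_length_px list `(mean, sd)`: gamma-distributed hair length.
#' @param hair_width_px list `(mean, sd)`: drawn hair stroke width
#'   (clamped to >= 1 px).
#' @param curvature maximum perpendicular deviation of the hair curve as a
#'   fraction of its length.
#' @param midvein list `(center, halfwidth, brightness)`: the bright band
#'   crossing the image horizontally, centered at `center` (fraction of
#'   the height), `halfwidth` px wide, additive `brightness`.
#' @param background list `(base, noise_sd, vignette)`: base RGB triple,
#'   Gaussian texture noise sd, radial vignette strength.
#' @param hair_brightness additive RGB delta of hair pixels.
#' @param seed default generation seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(256, 256),
                           hair_count = list(mean = 40, dispersion = 8),
                           hair_length_px = list(mean = 48, sd = 16),
                           hair_width_px = list(mean = 1.6, sd = 0.4),
                           curvature = 0.15,
                           midvein = list(center = 0.5, halfwidth = 9,
                                          brightness = 0.30),
                           background = list(base = c(0.36, 0.47, 0.28),
                                             noise_sd = 0.03,
                                             vignette = 0.12),
                           hair_brightness = c(0.27, 0.27, 0.24),
                           seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            hair_count$mean >= 0, hair_length_px$mean > 0,
            hair_width_px$mean > 0, curvature >= 0)
  structure(list(image_size = as.integer(image_size),
                 hair_count = hair_count,
                 hair_length_px = hair_length_px,
                 hair_width_px = hair_width_px,
                 curvature = curvature, midvein = midvein,
                 background = background,
                 hair_brightness = hair_brightness,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' A named synthetic genotype: a spec plus its nominal hairiness class
#'
#' @param name genotype name (distinct within a panel).
#' @param spec a [synthetic_spec()].
#' @param nominal_class GHS label the genotype is meant to emulate.
#' @return an object of class `synthetic_genotype`.
#' @export
synthetic_genotype <- function(name, spec, nominal_class = NA) {
  stopifnot(is.character(name), nchar(name) > 0,
            inherits(spec, "synthetic_spec"))
  if (!is.na(nominal_class)) nominal_class <- as.character(nominal_class)
  structure(list(name = name, spec = spec,
                 nominal_class = nominal_class),
            class = "synthetic_genotype")
}

# Separable box blur (k x k, k odd) with edge replication, via padded
# cumulative sums.
box_blur <- function(m, k = 3) {
  h <- (k - 1) / 2
  if (h == 0) return(m)
  blur_vertical <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[rep(1, h), , drop = FALSE], x,
                x[rep(n, h), , drop = FALSE])
    cs <- rbind(0, apply(xp, 2, cumsum))
    (cs[(k + 1):(k + n), , drop = FALSE] -
        cs[seq_len(n), , drop = FALSE]) / k
  }
  t(blur_vertical(t(blur_vertical(m))))
}

rnb <- function(n, mean, dispersion) {
  if (mean <= 0) return(rep(0L, n))
  if (!is.finite(dispersion)) return(stats::rpois(n, mean))
  stats::rnbinom(n, mu = mean, size = dispersion)
}

rgamma_ms <- function(n, mean, sd) {
  if (sd <= 1e-9) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

# Sample control points for one hair: endpoints uniform, interior points
# displaced perpendicular to the chord by <= curvature * length.
sample_hair <- function(H, W, len, curvature, midvein_rows, tries = 25) {
  for (t in seq_len(tries)) {
    a <- c(runif(1, 0, H - 1), runif(1, 0, W - 1))
    th <- runif(1, 0, 2 * pi)
    d <- c(cos(th), sin(th))
    b <- a + len * d
    # prefer hairs whose full length fits the image; after half the tries
    # accept edge hairs and truncate them at the 4% margin
    if (t <= tries / 2 &&
        (b[1] < 0 || b[1] > H - 1 || b[2] < 0 || b[2] > W - 1)) next
    b[1] <- min(max(b[1], -0.04 * H), 1.04 * H - 1)
    b[2] <- min(max(b[2], -0.04 * W), 1.04 * W - 1)
    perp <- c(-d[2], d[1])
    ts <- c(0, 1 / 3, 2 / 3, 1)
    dev <- runif(1, -1, 1) * curvature * len
    offs <- dev * sin(pi * ts)
    pts <- cbind(a[1] + ts * (b[1] - a[1]) + offs * perp[1],
                 a[2] + ts * (b[2] - a[2]) + offs * perp[2])
    # curvature displacement must not push control points past the
    # annotation model's out-of-bounds tolerance
    pts[, 1] <- pmin(pmax(pts[, 1], -0.045 * H), 1.045 * H - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], -0.045 * W), 1.045 * W - 1)
    inside_vein <- all(pts[, 1] >= midvein_rows[1] &
                         pts[, 1] <= midvein_rows[2])
    if (!inside_vein) return(pts)
  }
  NULL
}

#' Generate one synthetic leaf image with ground-truth trichome splines
#'
#' Deterministic given `(spec, seed)`. No generated hair lies wholly
#' within the midvein band, mirroring the annotation convention that
#' trichomes fully overlapping the (white) midvein are not traced.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param meta metadata list copied into the record (genotype, ghs, ...).
#' @return an [annotated_image()] whose `splines` are the exact generating
#'   curves.
#' @export
generate_image <- function(spec, seed = spec$seed, meta = list()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(seed, {
    bg <- spec$background
    rr <- matrix(seq_len(H) - 1, H, W)
    cc <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    # radial vignette, dark corners
    d2 <- ((rr - (H - 1) / 2) / (H / 2))^2 + ((cc - (W - 1) / 2) / (W / 2))^2
    vign <- 1 - bg$vignette * d2 / 2
    # low-frequency blotch + fine grain
    blotch <- box_blur(matrix(rnorm(H * W, 0, bg$noise_sd * 4), H, W),
                       k = 2 * floor(min(H, W) / 32) + 1)
    grain <- matrix(rnorm(H * W, 0, bg$noise_sd), H, W)
    lum <- vign + blotch + grain
    # midvein band with soft plateau profile
    mv <- spec$midvein
    center <- mv$center * (H - 1)
    prof <- mv$brightness / (1 + ((rr - center) / mv$halfwidth)^4)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- bg$base[ch] * lum + prof
    # hairs
    n_hairs <- rnb(1, spec$hair_count$mean, spec$hair_count$dispersion)
    splines <- list()
    strokes <- list()
    if (n_hairs > 0) {
      lens <- pmax(4, rgamma_ms(n_hairs, spec$hair_length_px$mean,
                                spec$hair_length_px$sd))
      wids <- pmax(1, rgamma_ms(n_hairs, spec$hair_width_px$mean,
                                spec$hair_width_px$sd))
      vein_rows <- c(center - mv$halfwidth, center + mv$halfwidth)
      for (i in seq_len(n_hairs)) {
        pts <- sample_hair(H, W, lens[i], spec$curvature, vein_rows)
        if (is.null(pts)) next
        sp <- spline_annotation(pts, c(H, W),
                                id = sprintf("hair_%04d", i))
        splines[[length(splines) + 1]] <- sp
        strokes[[length(strokes) + 1]] <- wids[i]
      }
      # randomized draw order (painter order; additive so cosmetic only)
      ord <- sample.int(length(splines))
      gain <- runif(length(splines), 0.8, 1.15)
      for (i in ord) {
        hm <- rasterize(list(splines[[i]]), c(H, W),
                        stroke_width = strokes[[i]])
        idx <- hm$foreground[, 1] + 1L + H * hm$foreground[, 2]
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[idx] <- pl[idx] + spec$hair_brightness[ch] * gain[i]
          img[, , ch] <- pl
        }
      }
    }
    # mild blur for antialiasing, then clamp
    for (ch in 1:3) img[, , ch] <- box_blur(img[, , ch], 3)
    img <- pmin(pmax(img, 0), 1)
    meta$image_id <- meta$image_id %||% sprintf("synthetic_%08d.png", seed)
    annotated_image(img, splines, meta)
  })
}

#' Generate a panel of synthetic genotypes
#'
#' Per-image seeds are derived by hashing `(seed, genotype name, image
#' index)`, so each image is deterministic independently of generation
#' order. Metadata carries the genotype name and its nominal GHS class.
#'
#' @param genotypes list of [synthetic_genotype()] (distinct names).
#' @param images_per_genotype images per genotype (>= 1).
#' @param seed panel seed.
#' @param meta extra metadata applied to every record (e.g.
#'   `list(environment = "GH", leaf = "L3")`).
#' @return list of [annotated_image()] records, writable with
#'   [write_annotations()].
#' @export
generate_panel <- function(genotypes, images_per_genotype, seed = 1L,
                           meta = list()) {
  stopifnot(images_per_genotype >= 1)
  nms <- vapply(genotypes, function(g) g$name, character(1))
  if (anyDuplicated(nms)) {
    stop_trichoseg("genotype names must be distinct within a panel",
                   class = "trichoseg_validation_error")
  }
  records <- list()
  for (g in genotypes) {
    for (i in seq_len(images_per_genotype)) {
      m <- meta
      m$genotype <- g$name
      m$ghs <- g$nominal_class
      m$image_id <- sprintf("%s_%03d.png", g$name, i)
      records[[length(records) + 1]] <-
        generate_image(g$spec, derive_seed(seed, g$name, i), meta = m)
    }
  }
  records
}

#' A standard five-genotype synthetic panel spanning the density range
#'
#' Hair-count means 0, 15, 35, 70 and 110 with nominal classes "1", "3",
#' "4", "4+" and "5"; all other parameters at [synthetic_spec()] defaults.
#'
#' @param image_size passed to [synthetic_spec()].
#' @return list of [synthetic_genotype()].
#' @export
default_panel <- function(image_size = c(256, 256)) {
  means <- c(0, 15, 35, 70, 110)
  classes <- c("1", "3", "4", "4+", "5")
  names <- c("glabrous", "mild", "mid", "hairy", "pilose")
  Map(function(nm, mu, cl) {
    synthetic_genotype(nm, synthetic_spec(
      image_size = image_size,
      hair_count = list(mean = mu, dispersion = 8)), cl)
  }, names, means, classes)
}

#' Read / write a synthetic panel specification as YAML
#'
#' @param path YAML file with fields `genotypes:` (list of name /
#'   nominal_class / spec overrides) and optional `images_per_genotype`,
#'   `seed`.
#' @return list with `genotypes`, `images_per_genotype`, `seed`.
#' @export
read_panel_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$genotypes)) {
    stop_trichoseg("panel YAML needs a 'genotypes' list",
                   class = "trichoseg_io_error")
  }
  genotypes <- lapply(doc$genotypes, function(g) {
    spec_args <- g$spec %||% list()
    if (!is.null(doc$image_size)) {
      spec_args$image_size <- spec_args$image_size %||% doc$image_size
    }
    synthetic_genotype(g$name, do.call(synthetic_spec, spec_args),
                       g$nominal_class %||% NA)
  })
  list(genotypes = genotypes,
       images_per_genotype = doc$images_per_genotype %||% 4L,
       seed = doc$seed %||% 1L)
}
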