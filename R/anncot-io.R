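# Dataset I/O: the JSON annotation dialect, PNG images, sparse-mask CSV
# files, and descriptors of the deposited cotton leaf datasets.

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop_trichoseg("reading JPEG needs the 'jpeg' package",
                       class = "trichoseg_io_error")
      }
      jpeg::readJPEG(path)
    },
    stop_trichoseg("unsupported image format: .", ext,
                   class = "trichoseg_io_error"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

write_image_file <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
}

#' Read an annotated image dataset
#'
#' Expects a directory of images plus a JSON annotation file in the
#' package dialect:
#' `{"images": [{"file", "height", "width", "meta": {...},`
#' `"splines": [{"id", "points": [[row, col], ...]}]}]}`.
#' Image files present in the directory but absent from the JSON become
#' records with empty spline lists.
#'
#' @param path directory containing images and `annotations.json`, or the
#'   path of the JSON file itself.
#' @param read_pixels if FALSE, only sizes and annotations are loaded.
#' @return list of [annotated_image()] records.
#' @export
read_annotations <- function(path, read_pixels = TRUE) {
  if (dir.exists(path)) {
    json_path <- file.path(path, "annotations.json")
    if (!file.exists(json_path)) {
      cand <- list.files(path, pattern = "\\.json$", full.names = TRUE)
      if (length(cand) != 1) {
        stop_trichoseg("no unambiguous annotation JSON in ", path,
                       class = "trichoseg_io_error")
      }
      json_path <- cand
    }
    dir <- path
  } else {
    json_path <- path
    dir <- dirname(path)
  }
  doc <- tryCatch(
    jsonlite::fromJSON(json_path, simplifyVector = FALSE),
    error = function(e) {
      stop_trichoseg("malformed annotation JSON '", json_path, "': ",
                     conditionMessage(e), class = "trichoseg_io_error")
    })
  if (is.null(doc$images)) {
    stop_trichoseg("annotation JSON '", json_path,
                   "' has no top-level \"images\" array",
                   class = "trichoseg_io_error")
  }
  records <- list()
  seen <- character(0)
  for (rec in doc$images) {
    fn <- rec$file %||% stop_trichoseg(
      "annotation record without \"file\" field",
      class = "trichoseg_io_error")
    fp <- file.path(dir, fn)
    if (!file.exists(fp)) {
      stop_trichoseg("annotation references missing image file: ", fn,
                     class = "trichoseg_io_error")
    }
    ref <- c(rec$height, rec$width)
    pixels <- NULL
    if (read_pixels) {
      pixels <- read_image_file(fp)
      if (!identical(as.integer(dim(pixels)[1:2]), as.integer(ref))) {
        stop_trichoseg("record '", fn, "': annotation reference_size ",
                       paste(ref, collapse = "x"), " differs from image ",
                       paste(dim(pixels)[1:2], collapse = "x"),
                       class = "trichoseg_validation_error")
      }
    }
    splines <- lapply(rec$splines, function(sp) {
      pts <- do.call(rbind, lapply(sp$points, unlist))
      if (is.null(pts) || nrow(pts) < 2) {
        stop_trichoseg("record '", fn, "', spline '", sp$id %||% "?",
                       "': fewer than 2 control points",
                       class = "trichoseg_validation_error")
      }
      spline_annotation(pts, ref, id = sp$id %||% "")
    })
    meta <- lapply(rec$meta %||% list(), function(v) v)
    meta$image_id <- meta$image_id %||% fn
    records[[length(records) + 1]] <-
      annotated_image(pixels, splines, meta, size = ref)
    seen <- c(seen, fn)
  }
  extra <- setdiff(list.files(dir, pattern = "\\.(png|jpg|jpeg)$",
                              ignore.case = TRUE), seen)
  for (fn in extra) {
    pixels <- if (read_pixels) read_image_file(file.path(dir, fn)) else NULL
    sz <- if (is.null(pixels)) {
      dim(read_image_file(file.path(dir, fn)))[1:2]
    } else dim(pixels)[1:2]
    records[[length(records) + 1]] <-
      annotated_image(pixels, list(), list(image_id = fn), size = sz)
  }
  records
}

#' Write an annotated image dataset (images + annotation JSON)
#'
#' @param records list of [annotated_image()].
#' @param dir output directory (created if needed).
#' @param write_images write `pixels` as PNG files.
#' @return invisibly, the JSON file path.
#' @export
write_annotations <- function(records, dir, write_images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  images <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    fn <- r$meta$image_id
    if (is.na(fn) || !grepl("\\.(png|jpg|jpeg)$", fn, ignore.case = TRUE)) {
      fn <- sprintf("image_%04d.png", i)
    }
    if (write_images && !is.null(r$pixels)) {
      write_image_file(r$pixels, file.path(dir, fn))
    }
    meta <- r$meta
    meta$image_id <- NULL
    list(
      file = fn, height = r$size[1], width = r$size[2],
      meta = meta[!vapply(meta, function(v) all(is.na(v)), TRUE)],
      splines = lapply(r$splines, function(s) {
        list(id = s$id,
             points = lapply(seq_len(nrow(s$points)),
                             function(k) as.numeric(s$points[k, ])))
      }))
  })
  json_path <- file.path(dir, "annotations.json")
  jsonlite::write_json(list(images = images), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(json_path)
}

#' Write / read a sparse mask as CSV
#'
#' Plain-text sparse format: a header line `# shape=H,W` followed by
#' `row,col` 0-based foreground indices. Storage is proportional to the
#' foreground count, which for trichome masks is a small fraction of the
#' raster.
#'
#' @param m a [sparse_mask()].
#' @param path CSV file path.
#' @return `write_mask_csv` the path invisibly; `read_mask_csv` a
#'   [sparse_mask()].
#' @export
write_mask_csv <- function(m, path) {
  stopifnot(inherits(m, "sparse_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shape=%d,%d", m$shape[1], m$shape[2]), con)
  writeLines("row,col", con)
  if (nrow(m$foreground) > 0) {
    writeLines(paste(m$foreground[, 1], m$foreground[, 2], sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  shp <- as.integer(strsplit(sub("^# shape=", "", hdr), ",")[[1]])
  if (length(shp) != 2 || any(is.na(shp))) {
    stop_trichoseg("mask CSV '", path, "' lacks a '# shape=H,W' header",
                   class = "trichoseg_io_error")
  }
  df <- utils::read.csv(path, skip = 1)
  sparse_mask(shp, cbind(df$row, df$col))
}

#' Write / read a dense mask as single-channel PNG (0/255)
#'
#' @param m a [sparse_mask()].
#' @param path PNG file path.
#' @return `write_mask_png` the path invisibly; `read_mask_png` a
#'   [sparse_mask()] (pixels > 0.5 are foreground).
#' @export
write_mask_png <- function(m, path) {
  dense <- sparse_decode(m)
  storage.mode(dense) <- "double"
  png::writePNG(dense, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sparse_encode((img > 0.5) * 1L)
}

#' Composition of the annotated cotton trichome dataset by hairiness class
#'
#' Per-GHS-class image and genotype counts of the 1250-image annotated
#' training corpus (images of the hairiest class, 5+, were too tangled for
#' humans to annotate confidently and are absent).
#'
#' @return data.frame with columns `ghs`, `n_images`, `n_genotypes`.
#' @export
anncot_class_counts <- function() {
  utils::read.csv(system.file("extdata", "anncot_class_counts.csv",
                              package = "trichoseg"),
                  colClasses = c("character", "integer", "integer"))
}

#' Reference genotype panel with breeder hairiness scores
#'
#' The 27 de-identified genotypes and their GHS classes used across the
#' deposited leaf-surface image datasets.
#'
#' @return data.frame with columns `genotype`, `ghs`.
#' @export
reference_genotypes <- function() {
  utils::read.csv(system.file("extdata", "reference_genotypes.csv",
                              package = "trichoseg"),
                  colClasses = "character")
}

#' Design of the follow-up leaf image collection (one image per leaf)
#'
#' Three experiments (field and glasshouse in year 3, field in year 4),
#' each imaging leaf 3 of 10 plants for each of the 27 genotypes, one
#' midvein image per leaf.
#'
#' @return data.frame with one row per experiment and columns
#'   `environment`, `year`, `n_genotypes`, `plants_per_genotype`,
#'   `images_per_plant`.
#' @export
cotleaf2_design <- function() {
  utils::read.csv(system.file("extdata", "cotleaf2_design.csv",
                              package = "trichoseg"),
                  colClasses = c("character", "character", "integer",
                                 "integer", "integer"))
}
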