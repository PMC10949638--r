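# The model-selection study: a grid over encoder x decoder pairs,
# augmentation recipes and losses, with repeat runs reported as
# mean +/- range, resumable cell by cell.

#' Specification of a model-selection grid
#'
#' @param encoders,decoders,recipes,losses nonempty axes of the grid
#'   (registry names / recipe strings).
#' @param repeats training repeats per cell (>= 1); repeat seeds are
#'   derived by hashing the cell identity, so results do not depend on
#'   grid axis order.
#' @param base a [model_config()] supplying the shared hyperparameters.
#' @param finalists optional character vector of cell keys
#'   (`"encoder|decoder|recipe|loss"`) additionally evaluated on the test
#'   split; by default no cell touches the test set.
#' @param seed grid seed.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(encoders, decoders, recipes, losses, repeats = 1L,
                      base = model_config(), finalists = character(0),
                      seed = 1L) {
  stopifnot(length(encoders) > 0, length(decoders) > 0,
            length(recipes) > 0, length(losses) > 0, repeats >= 1)
  bad <- setdiff(encoders, encoder_names())
  if (length(bad)) {
    stop_trichoseg("unknown encoder(s): ", paste(bad, collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  bad <- setdiff(decoders, decoder_names())
  if (length(bad)) {
    stop_trichoseg("unknown decoder(s): ", paste(bad, collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  bad <- setdiff(losses, loss_names())
  if (length(bad)) {
    stop_trichoseg("unknown loss(es): ", paste(bad, collapse = ", "),
                   class = "trichoseg_registry_error")
  }
  lapply(recipes, parse_recipe)
  structure(list(encoders = encoders, decoders = decoders,
                 recipes = recipes, losses = losses,
                 repeats = as.integer(repeats), base = base,
                 finalists = finalists, seed = as.integer(seed)),
            class = "grid_spec")
}

cell_key <- function(encoder, decoder, recipe, loss) {
  paste(encoder, decoder, recipe, loss, sep = "|")
}

#' Run a model-selection grid
#'
#' Trains every cell `repeats` times with seeds derived from the cell
#' identity (not its position, so reordering axes changes nothing),
#' evaluates on the validation split always, and on the test split only
#' for cells flagged as finalists. Cells are run in deterministic
#' (lexicographic key) order. With `out_dir`, results stream to
#' `grid_results.csv` and completed cells are skipped on rerun (resume is
#' idempotent). Cell failures are recorded and the grid continues.
#'
#' @param spec a [grid_spec()].
#' @param train_set,val_set,test_set annotated image lists.
#' @param out_dir optional directory for streaming results / resume.
#' @param quiet suppress progress messages.
#' @return a `grid_result` data.frame: one row per evaluated cell x
#'   split with `encoder`, `decoder`, `recipe`, `loss`, `split`,
#'   `mean_iou`, `range_iou`, `mean_f1`, `range_f1`, `repeats`; failures
#'   in attribute `failures`.
#' @export
run_grid <- function(spec, train_set, val_set, test_set = list(),
                     out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- expand.grid(encoder = spec$encoders, decoder = spec$decoders,
                       recipe = spec$recipes, loss = spec$losses,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cell_key(cells$encoder, cells$decoder,
                                cells$recipe, cells$loss)), , drop = FALSE]
  csv_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "grid_results.csv")
  }
  done <- if (!is.null(csv_path) && file.exists(csv_path)) {
    utils::read.csv(csv_path, colClasses = NA)
  } else {
    data.frame(encoder = character(), decoder = character(),
               recipe = character(), loss = character(),
               split = character(), mean_iou = numeric(),
               range_iou = numeric(), mean_f1 = numeric(),
               range_f1 = numeric(), repeats = integer())
  }
  failures <- character(0)
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    key <- cell_key(cl$encoder, cl$decoder, cl$recipe, cl$loss)
    existing <- cell_key(done$encoder, done$decoder, done$recipe, done$loss)
    if (key %in% existing) next
    if (!quiet) message("grid cell: ", key)
    rows <- tryCatch({
      per_rep <- lapply(seq_len(spec$repeats), function(rep) {
        cfg <- spec$base
        cfg$encoder <- cl$encoder; cfg$decoder <- cl$decoder
        cfg$recipe <- cl$recipe; cfg$loss <- cl$loss
        cfg$seed <- derive_seed(spec$seed, cl$encoder, cl$decoder,
                                cl$recipe, cl$loss, rep)
        rpt <- train_segmenter(cfg, train_set, val_set)
        out <- list(val = c(
          iou = rpt$epochs$val_iou[rpt$best_epoch],
          f1 = rpt$epochs$val_f1[rpt$best_epoch]))
        if (key %in% spec$finalists && length(test_set) > 0) {
          ev <- evaluate_segmentation(rpt$model, test_set)
          out$test <- attr(ev, "means")[c("iou", "f1")]
        }
        out
      })
      summarize <- function(split) {
        vals <- vapply(per_rep, function(r) r[[split]], numeric(2))
        data.frame(encoder = cl$encoder, decoder = cl$decoder,
                   recipe = cl$recipe, loss = cl$loss, split = split,
                   mean_iou = mean(vals[1, ]),
                   range_iou = diff(range(vals[1, ])),
                   mean_f1 = mean(vals[2, ]),
                   range_f1 = diff(range(vals[2, ])),
                   repeats = spec$repeats, stringsAsFactors = FALSE)
      }
      rows <- summarize("val")
      if (!is.null(per_rep[[1]]$test)) rows <- rbind(rows, summarize("test"))
      rows
    }, error = function(e) conditionMessage(e))
    if (is.character(rows)) {
      failures <- c(failures, paste0(key, ": ", rows))
      next
    }
    done <- rbind(done, rows)
    if (!is.null(csv_path)) {
      utils::write.csv(done, csv_path, row.names = FALSE)
    }
  }
  class(done) <- c("grid_result", class(done))
  attr(done, "failures") <- failures
  done
}

#' Select the best grid cell by validation performance
#'
#' Argmax of the mean metric on the validation split; ties are broken by
#' the other metric, then by lexicographic cell key.
#'
#' @param result a `grid_result` from [run_grid()].
#' @param metric `"iou"` or `"f1"`.
#' @return the winning row of `result` (split == "val").
#' @export
select_best <- function(result, metric = c("iou", "f1")) {
  metric <- match.arg(metric)
  rows <- result[result$split == "val", , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_trichoseg("empty grid result", class = "trichoseg_validation_error")
  }
  primary <- rows[[paste0("mean_", metric)]]
  other <- rows[[paste0("mean_", setdiff(c("iou", "f1"), metric))]]
  key <- cell_key(rows$encoder, rows$decoder, rows$recipe, rows$loss)
  o <- order(-primary, -other, key)
  rows[o[1], , drop = FALSE]
}

#' Render a grid result as a compact Markdown table
#'
#' @param result a `grid_result`.
#' @param split which split to tabulate.
#' @return character vector of Markdown lines.
#' @export
format_grid_markdown <- function(result, split = "val") {
  rows <- result[result$split == split, , drop = FALSE]
  fmt <- function(m, r, n) {
    if (n > 1) sprintf("%.4f ± %.3f", m, r / 2) else sprintf("%.4f", m)
  }
  c(sprintf("| Encoder | Decoder | Recipe | Loss | IoU (%s) | F1 (%s) |",
            split, split),
    "|---|---|---|---|---|---|",
    vapply(seq_len(nrow(rows)), function(i) {
      sprintf("| %s | %s | %s | %s | %s | %s |",
              rows$encoder[i], rows$decoder[i], rows$recipe[i],
              rows$loss[i],
              fmt(rows$mean_iou[i], rows$range_iou[i], rows$repeats[i]),
              fmt(rows$mean_f1[i], rows$range_f1[i], rows$repeats[i]))
    }, character(1)))
}
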