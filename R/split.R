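# Train/validation/test splitting with the floor/floor/remainder rounding
# used for the 1250-image annotated corpus (65/15/20 -> 812/187/251).

#' Split a dataset into train/validation/test
#'
#' Sizes follow floor/floor/remainder arithmetic:
#' `n_train = floor(f_train * N)`, `n_val = floor(f_val * N)`, the rest is
#' test. With `stratify_by`, the same rule is applied within each level of
#' that metadata key so per-stratum proportions deviate by at most one
#' record; strata with fewer than 3 records are assigned wholly to train
#' with a warning. The split is a partition (union equals the input,
#' pairwise disjoint) and is reproducible given `seed`.
#'
#' @param records list of [annotated_image()] (or any list; with
#'   stratification, elements must carry `$meta[[stratify_by]]`).
#' @param fractions numeric `(train, val, test)` summing to 1 (tol 1e-9).
#' @param seed integer seed for the shuffling.
#' @param stratify_by metadata key (e.g. `"ghs"`, `"genotype"`) or NULL.
#' @return named list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.65, 0.15, 0.20),
                          seed = 1L, stratify_by = NULL) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_trichoseg("fractions must be three nonnegative numbers summing ",
                   "to 1", class = "trichoseg_validation_error")
  }
  n <- length(records)
  take <- function(idx) {
    # floor/floor/remainder on a pre-shuffled index vector
    m <- length(idx)
    n_tr <- floor(fractions[1] * m)
    n_va <- floor(fractions[2] * m)
    list(train = idx[seq_len(n_tr)],
         val = idx[seq_len(n_va) + n_tr],
         test = idx[setdiff(seq_len(m), seq_len(n_tr + n_va))])
  }
  if (is.null(stratify_by)) {
    idx <- with_seed(seed, sample.int(n))
    parts <- take(idx)
  } else {
    key <- vapply(records, function(r) {
      v <- r$meta[[stratify_by]]
      if (is.null(v) || is.na(v)) "<missing>" else as.character(v)
    }, character(1))
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (lev in sort(unique(key))) {
      stratum <- which(key == lev)
      if (length(stratum) < 3) {
        warning("stratum '", lev, "' has fewer than 3 records; ",
                "assigning all of it to train", call. = FALSE)
        parts$train <- c(parts$train, stratum)
        next
      }
      idx <- with_seed(derive_seed(seed, "stratum", lev),
                       stratum[sample.int(length(stratum))])
      p <- take(idx)
      parts <- Map(c, parts, p)
    }
  }
  lapply(parts, function(ix) records[ix])
}
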