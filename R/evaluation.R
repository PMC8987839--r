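# Cell-wise evaluation protocol: predicted grids vs reference grids
# (human rater or ground-truth occupancy), tallied into a confusion
# matrix and summarised as overall accuracy, precision and recall.

#' Reference cell grid for an image
#'
#' Reference labels follow the rater convention: a cell is positive when
#' greenery occupies strictly more than half of it (see
#' [mask_to_grid_labels()] for deriving this from a ground-truth mask).
#'
#' @param cell_mask Logical rows x cols matrix.
#' @param image_id Image identifier.
#' @return A `reference_grid`.
#' @export
reference_grid <- function(cell_mask, image_id = "image") {
  if (!is.matrix(cell_mask) || !is.logical(cell_mask))
    stop("cell_mask must be a logical matrix")
  structure(list(image_id = image_id, cell_mask = cell_mask),
            class = "reference_grid")
}

#' Position-wise confusion counts over paired grids
#'
#' Pairs predictions and references by `image_id` and tallies every cell
#' position: `tp` (both positive), `fp` (predicted only), `fn`
#' (reference only), `tn` (neither).
#'
#' @param predictions A `grid_classification` or list of them.
#' @param references A `reference_grid` or list of them.
#' @return A `confusion_counts` list `tp, fp, fn, tn`.
#' @export
grid_confusion <- function(predictions, references) {
  as_list <- function(x, cls) if (inherits(x, cls)) list(x) else x
  predictions <- as_list(predictions, "grid_classification")
  references <- as_list(references, "reference_grid")
  ref_ids <- vapply(references, function(r) r$image_id, character(1))
  tp <- fp <- fn <- tn <- 0L
  for (pr in predictions) {
    k <- match(pr$image_id, ref_ids)
    if (is.na(k))
      stop("no reference grid for image '", pr$image_id, "'")
    rm_ <- references[[k]]$cell_mask
    pm <- pr$cell_mask
    if (!all(dim(pm) == dim(rm_)))
      stop(sprintf("grid shape mismatch for image '%s': %dx%d vs %dx%d",
                   pr$image_id, nrow(pm), ncol(pm), nrow(rm_), ncol(rm_)))
    tp <- tp + sum(pm & rm_)
    fp <- fp + sum(pm & !rm_)
    fn <- fn + sum(!pm & rm_)
    tn <- tn + sum(!pm & !rm_)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Cell confusion: tp=%d fp=%d fn=%d tn=%d (N=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Overall accuracy, precision and recall from confusion counts
#'
#' `accuracy = (tp+tn)/N`, `precision = tp/(tp+fp)`,
#' `recall = tp/(tp+fn)`. A metric whose denominator is zero is reported
#' as `NA` and named in the `undefined` field — never silently zero.
#'
#' @param counts A `confusion_counts` (or list with `tp, fp, fn, tn`).
#' @return An `eval_metrics` list with `accuracy`, `precision`,
#'   `recall`, and `undefined` (character vector of metrics with zero
#'   denominators).
#' @examples
#' confusion_metrics(list(tp = 2, fp = 1, fn = 1, tn = 6))
#' @export
confusion_metrics <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0L) stop("no cells tallied")
  undefined <- character(0)
  precision <- if (counts$tp + counts$fp > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else { undefined <- c(undefined, "precision"); NA_real_ }
  recall <- if (counts$tp + counts$fn > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else { undefined <- c(undefined, "recall"); NA_real_ }
  structure(list(accuracy = (counts$tp + counts$tn) / n,
                 precision = precision, recall = recall,
                 undefined = undefined),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("overall accuracy %s; precision %s; recall %s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall)))
  invisible(x)
}

#' Read / write cell grids as long-format CSV
#'
#' Dialect shared by predictions and references: columns
#' `image_id,row,col,positive` with 1-based cell indices.
#'
#' @param grids List of `grid_classification` or `reference_grid`.
#' @param path CSV path.
#' @return `write_grids` returns `path` invisibly; `read_grids` a named
#'   list of logical cell matrices.
#' @export
write_grids <- function(grids, path) {
  rows <- lapply(grids, function(g) {
    cm <- g$cell_mask
    data.frame(image_id = g$image_id,
               row = rep(seq_len(nrow(cm)), times = ncol(cm)),
               col = rep(seq_len(ncol(cm)), each = nrow(cm)),
               positive = as.integer(as.vector(cm)),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grids
#' @export
read_grids <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$image_id)) {
    d <- df[df$image_id == id, ]
    m <- matrix(FALSE, max(d$row), max(d$col))
    m[cbind(d$row, d$col)] <- d$positive > 0
    out[[as.character(id)]] <- m
  }
  out
}
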