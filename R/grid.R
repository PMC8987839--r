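# Whole-image inference: non-overlapping cell grid and the per-image
# Green View Index.

#' Construct a grid classification
#'
#' @param cell_mask Logical rows x cols matrix, `TRUE` = greenery cell.
#' @param image_id Image identifier.
#' @param cell_px Cell side in pixels.
#' @return A `grid_classification` with `positive_count` tallied.
#' @export
grid_classification <- function(cell_mask, image_id = "image",
                                cell_px = 32L) {
  if (!is.matrix(cell_mask) || !is.logical(cell_mask))
    stop("cell_mask must be a logical matrix")
  structure(list(image_id = image_id, rows = nrow(cell_mask),
                 cols = ncol(cell_mask), cell_px = as.integer(cell_px),
                 cell_mask = cell_mask,
                 positive_count = sum(cell_mask)),
            class = "grid_classification")
}

#' @export
print.grid_classification <- function(x, ...) {
  cat(sprintf("Grid classification '%s': %dx%d cells of %d px, %d positive (GVI %.2f%%)\n",
              x$image_id, x$rows, x$cols, x$cell_px, x$positive_count,
              gvi(x)))
  invisible(x)
}

#' Classify an image as a grid of square cells
#'
#' The image is tiled into non-overlapping `cell_px` squares from the
#' top-left corner (unlike training chopping, inference tiles do not
#' overlap; a 640x640 image yields the canonical 20x20 grid). Trailing
#' remainder pixels are truncated, never padded. Each cell is classified
#' at the model's decision threshold.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param model A fitted [cpm_train()] model, or a function
#'   `f(pixels, source)` returning greenery probabilities for a
#'   `(3*cell_px^2) x N` pixel matrix (`source` is a data.frame of cell
#'   top-left `x, y`; stubs and oracles may ignore either argument).
#' @param cell_px Cell side in pixels (default 32).
#' @param threshold Probability threshold; defaults to the model's
#'   configured `decision_threshold` (0.5 for function models).
#' @param image_id Identifier stored in the result.
#' @return A `grid_classification`.
#' @export
classify_grid <- function(image, model, cell_px = 32L, threshold = NULL,
                          image_id = "image") {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < cell_px || w < cell_px)
    stop(sprintf("image %dx%d smaller than one %d px cell", w, h, cell_px))
  gr <- h %/% cell_px; gc <- w %/% cell_px
  n <- gr * gc
  pix <- matrix(0, 3L * cell_px * cell_px, n)
  xs <- integer(n); ys <- integer(n)
  k <- 0L
  for (j in seq_len(gc) - 1L) for (i in seq_len(gr) - 1L) {
    k <- k + 1L
    y <- i * cell_px; x <- j * cell_px
    pix[, k] <- as.vector(image[(y + 1L):(y + cell_px),
                                (x + 1L):(x + cell_px), 1:3])
    xs[k] <- x; ys[k] <- y
  }
  src <- data.frame(x = xs, y = ys)
  if (inherits(model, "cpm")) {
    if (cell_px != model$patch_px)
      stop("cell_px must equal the model's patch size")
    probs <- predict(model, pix)
    if (is.null(threshold)) threshold <- model$config$decision_threshold
  } else if (is.function(model)) {
    probs <- model(pix, src)
    if (is.null(threshold)) threshold <- 0.5
  } else stop("model must be a cpm fit or a probability function")
  if (length(probs) != n) stop("model returned wrong number of probabilities")
  grid_classification(matrix(probs > threshold, gr, gc),
                      image_id = image_id, cell_px = cell_px)
}

#' Green View Index of a classified grid
#'
#' The percentage of grid cells classified as greenery:
#' `100 * positive_count / (rows * cols)`. Computed in full precision;
#' round only at I/O boundaries (e.g. 65/400 cells = 16.25%).
#'
#' @param grid A `grid_classification` or a logical cell matrix.
#' @return Percentage in `[0, 100]`.
#' @examples
#' g <- matrix(FALSE, 20, 20); g[seq_len(65)] <- TRUE
#' gvi(g)  # 16.25
#' @export
gvi <- function(grid) {
  cm <- if (inherits(grid, "grid_classification")) grid$cell_mask else grid
  if (!is.matrix(cm)) stop("grid must be a grid_classification or matrix")
  n <- length(cm)
  if (n == 0L) stop("zero-cell grid")
  100 * sum(cm) / n
}

#' Render the classified grid over an image
#'
#' Presentational overlay: translucent red tint over greenery cells,
#' green over the rest, with 1-px grid lines; pixels outside the covered
#' grid (truncated remainders) are left untouched.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param grid The matching `grid_classification`.
#' @param alpha Tint opacity (default 0.35).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_overlay <- function(image, grid, alpha = 0.35) {
  if (!inherits(grid, "grid_classification")) stop("grid must be a grid_classification")
  cp <- grid$cell_px
  if (dim(image)[1] < grid$rows * cp || dim(image)[2] < grid$cols * cp)
    stop("image dimensions inconsistent with grid")
  out <- image
  red <- c(1, 0, 0); green <- c(0, 1, 0)
  for (i in seq_len(grid$rows)) for (j in seq_len(grid$cols)) {
    tint <- if (grid$cell_mask[i, j]) red else green
    rr <- ((i - 1L) * cp + 1L):(i * cp)
    cc <- ((j - 1L) * cp + 1L):(j * cp)
    for (ch in 1:3)
      out[rr, cc, ch] <- (1 - alpha) * out[rr, cc, ch] + alpha * tint[ch]
  }
  line_rows <- c(seq(1L, grid$rows * cp, by = cp), grid$rows * cp)
  line_cols <- c(seq(1L, grid$cols * cp, by = cp), grid$cols * cp)
  out[line_rows, seq_len(grid$cols * cp), ] <- 0.2
  out[seq_len(grid$rows * cp), line_cols, ] <- 0.2
  out
}
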