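# Colour-band-difference baseline: the unsupervised per-pixel greenery
# rule used for head-to-head comparison with the patch classifier.

#' Parameters of the colour-band-difference rule
#'
#' @param delta Band-difference threshold on `[0, 1]`-scaled channels
#'   (default 0.05; on 0-255 channels that is about 12.75 levels).
#' @param min_region_px Optional despeckling: connected true-regions
#'   (4-connectivity) smaller than this many pixels are removed. Default
#'   0 = off.
#' @return A `color_params` list.
#' @export
color_params <- function(delta = 0.05, min_region_px = 0L) {
  if (delta < 0) stop("delta must be non-negative")
  structure(list(delta = delta, min_region_px = as.integer(min_region_px)),
            class = "color_params")
}

#' Per-pixel greenery by colour-band difference
#'
#' A pixel is classified greenery iff its green channel exceeds *both*
#' the red and the blue channel by strictly more than `delta` (high
#' reflectance in the green band, relatively low in red and blue). This
#' is a colour-only rule: it has no access to texture, so near-uniform
#' artificial-green surfaces pass it — the failure mode the patch
#' classifier is meant to avoid.
#'
#' @param image H x W x 3 RGB array; values in `[0, 1]` (0-255 input is
#'   rescaled).
#' @param params A [color_params()].
#' @return Logical H x W matrix.
#' @examples
#' px <- array(c(0.2, 0.4, 0.2), c(1, 1, 3))
#' color_classify_pixels(px)  # TRUE: both differences 0.2 > 0.05
#' @export
color_classify_pixels <- function(image, params = color_params()) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("grayscale input: convert to a 3-channel RGB array first")
  if (max(image) > 1) image <- image / 255
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- matrix(image[, , 1], h, w)
  g <- matrix(image[, , 2], h, w)
  b <- matrix(image[, , 3], h, w)
  mask <- (g - r > params$delta) & (g - b > params$delta)
  if (params$min_region_px > 0L && any(mask)) {
    lab <- label4_cpp(mask)
    sizes <- tabulate(lab)
    small <- which(sizes < params$min_region_px)
    if (length(small) > 0L) mask[lab %in% small] <- FALSE
  }
  mask
}

#' Put the baseline's pixel mask on the cell-grid footing
#'
#' Delegates to the same strict >50% occupancy rule as
#' [mask_to_grid_labels()], so baseline and patch-classifier results are
#' comparable cell by cell.
#'
#' @param mask Logical pixel mask from [color_classify_pixels()].
#' @param cell_px Cell side in pixels (default 32).
#' @param occupancy_threshold Fraction (default 0.5, strict).
#' @param image_id Identifier stored in the result.
#' @return A `grid_classification`.
#' @export
color_mask_to_grid <- function(mask, cell_px = 32L,
                               occupancy_threshold = 0.5,
                               image_id = "image") {
  grid_classification(
    mask_to_grid_labels(mask, cell_px, occupancy_threshold),
    image_id = image_id, cell_px = cell_px)
}
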