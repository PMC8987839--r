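# Synthetic streetscape generator: seeded scenes with known per-pixel
# greenery masks, standing in for street-level survey imagery.

.SCENE_CATEGORIES <- c("vegetation", "artificial_green", "shadow_vegetation",
                       "sky", "building", "road")
.GREEN_CATEGORIES <- c("vegetation", "shadow_vegetation")

.default_region_color <- function(category) {
  switch(category,
    vegetation        = c(0.20, 0.45, 0.16),
    artificial_green  = c(0.10, 0.60, 0.12),
    shadow_vegetation = c(0.20, 0.45, 0.16),
    sky               = c(0.55, 0.70, 0.95),
    building          = c(0.55, 0.54, 0.52),
    road              = c(0.35, 0.35, 0.36))
}

.default_region_amplitude <- function(category) {
  switch(category,
    vegetation        = 0.25,
    artificial_green  = 0.01,
    shadow_vegetation = 0.25,
    sky               = 0.00,
    building          = 0.02,
    road              = 0.02)
}

#' Describe one rectangular scene region
#'
#' Regions are axis-aligned boxes painted in list order (later regions
#' overwrite earlier ones, in both the image and the ground-truth mask).
#' `vegetation` and `shadow_vegetation` contribute to the greenery mask;
#' `artificial_green` deliberately does not: it renders as a near-uniform
#' green surface (turf, mats) that colour-threshold methods confuse with
#' vegetation but a texture-aware classifier should reject.
#'
#' @param category One of `"vegetation"`, `"artificial_green"`,
#'   `"shadow_vegetation"`, `"sky"`, `"building"`, `"road"`.
#' @param box Integer vector `c(x0, y0, x1, y1)`, 0-based half-open pixel
#'   coordinates (`x` = column, `y` = row).
#' @param texture_amplitude Relative amplitude of the per-pixel
#'   multiplicative luminance noise, in `[0, 1]`. Defaults per category:
#'   textured (0.25) for vegetation, near-uniform (0.01) for artificial
#'   green.
#' @param base_color RGB triple in `[0, 1]`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(category, box,
                        texture_amplitude = .default_region_amplitude(category),
                        base_color = .default_region_color(category)) {
  category <- match.arg(category, .SCENE_CATEGORIES)
  box <- as.integer(round(box))
  if (length(box) != 4L || box[3] <= box[1] || box[4] <= box[2])
    stop("region box must be c(x0, y0, x1, y1) with x1 > x0 and y1 > y0")
  if (texture_amplitude < 0 || texture_amplitude > 1)
    stop("texture_amplitude must lie in [0, 1]")
  structure(list(category = category, box = box,
                 texture_amplitude = texture_amplitude,
                 base_color = base_color),
            class = "region_spec")
}

#' Describe a synthetic streetscape
#'
#' @param regions List of [region_spec()] objects, painted in order.
#' @param width,height Canvas size in pixels (default 640, the nominal
#'   street-level survey image size).
#' @param seed Integer seed; the rendered scene is a deterministic
#'   function of the spec including this seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(regions, width = 640L, height = 640L, seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0L || height <= 0L) stop("canvas dimensions must be positive")
  for (r in regions) {
    if (!inherits(r, "region_spec")) stop("regions must be region_spec objects")
    b <- r$box
    if (b[1] < 0L || b[2] < 0L || b[3] > width || b[4] > height)
      stop(sprintf("region box [%d,%d)x[%d,%d) lies outside the %dx%d canvas",
                   b[1], b[3], b[2], b[4], width, height))
  }
  structure(list(width = width, height = height, regions = regions,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Mid-frequency "blotch" field: coarse Gaussian grid, bilinearly
# upsampled. Gives vegetation structure between pixel noise and the box.
.smooth_noise <- function(h, w, scale) {
  gh <- ceiling(h / scale) + 1L
  gw <- ceiling(w / scale) + 1L
  g <- matrix(rnorm(gh * gw), gh, gw)
  ys <- (seq_len(h) - 1) / scale
  xs <- (seq_len(w) - 1) / scale
  y0 <- pmin(floor(ys), gh - 2); fy <- ys - y0
  x0 <- pmin(floor(xs), gw - 2); fx <- xs - x0
  iy <- as.integer(y0) + 1L; ix <- as.integer(x0) + 1L
  ri <- rep(iy, times = w); ci <- rep(ix, each = h)
  FY <- matrix(rep(fy, times = w), h, w)
  FX <- matrix(rep(fx, each = h), h, w)
  g00 <- matrix(g[cbind(ri, ci)], h, w)
  g10 <- matrix(g[cbind(ri + 1L, ci)], h, w)
  g01 <- matrix(g[cbind(ri, ci + 1L)], h, w)
  g11 <- matrix(g[cbind(ri + 1L, ci + 1L)], h, w)
  g00 * (1 - FY) * (1 - FX) + g10 * FY * (1 - FX) +
    g01 * (1 - FY) * FX + g11 * FY * FX
}

# Paint one region; returns an h x w x 3 array in [0, 1] float.
.render_region <- function(region, h, w) {
  base <- region$base_color
  amp <- region$texture_amplitude
  block <- array(0, c(h, w, 3))
  if (region$category == "sky") {
    # vertical blue -> white gradient, top of region bluest
    t <- (seq_len(h) - 1) / max(h - 1, 1)
    for (ch in 1:3)
      block[, , ch] <- matrix(base[ch] + (1 - base[ch]) * t, h, w)
  } else if (region$category %in% c("building", "road")) {
    # low-frequency gray: broad sinusoidal shading + faint noise
    phase <- runif(2, 0, 2 * pi)
    shade <- 0.06 * outer(sin(2 * pi * (seq_len(h) / h) + phase[1]),
                          cos(2 * pi * (seq_len(w) / w) + phase[2]))
    noise <- amp * matrix(rnorm(h * w), h, w)
    for (ch in 1:3) block[, , ch] <- base[ch] * (1 + shade + noise)
  } else {
    # green surfaces: multiplicative luminance noise + blotch field
    lum <- 1 + amp * matrix(rnorm(h * w), h, w)
    if (amp > 0.05) lum <- lum * (1 + 0.6 * amp * .smooth_noise(h, w, 8))
    for (ch in 1:3) block[, , ch] <- base[ch] * lum
    if (region$category == "shadow_vegetation") {
      block <- block * runif(1, 0.3, 0.6)
    }
  }
  pmin(pmax(block, 0), 1)
}

#' Render a synthetic scene with its ground-truth greenery mask
#'
#' Regions are composited in list order in floating point, then the image
#' is quantised to 8-bit levels. The mask is computed from the region
#' geometry (not from rendered colours): a pixel is greenery iff the last
#' region covering it has category `vegetation` or `shadow_vegetation`.
#'
#' @param spec A [scene_spec()].
#' @return A `scene_fixture` list with elements `image` (H x W x 3 array
#'   in `[0, 1]`, quantised to 255 levels), `mask` (logical H x W matrix,
#'   `TRUE` = greenery), `category` (integer H x W matrix, 0 = untouched
#'   background, otherwise index into `levels` attribute) and `spec`.
#' @examples
#' sp <- scene_spec(list(region_spec("vegetation", c(0, 0, 64, 64))),
#'                  width = 64, height = 64, seed = 3)
#' fx <- generate_scene(sp)
#' mean(fx$mask)  # 1: full greenery coverage
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  h <- spec$height; w <- spec$width
  set.seed(spec$seed)
  img <- array(0.5, c(h, w, 3))  # neutral gray background
  cat_map <- matrix(0L, h, w)
  for (region in spec$regions) {
    b <- region$box
    rows <- (b[2] + 1L):b[4]
    cols <- (b[1] + 1L):b[3]
    img[rows, cols, ] <- .render_region(region, length(rows), length(cols))
    cat_map[rows, cols] <- match(region$category, .SCENE_CATEGORIES)
  }
  img <- round(img * 255) / 255
  mask <- matrix(.SCENE_CATEGORIES[pmax(cat_map, 1L)] %in% .GREEN_CATEGORIES &
                   cat_map > 0L, h, w)
  attr(cat_map, "levels") <- .SCENE_CATEGORIES
  structure(list(image = img, mask = mask, category = cat_map, spec = spec),
            class = "scene_fixture")
}

#' @export
print.scene_fixture <- function(x, ...) {
  cat(sprintf("Synthetic streetscape %dx%d px, %d regions, %.1f%% greenery\n",
              x$spec$width, x$spec$height, length(x$spec$regions),
              100 * mean(x$mask)))
  invisible(x)
}

#' Draw a randomised but plausibly laid-out streetscape spec
#'
#' Layered layout: sky band on top, building band, road band at the
#' bottom, then vegetation, shadowed vegetation and artificial-green
#' rectangles painted over them. All draws are deterministic per seed.
#'
#' @param seed Integer seed (also becomes the scene seed).
#' @param width,height Canvas size in pixels.
#' @param n_vegetation,n_shadow,n_artificial Number of rectangles of each
#'   green-ish kind; defaults draw 2-4 vegetation, 0-1 shadowed, 1-2
#'   artificial-green.
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(seed, width = 640L, height = 640L,
                              n_vegetation = NULL, n_shadow = NULL,
                              n_artificial = NULL) {
  set.seed(as.integer(seed) + 90191L)
  w <- as.integer(width); h <- as.integer(height)
  sky_h <- as.integer(round(h * runif(1, 0.25, 0.45)))
  road_y <- as.integer(round(h * runif(1, 0.75, 0.88)))
  regions <- list(
    region_spec("sky", c(0, 0, w, sky_h)),
    region_spec("building", c(0, sky_h, w, road_y),
                base_color = rep(runif(1, 0.45, 0.65), 3)),
    region_spec("road", c(0, road_y, w, h)))
  rand_box <- function(min_side, max_side, y_min_frac = 0.2) {
    bw <- as.integer(round(runif(1, min(min_side, w), min(max_side, w))))
    bh <- as.integer(round(runif(1, min(min_side, h), min(max_side, h))))
    x0 <- as.integer(floor(runif(1, 0, w - bw + 1)))
    y0 <- as.integer(floor(runif(1, min(y_min_frac * h, h - bh), h - bh + 1)))
    c(x0, min(y0, h - bh), x0 + bw, min(y0, h - bh) + bh)
  }
  nveg <- if (is.null(n_vegetation)) sample(2:4, 1) else n_vegetation
  nsh  <- if (is.null(n_shadow)) sample(0:1, 1) else n_shadow
  nart <- if (is.null(n_artificial)) sample(1:2, 1) else n_artificial
  for (i in seq_len(nveg)) {
    col <- c(runif(1, 0.12, 0.28), runif(1, 0.38, 0.55), runif(1, 0.10, 0.24))
    regions[[length(regions) + 1L]] <-
      region_spec("vegetation", rand_box(128, 288), base_color = col)
  }
  for (i in seq_len(nsh))
    regions[[length(regions) + 1L]] <-
      region_spec("shadow_vegetation", rand_box(96, 192))
  for (i in seq_len(nart))
    regions[[length(regions) + 1L]] <-
      region_spec("artificial_green", rand_box(96, 192))
  scene_spec(regions, width = w, height = h, seed = as.integer(seed))
}

#' Reduce a pixel mask to per-cell occupancy labels
#'
#' The canonical cell-labelling rule: the mask is tiled into
#' non-overlapping `cell_px` squares from the top-left (trailing
#' remainder rows/columns truncated) and a cell is positive iff the
#' greenery pixel fraction *strictly* exceeds `occupancy_threshold` —
#' "more than a half" at the default, so an exact tie is negative.
#'
#' @param mask Logical matrix (`TRUE` = greenery).
#' @param cell_px Cell side in pixels (default 32).
#' @param occupancy_threshold Fraction in `[0, 1)` (default 0.5).
#' @return Logical `floor(H/cell_px)` x `floor(W/cell_px)` matrix.
#' @examples
#' m <- matrix(TRUE, 64, 64); m[, 33:64] <- FALSE
#' mask_to_grid_labels(m)  # 2x2 grid, left column TRUE
#' @export
mask_to_grid_labels <- function(mask, cell_px = 32L, occupancy_threshold = 0.5) {
  if (cell_px <= 0L) stop("cell_px must be positive")
  if (!is.matrix(mask)) stop("mask must be a matrix")
  gr <- nrow(mask) %/% cell_px
  gc <- ncol(mask) %/% cell_px
  if (gr < 1L || gc < 1L) stop("mask smaller than one cell")
  m <- mask[seq_len(gr * cell_px), seq_len(gc * cell_px), drop = FALSE]
  a <- array(m, c(cell_px, gr, cell_px, gc))
  counts <- apply(a, c(2, 4), sum)
  counts / (cell_px * cell_px) > occupancy_threshold
}

#' Derive rectangle annotations automatically from a ground-truth mask
#'
#' Stands in for a human rater trimming rectangles: boxes are rejection
#' sampled on the canvas and accepted as positive when their greenery
#' pixel fraction is at least `purity`, as negative when it is at most
#' `1 - purity`.
#'
#' @param fixture A `scene_fixture`.
#' @param n_positive,n_negative Number of rectangles of each label.
#' @param min_side,max_side Box side bounds in pixels.
#' @param purity Minimum class purity of an accepted box (default 0.9).
#' @param seed Integer seed; sampling is deterministic per seed.
#' @param image_id Identifier recorded in the annotations.
#' @return A data.frame with columns `image_id, x0, y0, x1, y1, label`
#'   (0-based half-open boxes).
#' @export
scene_to_annotations <- function(fixture, n_positive, n_negative,
                                 min_side = 32L, max_side = 192L,
                                 purity = 0.9, seed = 1L,
                                 image_id = "scene") {
  if (!inherits(fixture, "scene_fixture")) stop("fixture must be a scene_fixture")
  mask <- fixture$mask
  h <- nrow(mask); w <- ncol(mask)
  max_side <- min(max_side, h, w)
  if (min_side > max_side) stop("min_side exceeds canvas")
  # integral image for O(1) box sums
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- t(apply(apply(mask, 2L, cumsum), 1L, cumsum))
  box_frac <- function(x0, y0, x1, y1) {
    s <- ii[y1 + 1L, x1 + 1L] - ii[y0 + 1L, x1 + 1L] -
      ii[y1 + 1L, x0 + 1L] + ii[y0 + 1L, x0 + 1L]
    s / ((x1 - x0) * (y1 - y0))
  }
  set.seed(as.integer(seed))
  need <- c(positive = n_positive, negative = n_negative)
  got <- list(positive = list(), negative = list())
  attempts <- 0L
  max_attempts <- 500L * (n_positive + n_negative) + 2000L
  while ((length(got$positive) < need["positive"] ||
          length(got$negative) < need["negative"]) &&
         attempts < max_attempts) {
    attempts <- attempts + 1L
    bw <- as.integer(round(runif(1, min_side, max_side)))
    bh <- as.integer(round(runif(1, min_side, max_side)))
    x0 <- as.integer(floor(runif(1, 0, w - bw + 1)))
    y0 <- as.integer(floor(runif(1, 0, h - bh + 1)))
    f <- box_frac(x0, y0, x0 + bw, y0 + bh)
    if (f >= purity && length(got$positive) < need["positive"]) {
      got$positive[[length(got$positive) + 1L]] <- c(x0, y0, x0 + bw, y0 + bh)
    } else if (f <= 1 - purity && length(got$negative) < need["negative"]) {
      got$negative[[length(got$negative) + 1L]] <- c(x0, y0, x0 + bw, y0 + bh)
    }
  }
  for (cls in c("positive", "negative")) {
    if (length(got[[cls]]) < need[[cls]])
      stop(sprintf(
        "could not sample %d %s rectangles at purity %.2f (got %d)",
        need[[cls]], cls, purity, length(got[[cls]])))
  }
  boxes <- do.call(rbind, c(got$positive, got$negative))
  data.frame(image_id = image_id,
             x0 = boxes[, 1], y0 = boxes[, 2],
             x1 = boxes[, 3], y1 = boxes[, 4],
             label = rep(c(TRUE, FALSE), c(n_positive, n_negative)),
             stringsAsFactors = FALSE)
}

#' Write a scene fixture to disk
#'
#' Emits `<stem>.png` (image), `<stem>_mask.png` (0/255 mask) and
#' `<stem>.yml` (spec echo) into `dir`.
#'
#' @param fixture A `scene_fixture`.
#' @param dir Output directory (created if needed).
#' @param stem File stem.
#' @return Invisibly, the image path.
#' @export
write_scene_fixture <- function(fixture, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  png::writePNG(fixture$image, img_path)
  png::writePNG(fixture$mask * 1.0, file.path(dir, paste0(stem, "_mask.png")))
  spec <- fixture$spec
  yaml::write_yaml(
    list(width = spec$width, height = spec$height, seed = spec$seed,
         regions = lapply(spec$regions, function(r)
           list(category = r$category, box = as.integer(r$box),
                texture_amplitude = r$texture_amplitude,
                base_color = as.numeric(r$base_color)))),
    file.path(dir, paste0(stem, ".yml")))
  invisible(img_path)
}

#' Read an RGB image from a PNG file
#'
#' @param path PNG path.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) stop("grayscale image: convert to RGB first")
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
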