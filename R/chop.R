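# The chopped-picture core: rectangle annotations -> overlapping square
# patch training sets.

#' Chopping parameters
#'
#' @param patch_px Patch side in pixels (default 32).
#' @param stride_px Tiling stride in pixels (default 16, i.e. 50% overlap
#'   both vertically and horizontally).
#' @return A `chop_params` list.
#' @export
chop_params <- function(patch_px = 32L, stride_px = 16L) {
  patch_px <- as.integer(patch_px); stride_px <- as.integer(stride_px)
  if (stride_px <= 0L || stride_px > patch_px)
    stop("need 0 < stride_px <= patch_px")
  structure(list(patch_px = patch_px, stride_px = stride_px),
            class = "chop_params")
}

#' Validate a rectangle annotation row
#'
#' @param image_id Source image identifier.
#' @param x0,y0,x1,y1 0-based half-open pixel box (`[x0,x1) x [y0,y1)`).
#' @param label `TRUE` for greenery.
#' @return One-row annotation data.frame.
#' @export
rect_annotation <- function(image_id, x0, y0, x1, y1, label) {
  if (x1 <= x0 || y1 <= y0)
    stop("rectangle must satisfy x1 > x0 and y1 > y0")
  data.frame(image_id = image_id, x0 = as.integer(x0), y0 = as.integer(y0),
             x1 = as.integer(x1), y1 = as.integer(y1),
             label = as.logical(label), stringsAsFactors = FALSE)
}

# Internal patchset constructor. pixels: (3*p^2) x N matrix, columns are
# patches flattened from the (p, p, 3) array, column-major.
.new_patchset <- function(pixels, label, source, patch_px) {
  structure(list(pixels = pixels, label = as.logical(label),
                 source = source, patch_px = as.integer(patch_px)),
            class = "cpm_patchset")
}

#' Number of patches and class balance of a patch set
#'
#' @param x A `cpm_patchset`.
#' @param ... Unused.
#' @export
print.cpm_patchset <- function(x, ...) {
  cat(sprintf("Patch set: %d patches of %dx%d px (%d greenery, %d other)\n",
              length(x$label), x$patch_px, x$patch_px,
              sum(x$label), sum(!x$label)))
  invisible(x)
}

#' Concatenate patch sets
#'
#' @param ... `cpm_patchset` objects with equal `patch_px`.
#' @return A combined `cpm_patchset`.
#' @export
combine_patchsets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "cpm_patchset"))
    sets <- sets[[1]]
  sets <- Filter(function(s) length(s$label) > 0L, sets)
  if (length(sets) == 0L) stop("nothing to combine")
  p <- unique(vapply(sets, function(s) s$patch_px, integer(1)))
  if (length(p) != 1L) stop("patch sizes differ")
  .new_patchset(do.call(cbind, lapply(sets, function(s) s$pixels)),
                unlist(lapply(sets, function(s) s$label)),
                do.call(rbind, lapply(sets, function(s) s$source)),
                p)
}

#' Subset a patch set
#'
#' @param x A `cpm_patchset`.
#' @param i Index vector over patches.
#' @param ... Unused.
#' @export
`[.cpm_patchset` <- function(x, i, ...) {
  .new_patchset(x$pixels[, i, drop = FALSE], x$label[i],
                x$source[i, , drop = FALSE], x$patch_px)
}

#' @export
length.cpm_patchset <- function(x) length(x$label)

#' Chop one annotated rectangle into overlapping square patches
#'
#' Tiles the rectangle with `patch_px` squares at stride `stride_px`
#' (default 32 px squares, 50% overlap both vertically and horizontally).
#' Only whole tiles fully inside the rectangle are kept — partial windows
#' at the far edges are discarded, never padded — so the patch count is
#' `max(0, floor((W-p)/s)+1) * max(0, floor((H-p)/s)+1)`.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param rect One-row annotation data.frame (see [rect_annotation()]).
#' @param params A [chop_params()].
#' @return A `cpm_patchset`; every patch inherits the rectangle's label,
#'   and `source` records each tile's top-left `(x, y)`.
#' @examples
#' img <- array(0.5, c(64, 64, 3))
#' chop_rectangle(img, rect_annotation("a", 0, 0, 64, 64, TRUE))  # 3x3 = 9
#' @export
chop_rectangle <- function(image, rect, params = chop_params()) {
  p <- params$patch_px; s <- params$stride_px
  x0 <- rect$x0; y0 <- rect$y0; x1 <- rect$x1; y1 <- rect$y1
  if (x0 < 0L || y0 < 0L || x1 > ncol(image) || y1 > nrow(image))
    stop(sprintf("rectangle [%d,%d)x[%d,%d) outside %dx%d image '%s'",
                 x0, x1, y0, y1, ncol(image), nrow(image), rect$image_id))
  w <- x1 - x0; h <- y1 - y0
  nx <- if (w >= p) (w - p) %/% s + 1L else 0L
  ny <- if (h >= p) (h - p) %/% s + 1L else 0L
  n <- nx * ny
  pix <- matrix(0, 3L * p * p, n)
  xs <- integer(n); ys <- integer(n)
  k <- 0L
  # row-major tile order: y outer, x inner
  if (n > 0L) for (j in seq_len(ny) - 1L) for (i in seq_len(nx) - 1L) {
    k <- k + 1L
    x <- x0 + i * s; y <- y0 + j * s
    pix[, k] <- as.vector(image[(y + 1L):(y + p), (x + 1L):(x + p), 1:3])
    xs[k] <- x; ys[k] <- y
  }
  .new_patchset(pix, rep(rect$label, n),
                data.frame(image_id = rep(rect$image_id, n), x = xs, y = ys,
                           stringsAsFactors = FALSE),
                p)
}

#' Build a training patch set from many annotated rectangles
#'
#' Concatenates [chop_rectangle()] over all annotations in stable order
#' (annotation order, then row-major tile order within a rectangle).
#'
#' @param images Named list of H x W x 3 arrays, keyed by `image_id`.
#' @param annotations Annotation data.frame
#'   (`image_id, x0, y0, x1, y1, label`).
#' @param params A [chop_params()].
#' @return A `cpm_patchset` (possibly empty).
#' @export
build_patchset <- function(images, annotations, params = chop_params()) {
  p <- params$patch_px
  if (nrow(annotations) == 0L)
    return(.new_patchset(matrix(0, 3L * p * p, 0L), logical(0),
                         data.frame(image_id = character(0), x = integer(0),
                                    y = integer(0)), p))
  absent <- setdiff(unique(annotations$image_id), names(images))
  if (length(absent) > 0L)
    stop("annotations reference absent images: ",
         paste(absent, collapse = ", "))
  sets <- lapply(seq_len(nrow(annotations)), function(i)
    chop_rectangle(images[[annotations$image_id[i]]],
                   annotations[i, , drop = FALSE], params))
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) == 0L)
    return(.new_patchset(matrix(0, 3L * p * p, 0L), logical(0),
                         data.frame(image_id = character(0), x = integer(0),
                                    y = integer(0)), p))
  combine_patchsets(sets)
}

#' Screen patches against a ground-truth mask
#'
#' Automatic counterpart of manually discarding chopped patches whose
#' area is mostly covered by the wrong class: a positive patch is kept
#' only when its greenery pixel fraction strictly exceeds `occupancy`, a
#' negative patch only when the fraction is strictly below
#' `1 - occupancy`. Only available when per-pixel masks exist (synthetic
#' data); real rectangle labels are otherwise trusted as-is.
#'
#' @param patchset A `cpm_patchset`.
#' @param masks Named list of logical masks keyed by `image_id`.
#' @param occupancy Fraction (default 0.5).
#' @return The filtered `cpm_patchset`.
#' @export
screen_patchset <- function(patchset, masks, occupancy = 0.5) {
  p <- patchset$patch_px
  keep <- vapply(seq_along(patchset$label), function(k) {
    src <- patchset$source[k, ]
    m <- masks[[src$image_id]]
    if (is.null(m)) stop("no mask for image ", src$image_id)
    f <- mean(m[(src$y + 1L):(src$y + p), (src$x + 1L):(src$x + p)])
    if (patchset$label[k]) f > occupancy else f < 1 - occupancy
  }, logical(1))
  patchset[keep]
}

#' Read / write rectangle annotations as CSV
#'
#' Plain CSV with header `image_id,x0,y0,x1,y1,label` (0-based half-open
#' boxes, label 0/1).
#'
#' @param path CSV path.
#' @return `read_annotations` returns the annotation data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x0", "y0", "x1", "y1", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns ", paste(need, collapse = ","))
  df$label <- as.logical(df$label)
  df[need]
}

#' @rdname read_annotations
#' @param annotations Annotation data.frame.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  out$label <- as.integer(out$label)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a patch archive (directory of PNG tiles + index CSV)
#'
#' @param patchset A `cpm_patchset`.
#' @param dir Archive directory.
#' @return `write_patch_archive` returns `dir` invisibly;
#'   `read_patch_archive` returns the reconstructed `cpm_patchset`.
#' @export
write_patch_archive <- function(patchset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- patchset$patch_px
  n <- length(patchset$label)
  files <- sprintf("patch_%06d.png", seq_len(n))
  for (k in seq_len(n)) {
    png::writePNG(array(patchset$pixels[, k], c(p, p, 3)),
                  file.path(dir, files[k]))
  }
  idx <- cbind(file = files, patchset$source,
               label = as.integer(patchset$label))
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_patch_archive
#' @export
read_patch_archive <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  if (nrow(idx) == 0L) stop("empty patch archive: ", dir)
  first <- png::readPNG(file.path(dir, idx$file[1]))
  p <- dim(first)[1]
  pix <- matrix(0, 3L * p * p, nrow(idx))
  for (k in seq_len(nrow(idx)))
    pix[, k] <- as.vector(png::readPNG(file.path(dir, idx$file[k]))[, , 1:3])
  .new_patchset(pix, as.logical(idx$label),
                data.frame(image_id = idx$image_id, x = idx$x, y = idx$y,
                           stringsAsFactors = FALSE),
                p)
}
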