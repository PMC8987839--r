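# Shared fixtures, all built in code at test time.

# Pure-colour patches: solid green vs solid gray (+ tiny noise so every
# patch is unique). Linearly separable by mean colour alone.
make_color_patchset <- function(n, seed = 1, patch_px = 32L) {
  set.seed(seed)
  d <- 3L * patch_px^2
  half <- n %/% 2L
  mk <- function(col) pmin(pmax(
    as.vector(outer(rep(1, patch_px^2), col)) + rnorm(d, 0, 0.01), 0), 1)
  px <- cbind(vapply(seq_len(half), function(i) mk(c(0.1, 0.6, 0.1)), numeric(d)),
              vapply(seq_len(n - half), function(i) mk(c(0.5, 0.5, 0.5)), numeric(d)))
  greenview:::.new_patchset(
    px, rep(c(TRUE, FALSE), c(half, n - half)),
    data.frame(image_id = "synthetic", x = 0L, y = 0L)[rep(1L, n), ],
    patch_px)
}

# Texture-only patches: same base green, label carried by high-frequency
# multiplicative luminance noise (vegetation) vs a flat surface
# (artificial green). Mean colour is uninformative by construction.
make_texture_patchset <- function(n, seed = 1, patch_px = 32L) {
  set.seed(seed)
  d <- 3L * patch_px^2
  half <- n %/% 2L
  base <- c(0.15, 0.5, 0.15)
  mk_tex <- function() pmin(pmax(
    as.vector(outer(1 + 0.25 * rnorm(patch_px^2), base)), 0), 1)
  mk_flat <- function() pmin(pmax(
    as.vector(outer(rep(1, patch_px^2), base)) + rnorm(d, 0, 0.005), 0), 1)
  px <- cbind(vapply(seq_len(half), function(i) mk_tex(), numeric(d)),
              vapply(seq_len(n - half), function(i) mk_flat(), numeric(d)))
  greenview:::.new_patchset(
    px, rep(c(TRUE, FALSE), c(half, n - half)),
    data.frame(image_id = "synthetic", x = 0L, y = 0L)[rep(1L, n), ],
    patch_px)
}

# Small-but-real training configuration for fast unit tests.
tiny_config <- function(epochs = 4L, seed = 1L, ...) {
  cpm_config(epochs = epochs, filters = c(8L, 16L), dense_units = 32L,
             seed = seed, ...)
}

# A quick fitted model shared across tests that only need *a* model.
fit_tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- cpm_train(make_color_patchset(160, seed = 5), tiny_config())
    cache
  }
})

# Brute-force sliding-window patch count (independent of the closed form).
brute_chop_count <- function(w, h, p, s) {
  n <- 0L
  x <- 0L
  while (x + p <= w) {
    y <- 0L
    while (y + p <= h) { n <- n + 1L; y <- y + s }
    x <- x + s
  }
  n
}

# Brute-force occupancy grid: explicit per-cell double loop.
brute_grid <- function(mask, cell_px, thr = 0.5) {
  gr <- nrow(mask) %/% cell_px
  gc <- ncol(mask) %/% cell_px
  out <- matrix(FALSE, gr, gc)
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    cell <- mask[((i - 1) * cell_px + 1):(i * cell_px),
                 ((j - 1) * cell_px + 1):(j * cell_px)]
    out[i, j] <- mean(cell) > thr
  }
  out
}

# Stub probability models for classify_grid.
stub_model <- function(prob) function(pixels, source) rep(prob, ncol(pixels))

# Oracle model: per-cell ground-truth occupancy lookup via cell coords.
oracle_model <- function(mask, cell_px = 32L) {
  function(pixels, source) {
    vapply(seq_len(nrow(source)), function(k) {
      x <- source$x[k]; y <- source$y[k]
      mean(mask[(y + 1):(y + cell_px), (x + 1):(x + cell_px)])
    }, numeric(1))
  }
}
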