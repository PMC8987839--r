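test_that("minimal, overlapping and degenerate rectangles chop correctly", {
  img <- array(runif(100 * 100 * 3), c(100, 100, 3))

  one <- chop_rectangle(img, rect_annotation("a", 0, 0, 32, 32, TRUE))
  expect_equal(length(one), 1L)
  expect_identical(one$pixels[, 1], as.vector(img[1:32, 1:32, ]))

  nine <- chop_rectangle(img, rect_annotation("a", 4, 8, 68, 72, TRUE))
  expect_equal(length(nine), 9L)  # 64x64 at p=32, s=16 -> 3x3

  none <- chop_rectangle(img, rect_annotation("a", 0, 0, 31, 100, FALSE))
  expect_equal(length(none), 0L)
})

test_that("closed-form patch counts match brute-force enumeration with containment", {
  set.seed(101)
  img <- array(runif(220 * 220 * 3), c(220, 220, 3))
  params <- chop_params(32, 16)
  for (k in seq_len(200)) {
    w <- sample(10:200, 1); h <- sample(10:200, 1)
    x0 <- sample(0:(220 - w), 1); y0 <- sample(0:(220 - h), 1)
    rect <- rect_annotation("a", x0, y0, x0 + w, y0 + h, k %% 2 == 0)
    ps <- chop_rectangle(img, rect, params)
    expect_equal(length(ps), brute_chop_count(w, h, 32, 16))
    if (length(ps) > 0) {
      # containment: every tile inside its rectangle
      expect_true(all(ps$source$x >= x0 & ps$source$x + 32 <= x0 + w))
      expect_true(all(ps$source$y >= y0 & ps$source$y + 32 <= y0 + h))
      # label conservation
      expect_true(all(ps$label == rect$label))
    }
  }
})

test_that("patches inherit pixels from their exact tile position", {
  img <- array(runif(80 * 80 * 3), c(80, 80, 3))
  ps <- chop_rectangle(img, rect_annotation("a", 16, 8, 80, 72, TRUE))
  k <- sample(length(ps), 1)
  x <- ps$source$x[k]; y <- ps$source$y[k]
  expect_identical(ps$pixels[, k],
                   as.vector(img[(y + 1):(y + 32), (x + 1):(x + 32), ]))
})

test_that("rectangles outside the image are rejected by name", {
  img <- array(0.5, c(64, 64, 3))
  expect_error(
    chop_rectangle(img, rect_annotation("cam7", 40, 0, 72, 32, TRUE)),
    "cam7")
})

test_that("patchset assembly tallies classes over annotations in stable order", {
  imgs <- list(a = array(runif(64 * 64 * 3), c(64, 64, 3)),
               b = array(runif(96 * 96 * 3), c(96, 96, 3)))
  ann <- rbind(rect_annotation("a", 0, 0, 32, 32, TRUE),
               rect_annotation("b", 0, 0, 32, 32, FALSE),
               rect_annotation("b", 0, 0, 96, 96, TRUE))
  ps <- build_patchset(imgs, ann)
  counts <- c(1L, 1L, brute_chop_count(96, 96, 32, 16))
  expect_equal(length(ps), sum(counts))
  expect_equal(sum(ps$label), counts[1] + counts[3])
  expect_equal(sum(!ps$label), counts[2])
  # stable order: annotation order, then row-major tiles
  expect_identical(ps$source$image_id[1:2], c("a", "b"))

  empty <- build_patchset(imgs, ann[0, ])
  expect_equal(length(empty), 0L)

  expect_error(build_patchset(imgs["a"], ann), "b")
})

test_that("mask-based screening discards patches mostly covered by the wrong class", {
  img <- array(0.5, c(64, 96, 3))
  mask <- matrix(FALSE, 64, 96)
  mask[, 1:48] <- TRUE  # left half greenery
  # a rectangle straddling the boundary, labelled greenery
  ps <- build_patchset(list(s = img),
                       rect_annotation("s", 0, 0, 96, 64, TRUE))
  kept <- screen_patchset(ps, list(s = mask))
  # retained tiles must genuinely be majority-green
  p <- ps$patch_px
  for (k in seq_len(length(kept))) {
    f <- mean(mask[(kept$source$y[k] + 1):(kept$source$y[k] + p),
                   (kept$source$x[k] + 1):(kept$source$x[k] + p)])
    expect_gt(f, 0.5)
  }
  expect_lt(length(kept), length(ps))
})

test_that("annotation CSV round trips", {
  ann <- rbind(rect_annotation("img1", 0, 4, 64, 68, TRUE),
               rect_annotation("img2", 10, 20, 42, 52, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_identical(read_annotations(path), ann)
})

test_that("patch archives round trip exactly", {
  fx <- generate_scene(random_scene_spec(3, width = 96, height = 96))
  ps <- chop_rectangle(fx$image, rect_annotation("s", 0, 0, 96, 96, TRUE))
  dir <- withr::local_tempdir()
  write_patch_archive(ps, dir)
  back <- read_patch_archive(dir)
  expect_equal(back$pixels, ps$pixels, tolerance = 1e-12)
  expect_identical(back$label, ps$label)
  expect_identical(back$source$x, ps$source$x)
})

test_that("chop parameters are validated", {
  expect_error(chop_params(32, 0), "stride")
  expect_error(chop_params(32, 33), "stride")
  expect_error(rect_annotation("a", 10, 0, 10, 5, TRUE), "x1 > x0")
})
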