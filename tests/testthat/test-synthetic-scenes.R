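test_that("full and empty greenery coverage produce all-true / all-false masks", {
  full <- generate_scene(scene_spec(
    list(region_spec("vegetation", c(0, 0, 64, 64))),
    width = 64, height = 64, seed = 1))
  expect_true(all(full$mask))

  none <- generate_scene(scene_spec(
    list(region_spec("sky", c(0, 0, 64, 32)),
         region_spec("building", c(0, 32, 64, 64))),
    width = 64, height = 64, seed = 1))
  expect_false(any(none$mask))
})

test_that("identical spec and seed render byte-identical scenes", {
  sp <- random_scene_spec(17, width = 160, height = 160)
  fx1 <- generate_scene(sp)
  fx2 <- generate_scene(sp)
  expect_identical(fx1$image, fx2$image)
  expect_identical(fx1$mask, fx2$mask)
  expect_identical(fx1$category, fx2$category)
})

test_that("later regions overwrite earlier ones in image and mask", {
  sp <- scene_spec(list(
    region_spec("vegetation", c(0, 0, 96, 96)),
    region_spec("artificial_green", c(32, 32, 64, 64))),
    width = 96, height = 96, seed = 2)
  fx <- generate_scene(sp)
  # independent per-pixel oracle: replay the painting order on geometry
  oracle <- matrix(FALSE, 96, 96)
  for (r in sp$regions) {
    b <- r$box
    oracle[(b[2] + 1):b[4], (b[1] + 1):b[3]] <-
      r$category %in% c("vegetation", "shadow_vegetation")
  }
  expect_identical(fx$mask, oracle)
  expect_false(any(fx$mask[33:64, 33:64]))
})

test_that("mask fraction equals the area-weighted union of green regions", {
  sp <- scene_spec(list(
    region_spec("building", c(0, 0, 80, 80)),
    region_spec("vegetation", c(0, 0, 40, 80)),       # 3200 px
    region_spec("shadow_vegetation", c(20, 0, 60, 40)), # adds [40,60)x[0,40)
    region_spec("road", c(0, 60, 80, 80))),            # erases [0,60) rows? no: y 60..80
    width = 80, height = 80, seed = 3)
  fx <- generate_scene(sp)
  # brute-force per-pixel union with overwrite resolution
  expected <- 0L
  for (x in 0:79) for (y in 0:79) {
    cat_last <- NA_character_
    for (r in sp$regions) {
      b <- r$box
      if (x >= b[1] && x < b[3] && y >= b[2] && y < b[4]) cat_last <- r$category
    }
    if (!is.na(cat_last) && cat_last %in% c("vegetation", "shadow_vegetation"))
      expected <- expected + 1L
  }
  expect_identical(sum(fx$mask), expected)
})

test_that("rendered texture separates vegetation from artificial green", {
  fx <- generate_scene(scene_spec(list(
    region_spec("vegetation", c(0, 0, 64, 64)),
    region_spec("artificial_green", c(64, 0, 128, 64))),
    width = 128, height = 64, seed = 4))
  g_veg <- fx$image[, 1:64, 2]
  g_art <- fx$image[, 65:128, 2]
  expect_gt(sd(g_veg), 5 * sd(g_art))  # high-frequency vs near-uniform
})

test_that("shadowed vegetation is vegetation darkened by a factor in [0.3, 0.6]", {
  base <- c(0.2, 0.45, 0.16)
  fx <- generate_scene(scene_spec(list(
    region_spec("vegetation", c(0, 0, 64, 64), base_color = base),
    region_spec("shadow_vegetation", c(64, 0, 128, 64), base_color = base)),
    width = 128, height = 64, seed = 6))
  expect_true(all(fx$mask))
  ratio <- mean(fx$image[, 65:128, ]) / mean(fx$image[, 1:64, ])
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.65)
})

test_that("region boxes outside the canvas are rejected", {
  expect_error(scene_spec(list(region_spec("vegetation", c(0, 0, 65, 64))),
                          width = 64, height = 64),
               "outside")
})

test_that("occupancy grid follows the strict majority rule", {
  # exactly half the cell green -> negative ("more than a half" is strict)
  m <- matrix(FALSE, 32, 32)
  m[1:16, ] <- TRUE  # 512 of 1024 pixels
  expect_false(mask_to_grid_labels(m)[1, 1])
  m[17, 1] <- TRUE   # 513 of 1024
  expect_true(mask_to_grid_labels(m)[1, 1])

  # left half of a 64x64 mask -> left grid column positive
  m2 <- matrix(FALSE, 64, 64)
  m2[, 1:32] <- TRUE
  expect_identical(mask_to_grid_labels(m2),
                   matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))

  m3 <- matrix(TRUE, 640, 640)
  g3 <- mask_to_grid_labels(m3)
  expect_identical(dim(g3), c(20L, 20L))
  expect_true(all(g3))
})

test_that("grid truncation and labels match a brute-force per-cell loop", {
  set.seed(31)
  for (dims in list(c(64, 64), c(70, 97), c(33, 129), c(96, 65))) {
    mask <- matrix(runif(dims[1] * dims[2]) < 0.5, dims[1], dims[2])
    got <- mask_to_grid_labels(mask, cell_px = 32)
    expect_identical(dim(got), as.integer(dims %/% 32))
    expect_identical(got, brute_grid(mask, 32))
  }
  expect_error(mask_to_grid_labels(matrix(TRUE, 10, 10), cell_px = 0), "cell_px")
  expect_error(mask_to_grid_labels(matrix(TRUE, 10, 10), cell_px = 32), "smaller")
})

test_that("derived annotations meet their purity when re-measured", {
  fx <- generate_scene(scene_spec(list(
    region_spec("building", c(0, 0, 256, 256)),
    region_spec("vegetation", c(0, 0, 128, 256))),
    width = 256, height = 256, seed = 9))
  ann <- scene_to_annotations(fx, n_positive = 3, n_negative = 5,
                              min_side = 32, max_side = 96, seed = 4,
                              image_id = "fx")
  expect_equal(nrow(ann), 8L)
  expect_equal(sum(ann$label), 3L)
  for (k in seq_len(nrow(ann))) {
    f <- mean(fx$mask[(ann$y0[k] + 1):ann$y1[k], (ann$x0[k] + 1):ann$x1[k]])
    if (ann$label[k]) expect_gte(f, 0.9) else expect_lte(f, 0.1)
  }
  # deterministic per seed
  ann2 <- scene_to_annotations(fx, 3, 5, min_side = 32, max_side = 96,
                               seed = 4, image_id = "fx")
  expect_identical(ann, ann2)
})

test_that("infeasible annotation requests fail naming the class", {
  all_green <- generate_scene(scene_spec(
    list(region_spec("vegetation", c(0, 0, 64, 64))),
    width = 64, height = 64, seed = 1))
  expect_error(scene_to_annotations(all_green, 1, 1, seed = 1), "negative")
})

test_that("scene fixtures round-trip through PNG files", {
  fx <- generate_scene(random_scene_spec(23, width = 128, height = 128))
  dir <- withr::local_tempdir()
  write_scene_fixture(fx, dir, "s1")
  img <- read_image(file.path(dir, "s1.png"))
  expect_equal(img, fx$image, tolerance = 1e-12)  # image pre-quantised to 255ths
  mask <- png::readPNG(file.path(dir, "s1_mask.png")) > 0.5
  expect_identical(unname(mask), unname(fx$mask))
  expect_true(file.exists(file.path(dir, "s1.yml")))
})
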