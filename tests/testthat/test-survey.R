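# Builds a tiny on-disk survey: a textured scene, its byte-identical
# duplicate, and a uniform (blank) frame.
make_survey <- function(dir) {
  fx <- generate_scene(random_scene_spec(40, width = 96, height = 96))
  p1 <- file.path(dir, "a.png"); png::writePNG(fx$image, p1)
  p2 <- file.path(dir, "b.png"); file.copy(p1, p2)
  p3 <- file.path(dir, "c.png")
  png::writePNG(array(0.5, c(96, 96, 3)), p3)
  data.frame(image_id = c("a", "b", "c"), district_id = "D1",
             lat = 35, lon = 135.7, heading = c(0, 90, 180),
             path = c(p1, p2, p3), stringsAsFactors = FALSE)
}

test_that("duplicate and blank images are dropped with reasons", {
  man <- make_survey(withr::local_tempdir())
  res <- filter_images(man)
  expect_identical(res$kept$image_id, "a")
  expect_identical(res$dropped$reason[res$dropped$image_id == "b"], "duplicate")
  expect_identical(res$dropped$reason[res$dropped$image_id == "c"], "blank")
  # count conservation
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(man))
  # idempotence
  again <- filter_images(res$kept)
  expect_equal(nrow(again$dropped), 0L)
  expect_identical(again$kept$image_id, res$kept$image_id)
})

test_that("the manual exclude list and unreadable files are handled", {
  man <- make_survey(withr::local_tempdir())
  res <- filter_images(man, exclude = "a")
  expect_identical(res$dropped$reason[res$dropped$image_id == "a"], "excluded")
  man$path[1] <- file.path(dirname(man$path[1]), "missing.png")
  expect_error(filter_images(man), "missing.png")
})

test_that("manifests validate their headings", {
  man <- make_survey(withr::local_tempdir())
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, path)
  expect_identical(read_manifest(path)$image_id, man$image_id)
  man$heading[1] <- 45
  write_manifest(man, path)
  expect_error(read_manifest(path), "45")
})

test_that("district aggregation pools image GVIs and applies the minimum count", {
  gvis <- data.frame(
    image_id = sprintf("i%02d", 1:21),
    district_id = rep(c("D1", "D2", "D3"), c(2, 9, 10)),
    gvi_percent = c(10, 20, rep(5, 9), rep(12.5, 10)))
  two <- aggregate_districts(gvis, min_images = 2)
  expect_equal(two$mean_gvi[two$district_id == "D1"], 15)

  # the mapping rule: fewer than 10 images -> excluded
  ten <- aggregate_districts(gvis, min_images = 10)
  expect_identical(ten$district_id, "D3")
  expect_equal(ten$n_images, 10L)
  expect_equal(ten$mean_gvi, 12.5)  # identical image GVIs -> same mean

  expect_equal(nrow(aggregate_districts(gvis[0, ])), 0L)
})

test_that("district means are bounded by the per-image extremes", {
  set.seed(55)
  gvis <- data.frame(
    image_id = sprintf("i%03d", 1:60),
    district_id = sample(c("A", "B", "C"), 60, replace = TRUE),
    gvi_percent = runif(60, 0, 100))
  agg <- aggregate_districts(gvis, min_images = 1)
  for (k in seq_len(nrow(agg))) {
    v <- gvis$gvi_percent[gvis$district_id == agg$district_id[k]]
    expect_gte(agg$mean_gvi[k], min(v))
    expect_lte(agg$mean_gvi[k], max(v))
  }
  # sorted output
  expect_identical(agg$district_id, sort(agg$district_id))
})

poly_feature <- function(id, ring) {
  list(type = "Feature",
       properties = list(district_id = id),
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

test_that("district GVI exports to GeoJSON with a CSV twin", {
  districts <- data.frame(district_id = c("D1", "D2"), n_images = c(12L, 30L),
                          mean_gvi = c(16.254, 4.7), stringsAsFactors = FALSE)
  fc <- list(type = "FeatureCollection", features = list(
    poly_feature("D1", list(c(135.7, 35), c(135.8, 35), c(135.8, 35.1),
                            c(135.7, 35))),
    poly_feature("D2", list(c(135.5, 35), c(135.6, 35), c(135.6, 35.1),
                            c(135.5, 35)))))
  gj <- withr::local_tempfile(fileext = ".geojson")
  csv <- withr::local_tempfile(fileext = ".csv")
  jsonlite::write_json(fc, withr::local_tempfile(fileext = ".json"))
  out <- export_district_gvi(districts, fc, geojson_path = gj, csv_path = csv)
  expect_length(out$features, 2L)

  back <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  props <- back$features[[1]]$properties
  expect_identical(props$district_id, "D1")
  expect_equal(props$n_images, 12L)
  expect_equal(props$mean_gvi, 16.254)
  # CSV twin rounds to 2 decimals at the I/O boundary
  twin <- read.csv(csv)
  expect_equal(twin$mean_gvi, c(16.25, 4.7))
})

test_that("districts without polygons stay in the CSV and are warned about", {
  districts <- data.frame(district_id = c("D1", "D9"), n_images = c(10L, 11L),
                          mean_gvi = c(8, 9), stringsAsFactors = FALSE)
  fc <- list(type = "FeatureCollection", features = list(
    poly_feature("D1", list(c(0, 0), c(1, 0), c(1, 1), c(0, 0)))))
  csv <- withr::local_tempfile(fileext = ".csv")
  expect_warning(out <- export_district_gvi(districts, fc, csv_path = csv),
                 "D9")
  expect_length(out$features, 1L)
  expect_equal(nrow(read.csv(csv)), 2L)

  expect_error(export_district_gvi(districts, list(type = "nope")),
               "malformed")
})
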