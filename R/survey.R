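# Survey management: image manifest, exclusion rules, district-level
# aggregation and mappable export.

#' Read / write a survey manifest
#'
#' CSV with header `image_id,district_id,lat,lon,heading,path`. Headings
#' are the four cardinal camera angles 0/90/180/270.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "district_id", "lat", "lon", "heading", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  bad <- !df$heading %in% c(0, 90, 180, 270)
  if (any(bad))
    stop("invalid headings (must be 0/90/180/270): ",
         paste(unique(df$heading[bad]), collapse = ", "))
  df <- df[need]
  # relative image paths are relative to the manifest file
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' @rdname read_manifest
#' @param manifest Manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Apply the survey exclusion rules
#'
#' Drops exact byte-duplicates (content hash; the first occurrence in
#' manifest order is kept) and blank images (every channel's pixel
#' standard deviation below `blank_sd` on the 0-255 scale). An optional
#' exclude list stands in for manual removal of blurred images.
#'
#' @param manifest Manifest data.frame with a `path` column.
#' @param blank_sd Blankness threshold (default 1.0 gray levels).
#' @param exclude Character vector of `image_id`s to drop manually.
#' @return List with `kept` (manifest rows) and `dropped` (rows plus a
#'   `reason` column: `"duplicate"`, `"blank"` or `"excluded"`).
#' @export
filter_images <- function(manifest, blank_sd = 1.0, exclude = character(0)) {
  n <- nrow(manifest)
  reason <- rep(NA_character_, n)
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("unreadable image files: ",
         paste(manifest$path[missing], collapse = ", "))
  hashes <- unname(tools::md5sum(manifest$path))
  dup <- duplicated(hashes)
  reason[dup] <- "duplicate"
  for (i in which(!dup)) {
    if (manifest$image_id[i] %in% exclude) { reason[i] <- "excluded"; next }
    img <- read_image(manifest$path[i])
    sds <- apply(img, 3, sd) * 255
    if (all(sds < blank_sd)) reason[i] <- "blank"
  }
  kept <- manifest[is.na(reason), , drop = FALSE]
  dropped <- manifest[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  list(kept = kept, dropped = dropped)
}

#' Aggregate per-image GVI to district level
#'
#' Unweighted mean of the per-image GVI over all images pooled within a
#' district; districts with fewer than `min_images` images are excluded
#' from the output (the mapping rule: at least 10 images per district).
#'
#' @param image_gvis Data.frame with columns `image_id, district_id,
#'   gvi_percent`.
#' @param min_images Minimum image count per district (default 10).
#' @return Data.frame `district_id, n_images, mean_gvi`, sorted by
#'   district id; empty input gives an empty frame.
#' @export
aggregate_districts <- function(image_gvis, min_images = 10L) {
  empty <- data.frame(district_id = character(0), n_images = integer(0),
                      mean_gvi = numeric(0), stringsAsFactors = FALSE)
  if (nrow(image_gvis) == 0L) return(empty)
  counts <- table(image_gvis$district_id)
  means <- tapply(image_gvis$gvi_percent, image_gvis$district_id, mean)
  ids <- sort(names(counts))
  out <- data.frame(district_id = ids,
                    n_images = as.integer(counts[ids]),
                    mean_gvi = as.numeric(means[ids]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_images >= min_images, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export district GVI as GeoJSON and CSV
#'
#' Joins district means onto boundary polygons by `district_id` and
#' writes a GeoJSON FeatureCollection (one feature per district with
#' properties `district_id`, `n_images`, `mean_gvi`) plus a flat CSV
#' twin. Districts without a polygon still appear in the CSV; a warning
#' names them.
#'
#' @param districts Data.frame from [aggregate_districts()].
#' @param polygons Path to a GeoJSON FeatureCollection whose features
#'   carry a `district_id` property, or the equivalent parsed list.
#' @param geojson_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the feature list written.
#' @export
export_district_gvi <- function(districts, polygons, geojson_path = NULL,
                                csv_path = NULL) {
  if (is.character(polygons))
    polygons <- jsonlite::fromJSON(polygons, simplifyVector = FALSE)
  if (!identical(polygons$type, "FeatureCollection") ||
      is.null(polygons$features))
    stop("malformed boundary file: expected a GeoJSON FeatureCollection")
  poly_ids <- vapply(polygons$features, function(f)
    as.character(f$properties$district_id %||% NA_character_), character(1))
  feats <- list()
  for (i in seq_len(nrow(districts))) {
    k <- match(districts$district_id[i], poly_ids)
    if (is.na(k)) next
    f <- polygons$features[[k]]
    f$properties <- list(district_id = districts$district_id[i],
                         n_images = districts$n_images[i],
                         mean_gvi = districts$mean_gvi[i])
    feats[[length(feats) + 1L]] <- f
  }
  missing <- setdiff(districts$district_id, poly_ids)
  if (length(missing) > 0L)
    warning("no boundary polygon for district(s): ",
            paste(missing, collapse = ", "))
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(geojson_path))
    jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    out <- districts
    out$mean_gvi <- round(out$mean_gvi, 2)
    write.csv(out, csv_path, row.names = FALSE)
  }
  invisible(fc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
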