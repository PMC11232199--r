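# File I/O: slides as RGB TIFF, masks as single-channel 8-bit PNG,
# annotations as QuPath-dialect GeoJSON, stain statistics as YAML,
# cohort manifests and reports as CSV.

#' Read and write slide images (RGB TIFF)
#'
#' Intensities are stored 8-bit; [normalize_stain()] output (continuous,
#' possibly slightly out of range) is clipped and rounded on write.
#'
#' @param image H x W x 3 array, 0-255.
#' @param path file path.
#' @return `read_slide_tiff()` returns an integer H x W x 3 array.
#' @export
write_slide_tiff <- function(image, path) {
  tiff::writeTIFF(clip255(image) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_slide_tiff
#' @export
read_slide_tiff <- function(path) {
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3L))
  array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3L))
}

#' Read and write label masks (single-channel 8-bit PNG)
#'
#' Class indices 0-9 and the ignore label 255 are stored as gray levels.
#'
#' @param mask integer H x W matrix with values 0-255.
#' @param path file path.
#' @return `read_mask_png()` returns an integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

# Circle approximation used when writing disc strokes as polygons.
disc_polygon <- function(row, col, radius, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = col - 0.5 + radius * cos(th), y = row - 0.5 + radius * sin(th))
}

#' Write annotations as a QuPath-dialect GeoJSON FeatureCollection
#'
#' Each feature is a Polygon with a `classification` property carrying the
#' class name, the dialect QuPath uses for its annotation exports. Stroke
#' tables (from [sparse_annotations()]) are written as circle polygons;
#' border polygons are written verbatim.
#'
#' @param strokes tibble with `class_index`, `row`, `col`, `radius` (or the
#'   sparse grid carrying it as the `strokes` attribute), or `NULL`.
#' @param polygons named list of vertex matrices to include (name = class),
#'   e.g. `list(tumor_border = slide$tumor_border)`.
#' @param path file path.
#' @param schema a [tme_schema()].
#' @return the path, invisibly.
#' @export
write_annotations_geojson <- function(strokes = NULL, polygons = NULL, path,
                                      schema = tme_schema()) {
  if (is.matrix(strokes) && !is.null(attr(strokes, "strokes"))) {
    strokes <- attr(strokes, "strokes")
  }
  features <- list()
  if (!is.null(strokes) && nrow(strokes)) {
    for (i in seq_len(nrow(strokes))) {
      nm <- schema$classes$fine[match(strokes$class_index[i],
                                      schema$classes$index)]
      poly <- disc_polygon(strokes$row[i], strokes$col[i], strokes$radius[i])
      features[[length(features) + 1L]] <- geojson_feature(poly, nm)
    }
  }
  if (!is.null(polygons)) {
    for (nm in names(polygons)) {
      features[[length(features) + 1L]] <- geojson_feature(polygons[[nm]], nm)
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 4)
  invisible(path)
}

geojson_feature <- function(poly, class_name) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(unname(split(ring, row(ring))) |>
                                         lapply(as.numeric))),
    properties = list(objectType = "annotation",
                      classification = list(name = class_name))
  )
}

#' Read a QuPath-dialect GeoJSON annotation file
#'
#' @param path file path.
#' @return tibble with `class_name` and a `polygon` list-column of vertex
#'   matrices (columns x, y).
#' @export
read_annotations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(ft) {
    coords <- ft$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))))
    colnames(xy) <- c("x", "y")
    tibble::tibble(class_name = ft$properties$classification$name %||% NA_character_,
                   polygon = list(xy))
  })
  dplyr::bind_rows(rows)
}

#' Rasterize GeoJSON annotations into a sparse label grid
#'
#' @param features tibble from [read_annotations_geojson()].
#' @param h,w output size in pixels.
#' @param schema a [tme_schema()].
#' @return integer H x W sparse label grid (`ignore_index` elsewhere).
#' @export
rasterize_annotations <- function(features, h, w, schema = tme_schema()) {
  out <- matrix(schema$ignore_index, h, w)
  for (i in seq_len(nrow(features))) {
    k <- schema$classes$index[match(features$class_name[i], schema$classes$fine)]
    if (is.na(k)) next
    sel <- rasterize_polygon(features$polygon[[i]], h, w)
    out[sel] <- k
  }
  out
}

#' Write and read stain statistics as YAML
#' @param stats a [stain_stats()] tibble.
#' @param path file path.
#' @return `read_stain_stats()` returns a `stain_stats` tibble.
#' @export
write_stain_stats <- function(stats, path) {
  yaml::write_yaml(list(channel = stats$channel, mean = stats$mean,
                        sd = stats$sd), path, precision = 12L)
  invisible(path)
}

#' @rdname write_stain_stats
#' @export
read_stain_stats <- function(path) {
  y <- yaml::read_yaml(path)
  st <- tibble::tibble(channel = unlist(y$channel),
                       mean = as.numeric(unlist(y$mean)),
                       sd = as.numeric(unlist(y$sd)))
  class(st) <- c("stain_stats", class(st))
  st
}
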