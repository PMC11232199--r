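#' Foreground (tissue vs glass) segmentation
#'
#' CLAM-style thresholding foreground segmentation: the image is converted to
#' HSV, the saturation channel is median-filtered, thresholded (Otsu by
#' default, or a fixed threshold for strict reproducibility), morphologically
#' closed, and connected components below a minimum area are dropped.
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param sat_threshold fixed saturation threshold in \[0, 1\]; `NULL`
#'   (default) uses Otsu on the filtered saturation channel.
#' @param median_radius half-width of the median filter window (pixels).
#' @param close_size diameter of the disc structuring element for closing.
#' @param min_area minimum connected-component area (pixels) to retain.
#' @return logical H x W matrix, `TRUE` = tissue. A fully blank image yields
#'   an all-`FALSE` mask.
#' @export
segment_foreground <- function(image, sat_threshold = NULL,
                               median_radius = 2L, close_size = 5L,
                               min_area = 64L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- matrix(aperm(image, c(3, 1, 2)), nrow = 3)
  sat <- matrix(grDevices::rgb2hsv(rgb, maxColorValue = 255)[2, ], h, w)
  sat <- EBImage::medianFilter(sat, median_radius)
  if (is.null(sat_threshold)) {
    if (max(sat) - min(sat) < 1e-3) return(matrix(FALSE, h, w))
    sat_threshold <- EBImage::otsu(sat, range = range(sat))
  }
  mask <- sat > sat_threshold
  if (!any(mask)) return(mask)
  mask <- EBImage::closing(mask, EBImage::makeBrush(close_size, "disc")) > 0
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, h, w)
}

#' Regular tile grid over a slide
#'
#' Non-overlapping `tile_size` x `tile_size` boxes anchored at the origin,
#' half-open `[r0, r1) x [c0, c1)` in 0-based full-resolution pixel
#' coordinates, row-major order. Partial tiles at the bottom/right edge are
#' discarded so every tile has a uniform shape.
#'
#' @param mask a matrix (only its dimensions are used) or an integer vector
#'   `c(height, width)`.
#' @param tile_size tile edge in pixels (default 512).
#' @return tibble with columns `tile_id, r0, r1, c0, c1`.
#' @examples
#' nrow(tile_grid(c(1024, 1024), 512)) # 4
#' @export
tile_grid <- function(mask, tile_size = 512L) {
  stopifnot(tile_size >= 1)
  dims <- if (is.matrix(mask)) dim(mask) else as.integer(mask[1:2])
  tile_size <- as.integer(tile_size)
  nr <- dims[1] %/% tile_size
  nc <- dims[2] %/% tile_size
  if (nr == 0L || nc == 0L) {
    return(tibble::tibble(tile_id = integer(), r0 = integer(), r1 = integer(),
                          c0 = integer(), c1 = integer()))
  }
  g <- expand.grid(c0 = (seq_len(nc) - 1L) * tile_size,
                   r0 = (seq_len(nr) - 1L) * tile_size)
  tibble::tibble(
    tile_id = seq_len(nrow(g)),
    r0 = g$r0, r1 = g$r0 + tile_size,
    c0 = g$c0, c1 = g$c0 + tile_size
  )
}

#' Extract, glass-filter and downsample tiles
#'
#' Computes each box's tissue fraction as the mean of the foreground mask
#' within it, removes tiles below the glass threshold (comparison is
#' inclusive: a tile exactly at the threshold is kept), and area-averages the
#' retained tile pixels by the integer downsample factor (512 px tiles at
#' factor 2 become 256 px).
#'
#' @param image H x W x 3 array, 0-255.
#' @param mask logical foreground mask from [segment_foreground()].
#' @param boxes tibble from [tile_grid()].
#' @param downsample integer downsampling factor (default 2).
#' @param glass_threshold minimum tissue fraction in \[0, 1\] (default 0.30).
#' @param slide_id,pixel_size provenance carried into the tile set.
#' @return A `tile_set`: list with `tiles` (boxes plus `tissue_fraction` and
#'   `retained`), `data` (named list of downsampled tile arrays, one per
#'   retained tile, names = tile_id), `tile_size`, `downsample`,
#'   `pixel_size_effective`, `slide_id`.
#' @export
extract_tiles <- function(image, mask, boxes, downsample = 2L,
                          glass_threshold = 0.30, slide_id = "slide",
                          pixel_size = NA_real_) {
  stopifnot(glass_threshold >= 0, glass_threshold <= 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (nrow(boxes) && (max(boxes$r1) > h || max(boxes$c1) > w || min(boxes$r0) < 0)) {
    stop("tile box outside image bounds", call. = FALSE)
  }
  tf <- vapply(seq_len(nrow(boxes)), function(i) {
    mean(mask[(boxes$r0[i] + 1L):boxes$r1[i], (boxes$c0[i] + 1L):boxes$c1[i]])
  }, numeric(1))
  tiles <- dplyr::mutate(boxes, tissue_fraction = tf,
                         retained = tf >= glass_threshold)
  data <- list()
  for (i in which(tiles$retained)) {
    sub <- image[(tiles$r0[i] + 1L):tiles$r1[i],
                 (tiles$c0[i] + 1L):tiles$c1[i], , drop = FALSE]
    data[[as.character(tiles$tile_id[i])]] <- map_channels(sub, function(m) block_mean(m, downsample))
  }
  ts <- if (nrow(boxes)) boxes$r1[1] - boxes$r0[1] else NA_integer_
  structure(
    list(tiles = tiles, data = data, tile_size = ts,
         downsample = as.integer(downsample),
         glass_threshold = glass_threshold,
         pixel_size_effective = pixel_size * downsample,
         slide_id = slide_id),
    class = "tile_set"
  )
}

#' @export
print.tile_set <- function(x, ...) {
  cat("<tile_set> ", x$slide_id, ": ", sum(x$tiles$retained), "/",
      nrow(x$tiles), " tiles retained (tile ", x$tile_size, " px, downsample x",
      x$downsample, ")\n", sep = "")
  invisible(x)
}

#' Optical density transform and its inverse
#'
#' Absorbance convention: `OD = -log10(max(I, 1) / 255)` per channel, with
#' the white point at 255 and intensities clamped to at least 1 so the
#' transform is finite and invertible. `od_inverse()` is the exact inverse on
#' the clamped domain; a round trip changes intensities by at most one unit
#' (only values below 1 are lifted to 1).
#'
#' @param image array of intensities 0-255.
#' @param od array of optical densities.
#' @return array of the same shape.
#' @examples
#' od_transform(array(255, c(1, 1, 3))) # all zero
#' @export
od_transform <- function(image) {
  -log10(pmax(image, 1) / 255)
}

#' @rdname od_transform
#' @export
od_inverse <- function(od) {
  clip255(255 * 10^(-od))
}

#' Per-channel optical density statistics over foreground pixels
#'
#' @param image H x W x 3 array, 0-255.
#' @param mask logical foreground mask.
#' @return A `stain_stats` tibble: `channel` (R, G, B), `mean`, `sd` of the
#'   optical density over foreground pixels.
#' @export
stain_stats <- function(image, mask) {
  stopifnot(any(mask))
  od <- od_transform(image)
  st <- tibble::tibble(
    channel = c("R", "G", "B"),
    mean = vapply(1:3, function(c) mean(od[, , c][mask]), numeric(1)),
    sd = vapply(1:3, function(c) stats::sd(od[, , c][mask]), numeric(1))
  )
  class(st) <- c("stain_stats", class(st))
  st
}

#' Mean/variance optical density stain normalization
#'
#' Applies the per-channel affine map `od' = (od - mu_src) / sd_src * sd_ref
#' + mu_ref` in optical density space, where the source statistics are
#' computed over foreground pixels only. Background (glass) pixels pass
#' through unchanged. The returned image is kept on the continuous 0-255
#' intensity scale (not re-quantized to integers) so the foreground OD
#' mean/sd match the reference exactly up to clipping; quantization happens
#' only when the image is written to disk.
#'
#' @param image H x W x 3 array, 0-255.
#' @param mask logical foreground mask.
#' @param reference a [stain_stats()] tibble (the normalization target).
#' @return numeric H x W x 3 array on the 0-255 scale.
#' @export
normalize_stain <- function(image, mask, reference) {
  stopifnot(inherits(reference, "stain_stats"), any(mask))
  if (any(reference$sd <= 0)) stop("reference sd must be positive", call. = FALSE)
  src <- stain_stats(image, mask)
  if (any(src$sd == 0)) {
    stop("degenerate image: zero OD variance on channel ",
         paste(src$channel[src$sd == 0], collapse = ", "), call. = FALSE)
  }
  od <- od_transform(image)
  out <- image * 1.0
  for (c in 1:3) {
    ch_od <- od[, , c]
    ch_od[mask] <- (ch_od[mask] - src$mean[c]) / src$sd[c] * reference$sd[c] + reference$mean[c]
    ch <- out[, , c]
    # continuous (unclipped) inverse so the mapped OD statistics are exact;
    # values are clipped to the displayable range only on file write
    ch[mask] <- 255 * 10^(-ch_od[mask])
    out[, , c] <- ch
  }
  out
}

#' One-call preprocessing of a slide image
#'
#' Convenience wrapper: foreground segmentation, tiling, glass filtering and
#' optional stain normalization, with the defaults used throughout the
#' pipeline (512 px tiles, x2 downsample, 30% glass threshold).
#'
#' @param image H x W x 3 array, 0-255.
#' @param tile_size,downsample,glass_threshold see [extract_tiles()].
#' @param reference optional [stain_stats()] normalization target.
#' @param slide_id,pixel_size provenance.
#' @return list with `mask`, `image` (normalized if a reference was given)
#'   and `tile_set`.
#' @export
preprocess_slide <- function(image, tile_size = 512L, downsample = 2L,
                             glass_threshold = 0.30, reference = NULL,
                             slide_id = "slide", pixel_size = NA_real_) {
  mask <- segment_foreground(image)
  if (!is.null(reference)) image <- normalize_stain(image, mask, reference)
  boxes <- tile_grid(mask, tile_size)
  tiles <- extract_tiles(image, mask, boxes, downsample, glass_threshold,
                         slide_id = slide_id, pixel_size = pixel_size)
  list(mask = mask, image = image, tile_set = tiles)
}
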