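# Internal numerical utilities shared by the generator, the feature stack and
# the evaluators. Images are plain arrays: H x W (masks) or H x W x 3 (RGB,
# 0-255). Pixel (i, j) in 1-based array indexing has its center at continuous
# coordinates (x, y) = (j - 0.5, i - 0.5), origin at the top-left corner.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive n reproducible child seeds from one parent seed (all < 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

pad_replicate <- function(m, rpad, cpad = rpad) {
  m <- m[c(rep(1L, rpad), seq_len(nrow(m)), rep(nrow(m), rpad)), , drop = FALSE]
  m[, c(rep(1L, cpad), seq_len(ncol(m)), rep(ncol(m), cpad)), drop = FALSE]
}

# Separable Gaussian blur with replicate padding; sigma may differ per axis
# (anisotropic blur is used for fibrillar textures). sigma = 0 skips an axis.
sep_blur <- function(m, sigma_r, sigma_c = sigma_r) {
  kr <- if (sigma_r > 0) gauss_kernel(sigma_r) else 1
  kc <- if (sigma_c > 0) gauss_kernel(sigma_c) else 1
  rr <- (length(kr) - 1L) %/% 2L
  rc <- (length(kc) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_replicate(m, rr, rc)
  if (rr > 0) p <- stats::filter(p, kr, sides = 2)      # along columns
  if (rc > 0) p <- t(stats::filter(t(p), kc, sides = 2)) # along rows
  matrix(p[(rr + 1L):(rr + h), (rc + 1L):(rc + w)], h, w)
}

# Smooth Gaussian random field, standardized to zero mean / unit sd.
smooth_noise <- function(h, w, sigma) {
  f <- sep_blur(matrix(stats::rnorm(h * w), h, w), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Rasterize a polygon onto a pixel grid
#'
#' Even-odd scanline rasterization: a pixel is inside if its center
#' (x = col - 0.5, y = row - 0.5) falls inside the polygon. The generator's
#' bookkeeping and [class_areas()] share this one rule, so border membership
#' is decided identically everywhere.
#'
#' @param xy vertex matrix with columns x, y (implicitly closed).
#' @param h,w output grid size.
#' @return logical H x W mask.
#' @export
rasterize_polygon <- function(xy, h, w) {
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    yc <- i - 0.5
    cr <- (y <= yc & y2 > yc) | (y2 <= yc & y > yc)
    if (!any(cr)) next
    xs <- sort(x[cr] + (yc - y[cr]) / (y2[cr] - y[cr]) * (x2[cr] - x[cr]))
    for (k in seq.int(1L, length(xs) - 1L, by = 2L)) {
      j0 <- max(1L, as.integer(floor(xs[k] + 0.5)) + 1L)
      j1 <- min(w, as.integer(ceiling(xs[k + 1L] + 0.5)) - 1L)
      if (j0 <= j1) mask[i, j0:j1] <- TRUE
    }
  }
  mask
}

# Shoelace area of a polygon in pixel^2.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Area-average a matrix by an integer factor; trailing rows/cols that do not
# fill a block are dropped.
block_mean <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  h <- (nrow(m) %/% f) * f
  w <- (ncol(m) %/% f) * f
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  rg <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f, ncol = w)
  t(matrix(colMeans(matrix(t(rg), nrow = f)), nrow = w %/% f, ncol = h %/% f))
}

upsample_nearest <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f), drop = FALSE]
}

# Apply a matrix-valued function channel-wise over an H x W x C array; the
# function may change the spatial size (e.g. block averaging).
map_channels <- function(arr, fn) {
  nc <- dim(arr)[3]
  first <- fn(arr[, , 1])
  out <- array(0, c(nrow(first), ncol(first), nc))
  out[, , 1] <- first
  for (c in seq_len(nc)[-1]) out[, , c] <- fn(arr[, , c])
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

hex_to_rgb <- function(hex) {
  v <- grDevices::col2rgb(hex)
  as.numeric(v[, 1])
}
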