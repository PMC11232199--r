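test_that("a blank slide yields an empty foreground mask", {
  white <- array(255, c(40, 40, 3))
  expect_equal(sum(segment_foreground(white)), 0L)
})

test_that("a saturated disc on glass is recovered within morphology tolerance", {
  h <- 80; w <- 80; r <- 22
  img <- array(250, c(h, w, 3))
  d2 <- outer((seq_len(h) - 40)^2, (seq_len(w) - 40)^2, `+`)
  disc <- d2 <= r^2
  img[, , 1][disc] <- 160; img[, , 2][disc] <- 80; img[, , 3][disc] <- 140
  mask <- segment_foreground(img)
  # analytic oracle: disc area, with a margin for median filter + closing
  expect_gt(sum(mask & disc) / sum(disc), 0.95)
  expect_lt(sum(mask & !disc), 0.1 * sum(disc))
})

test_that("the foreground mask covers the synthetic slide's tissue", {
  sl <- small_slide()
  mask <- segment_foreground(sl$image)
  tissue <- sl$truth_mask != 255L
  expect_gte(mean(mask[tissue]), 0.99)
})

test_that("tile grids follow the drop-partial-edge rule", {
  expect_equal(nrow(tile_grid(c(1024, 1024), 512)), 4L)
  expect_equal(nrow(tile_grid(c(1023, 1024), 512)), 2L)
  expect_equal(nrow(tile_grid(c(5120, 5120), 512)), 100L)
  g <- tile_grid(c(96, 64), 32)
  expect_equal(nrow(g), 6L)
  expect_true(all(g$r1 - g$r0 == 32L))
  # boxes partition the covered area: no pixel in two boxes
  cover <- matrix(0L, 96, 64)
  for (i in seq_len(nrow(g))) {
    cover[(g$r0[i] + 1):g$r1[i], (g$c0[i] + 1):g$c1[i]] <-
      cover[(g$r0[i] + 1):g$r1[i], (g$c0[i] + 1):g$c1[i]] + 1L
  }
  expect_true(all(cover <= 1L))
  expect_equal(sum(cover), 6L * 32L * 32L)
})

test_that("the glass threshold is inclusive at exactly 30%", {
  img <- array(120, c(10, 20, 3))
  mask <- matrix(FALSE, 10, 20)
  mask[1:10, 1:3] <- TRUE              # left tile: 30 / 100 = 0.30 exactly
  right <- matrix(FALSE, 10, 10)
  right[seq_len(29)] <- TRUE           # right tile: 29 / 100 = 0.29
  mask[, 11:20] <- right
  boxes <- tile_grid(mask, 10)
  ts <- extract_tiles(img, mask, boxes, downsample = 1, glass_threshold = 0.30)
  expect_equal(ts$tiles$tissue_fraction, c(0.30, 0.29))
  expect_equal(ts$tiles$retained, c(TRUE, FALSE))
})

test_that("an all-glass slide yields an empty tile set and bad boxes error", {
  img <- array(255, c(64, 64, 3))
  mask <- matrix(FALSE, 64, 64)
  ts <- extract_tiles(img, mask, tile_grid(mask, 32), glass_threshold = 0.3)
  expect_equal(sum(ts$tiles$retained), 0L)
  expect_length(ts$data, 0L)
  bad <- tibble::tibble(tile_id = 1L, r0 = 0L, r1 = 128L, c0 = 0L, c1 = 32L)
  expect_error(extract_tiles(img, mask, bad), "outside")
})

test_that("raising the glass threshold never increases retained tiles", {
  set.seed(42)
  sl <- small_slide()
  mask <- segment_foreground(sl$image)
  boxes <- tile_grid(mask, 32)
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    sum(extract_tiles(sl$image, mask, boxes, glass_threshold = th)$tiles$retained)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tiles are area-averaged by the downsample factor", {
  img <- array(0, c(4, 4, 3))
  img[, , 1] <- matrix(c(0, 100, 0, 100,
                         200, 100, 200, 100,
                         8, 8, 8, 8,
                         0, 16, 0, 16), 4, 4, byrow = TRUE)
  mask <- matrix(TRUE, 4, 4)
  ts <- extract_tiles(img, mask, tile_grid(mask, 4), downsample = 2,
                      glass_threshold = 0)
  expect_equal(dim(ts$data[[1]]), c(2L, 2L, 3L))
  expect_equal(ts$data[[1]][1, 1, 1], mean(c(0, 100, 200, 100)))
  expect_equal(ts$data[[1]][2, 2, 1], mean(c(8, 8, 0, 16)))
  expect_equal(ts$pixel_size_effective, NA_real_ * 2)
})

test_that("optical density obeys its closed form and round-trips", {
  expect_equal(od_transform(array(255, c(1, 1, 3))),
               array(0, c(1, 1, 3)))
  expect_equal(od_transform(26), -log10(26 / 255), tolerance = 1e-12)
  expect_equal(od_transform(26), 0.9916, tolerance = 1e-4)
  set.seed(1)
  x <- array(sample(0:255, 300, replace = TRUE), c(10, 10, 3))
  back <- od_inverse(od_transform(x))
  expect_true(max(abs(back - pmax(x, 1))) < 1e-9)
  expect_lte(max(abs(back - x)), 1 + 1e-9)
})

test_that("stain normalization maps foreground OD stats onto the reference", {
  sl <- small_slide()
  fg <- segment_foreground(sl$image)
  ref <- stain_stats(sl$image, fg)
  # a differently tinted slide
  other <- generate_slide(synthetic_slide_config(height = 128, width = 128,
                                                 texture_seed = 9), seed = 13)
  img2 <- other$image * 1.0
  img2[, , 1] <- pmin(img2[, , 1] * 0.85, 255)
  img2[, , 3] <- pmin(img2[, , 3] * 1.10, 255)
  fg2 <- segment_foreground(array(as.integer(round(img2)), dim(img2)))
  nrm <- normalize_stain(img2, fg2, ref)
  st <- stain_stats(nrm, fg2)
  expect_true(max(abs(st$mean - ref$mean)) < 1e-3)
  expect_true(max(abs(st$sd - ref$sd)) < 1e-3)
  # background pixels pass through unchanged
  expect_equal(nrm[, , 1][!fg2], img2[, , 1][!fg2])
})

test_that("normalization is idempotent and errors on degenerate input", {
  sl <- small_slide()
  fg <- segment_foreground(sl$image)
  ref <- stain_stats(sl$image, fg)
  once <- normalize_stain(sl$image, fg, ref)
  st1 <- stain_stats(once, fg)
  twice <- normalize_stain(once, fg, ref)
  st2 <- stain_stats(twice, fg)
  expect_true(max(abs(st2$mean - st1$mean)) < 1e-6)
  expect_true(max(abs(st2$sd - st1$sd)) < 1e-6)
  # constant foreground has zero OD variance
  flat <- array(128, c(16, 16, 3))
  expect_error(normalize_stain(flat, matrix(TRUE, 16, 16), ref), "degenerate")
})
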