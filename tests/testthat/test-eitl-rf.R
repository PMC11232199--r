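test_that("the feature stack has channels x scales x 3 features", {
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  f1 <- pixel_features(img, scales = 2)
  expect_equal(dim(f1)[3], 18L)
  f3 <- pixel_features(img, scales = c(1, 2, 4))
  expect_equal(dim(f3)[3], 54L)
  expect_length(attr(f3, "feature_names"), 54L)
  # deterministic
  expect_identical(f3, pixel_features(img, scales = c(1, 2, 4)))
})

test_that("gradient and local-std features vanish on a constant image", {
  img <- array(137, c(20, 20, 3))
  f <- pixel_features(img, scales = c(1, 2))
  nms <- attr(f, "feature_names")
  for (i in grep("_grad|_sd", nms)) {
    expect_equal(max(abs(f[, , i])), 0, tolerance = 1e-6)
  }
})

test_that("larger smoothing scales reduce feature variance on noise", {
  set.seed(5)
  img <- array(runif(48 * 48 * 3, 0, 255), c(48, 48, 3))
  f <- pixel_features(img, scales = c(1, 2, 4))
  nms <- attr(f, "feature_names")
  v <- vapply(paste0("R_s", c(1, 2, 4), "_smooth"),
              function(n) var(as.vector(f[, , match(n, nms)])), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("the forest trains with 50 trees, is seeded, and separates colors", {
  set.seed(3)
  n <- 300
  x <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 4), n, 4))
  y <- rep(c(0L, 5L), each = n)
  m <- rf_fit(x, y, rf_config(seed = 2))
  expect_equal(m$forest$ntree, 50L)
  expect_equal(m$classes, c(0L, 5L))
  # training-pixel accuracy on well-separated classes
  pred <- as.integer(as.character(predict(m$forest, x)))
  expect_gte(mean(pred == y), 0.99)
  # identical seed, identical predictions
  m2 <- rf_fit(x, y, rf_config(seed = 2))
  expect_identical(predict(m2$forest, x), predict(m$forest, x))
  expect_error(rf_fit(x, rep(1L, nrow(x))), "two classes")
})

test_that("segmentation recovers a pure-class region and respects the mask", {
  sl <- small_slide()
  feats <- small_features()
  sp <- small_sparse()
  ann <- which(sp != 255L)
  m <- rf_fit(features_at(feats, ann), sp[ann], rf_config(seed = 4))
  tissue <- sl$truth_mask != 255L
  pred <- rf_segment(m, sl$image, tissue_mask = tissue, feature_stack = feats)
  # empty mask -> everything ignore
  none <- rf_segment(m, sl$image, tissue_mask = matrix(FALSE, 128, 128),
                     feature_stack = feats)
  expect_true(all(none == 255L))
  # tumor region is recovered almost everywhere
  tumor <- sl$truth_mask == 0L
  expect_gte(mean(pred[tumor] == 0L), 0.95)
  # non-tissue pixels carry the ignore label
  expect_true(all(pred[!tissue] == 255L))
  # deterministic for a fixed model
  expect_identical(pred, rf_segment(m, sl$image, tissue_mask = tissue,
                                    feature_stack = feats))
})

test_that("refinement stops per the stopping rules and never drops annotations", {
  sl <- small_slide()
  sp <- small_sparse()
  # target 0: first iteration always exceeds it
  r0 <- eitl_refine(sl, sp, target_accuracy = 0, seed = 2)
  expect_equal(nrow(r0$trace), 1L)
  expect_equal(r0$stop_reason, "target_reached")
  # unreachable target + always-notable improvement: runs all 5 iterations
  r5 <- eitl_refine(sl, sp, target_accuracy = 1.01, min_improvement = -1,
                    seed = 2)
  expect_equal(nrow(r5$trace), 5L)
  expect_equal(r5$stop_reason, "max_iterations")
  expect_true(all(diff(r5$trace$n_annotated_pixels) > 0))
  expect_gte(r5$trace$accuracy[5], r5$trace$accuracy[1] - 0.02)
  tr <- tidy(r5)
  expect_equal(nrow(tr), 5L)
  g <- glance(r5)
  expect_equal(g$iterations, 5L)
})

test_that("conflicting oracle labels are rejected", {
  sl <- small_slide()
  sp <- small_sparse()
  bad_oracle <- function(slide, predicted_mask, k_worst, strokes, seed) {
    out <- matrix(255L, nrow(predicted_mask), ncol(predicted_mask))
    idx <- which(sp != 255L)[1]
    out[idx] <- (sp[idx] + 1L) %% 10L  # contradicts an existing annotation
    attr(out, "n_strokes") <- 1L
    attr(out, "strokes") <- tibble::tibble(class_index = out[idx],
                                           row = 1L, col = 1L, radius = 1L)
    out
  }
  expect_error(
    eitl_refine(sl, sp, oracle = bad_oracle, target_accuracy = 1.01,
                min_improvement = -1, max_iter = 2, seed = 2),
    "conflicting")
})

test_that("the tumor border traces a solid disc faithfully", {
  h <- 96; w <- 96
  mask <- matrix(9L, h, w)  # background_normal
  d2 <- outer((seq_len(h) - 48)^2, (seq_len(w) - 48)^2, `+`)
  disc <- d2 <= 30^2
  mask[disc] <- 0L
  tb <- tumor_border(mask, min_area = 50)
  expect_length(tb$polygons, 1L)
  rast <- rasterize_polygon(tb$polygons[[1]], h, w)
  iou <- sum(rast & disc) / sum(rast | disc)
  expect_gte(iou, 0.95)
  # shoelace area of the polygon matches the processed pixel count within 2%
  poly_area <- sum(vapply(tb$polygons, tmeseg:::polygon_area, numeric(1)))
  expect_lt(abs(poly_area - tb$area_pixels) / tb$area_pixels, 0.02)
  # all-normal mask: empty border with a warning
  expect_warning(empty <- tumor_border(matrix(9L, 32, 32)), "no tumor")
  expect_length(empty$polygons, 0L)
})
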