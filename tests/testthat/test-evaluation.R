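test_that("majority labels follow greatest coverage with index tie-breaks", {
  expect_equal(majority_label(c(A = 60, B = 40)), "A")
  expect_equal(majority_label(c(A = 50, B = 50)), "A")
  expect_equal(majority_label(c(A = 0, B = 7)), "B")
  expect_equal(majority_label(c(5, 9, 9)), 2L)
  expect_error(majority_label(c(A = 0, B = 0)), "no labeled")
})

test_that("evaluation tiles pair truth and prediction by majority", {
  sch <- tme_schema()
  truth <- matrix(0L, 12, 12)      # all ADCA
  truth[1:2, 1:2] <- 255L          # an unannotated corner
  labs <- evaluation_tiles(truth, truth, pixel_size = 1, tile_edge_um = 4)
  expect_true(all(labs$truth == "ADCA"))
  expect_true(all(labs$pred == labs$truth))
  # prediction fully unlabeled -> NA pred
  pred <- matrix(255L, 12, 12)
  labs2 <- evaluation_tiles(truth, pred, pixel_size = 1, tile_edge_um = 4)
  expect_true(all(is.na(labs2$pred)))
  expect_error(evaluation_tiles(truth, truth, pixel_size = NA), "pixel_size")
})

test_that("tile enumeration matches a brute-force grid scan", {
  set.seed(61)
  for (trial in 1:25) {
    h <- sample(8:20, 1); w <- sample(8:20, 1); edge <- sample(3:6, 1)
    truth <- random_fine_mask(h, w)
    pred <- random_fine_mask(h, w, p_ignore = 0)
    labs <- evaluation_tiles(truth, pred, pixel_size = 1, tile_edge_um = edge)
    # oracle: exhaustive scan of grid cells with any annotated pixel
    n_expected <- 0L
    for (tr in seq_len(ceiling(h / edge))) for (tc in seq_len(ceiling(w / edge))) {
      cell <- truth[((tr - 1) * edge + 1):min(tr * edge, h),
                    ((tc - 1) * edge + 1):min(tc * edge, w)]
      if (any(cell != 255L)) n_expected <- n_expected + 1L
    }
    expect_equal(nrow(labs), n_expected)
  }
})

test_that("the literal-area reading of the tile size is supported", {
  truth <- matrix(0L, 20, 20)
  # 100 um^2 at 1 um/px -> 10 px edge; default reading -> 100 px edge capped
  a <- evaluation_tiles(truth, truth, pixel_size = 1, tile_edge_um = 100,
                        literal_area = TRUE)
  expect_equal(nrow(a), 4L)
  b <- evaluation_tiles(truth, truth, pixel_size = 1, tile_edge_um = 100)
  expect_equal(nrow(b), 1L)
})

test_that("confusion matrices count pairs exactly", {
  cl <- c("a", "b", "c")
  truth <- c("a", "a", "b", "c", "c", "c")
  pred <- c("a", "b", "b", "c", "a", "c")
  cm <- confusion(truth, pred, classes = cl)
  expect_equal(sum(cm), 6L)
  expect_equal(unclass(cm)["a", "b"], 1L)
  expect_equal(unclass(cm)["c", "c"], 2L)
  expect_equal(rowSums(cm), c(a = 2, b = 1, c = 3))
  # perfect agreement is diagonal
  cmd <- confusion(truth, truth, classes = cl)
  expect_equal(sum(diag(cmd)), 6L)
  expect_true(all(cmd[upper.tri(cmd)] == 0L) && all(cmd[lower.tri(cmd)] == 0L))
  expect_error(confusion(c("a", "z"), c("a", "a"), classes = cl), "unknown")
  expect_warning(confusion(c("a", "b"), c("a", NA), classes = cl), "dropped")
})

test_that("confusion counting matches a brute-force nested tally", {
  set.seed(62)
  cl <- letters[1:4]
  for (trial in 1:25) {
    n <- sample(20:60, 1)
    truth <- sample(cl, n, replace = TRUE)
    pred <- sample(cl, n, replace = TRUE)
    cm <- unclass(confusion(truth, pred, classes = cl))
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      expect_equal(cm[i, j], sum(truth == cl[i] & pred == cl[j]))
    }
  }
})

test_that("precision, recall and F1 follow their one-vs-rest definitions", {
  cm <- confusion(c("a", "a", "a", "b", "b", "c"),
                  c("a", "a", "b", "b", "b", "b"), classes = c("a", "b", "c"))
  rep <- precision_recall_f1(cm)
  pc <- rep$per_class
  expect_equal(pc$precision[pc$class == "a"], 1)
  expect_equal(pc$recall[pc$class == "a"], 2 / 3)
  expect_equal(pc$precision[pc$class == "b"], 2 / 4)
  expect_equal(pc$recall[pc$class == "b"], 1)
  # c was never predicted: flagged, reported as 0
  expect_equal(pc$precision[pc$class == "c"], 0)
  expect_true(pc$precision_undefined[pc$class == "c"])
  expect_equal(glance(rep)$accuracy, rep$accuracy)
  expect_error(precision_recall_f1(matrix(0L, 2, 2)), "empty")
})

test_that("F1 is the harmonic mean and P = R implies F1 = P", {
  expect_equal(round(f1_score(0.96, 0.88), 2), 0.92)
  expect_equal(round(f1_score(1.00, 0.75), 2), 0.86)
  expect_equal(f1_score(0.7, 0.7), 0.7)
  expect_equal(f1_score(0, 0), 0)
  set.seed(63)
  for (i in 1:50) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("support-weighted recall equals overall accuracy on random matrices", {
  set.seed(64)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    m <- matrix(rpois(k * k, 5), k, k,
                dimnames = list(letters[1:k], letters[1:k]))
    m[1, ] <- m[1, ] + 1  # ensure a non-empty matrix
    rep <- precision_recall_f1(m)
    expect_equal(rep$weighted$recall, rep$accuracy, tolerance = 1e-12)
  }
})

test_that("tile-level accuracy is robust where pixel Dice is penalized", {
  # boundary-jittered prediction: shift the truth two pixels sideways
  sl <- small_slide()
  truth <- sl$truth_mask
  pred <- truth
  pred[, 3:ncol(truth)] <- truth[, 1:(ncol(truth) - 2)]
  # pixel-level Dice of the tumor class under jitter
  a <- truth == 0L; b <- pred == 0L
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  labs <- evaluation_tiles(truth, pred, pixel_size = sl$pixel_size,
                           tile_edge_um = 8)
  tile_acc <- mean(labs$truth == labs$pred, na.rm = TRUE)
  expect_gt(tile_acc, dice)
})

test_that("cross-validation folds hold out whole cases and pool by summation", {
  slides <- lapply(1:3, function(s) {
    generate_slide(synthetic_slide_config(height = 96, width = 96,
                                          texture_seed = s),
                   seed = 50 + s, case_id = paste0("cv", s),
                   arm = "ADCA_fibrotic")
  })
  cv <- crossval(slides, k_folds = 3, seed = 2, strokes_per_class = 8)
  expect_equal(nrow(cv$folds), 3L)
  expect_setequal(cv$assignment$case_id, c("cv1", "cv2", "cv3"))
  expect_equal(anyDuplicated(cv$assignment$fold), 0L)
  # pooled confusion equals the sum of the fold confusions
  summed <- Reduce(`+`, lapply(cv$folds$report, function(r) unclass(r$cm)))
  expect_equal(unclass(cv$pooled$cm), summed)
  expect_error(crossval(slides[1:2], k_folds = 3), "fewer cases|length")
})
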