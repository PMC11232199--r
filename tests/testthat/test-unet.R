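test_that("tile split arithmetic reproduces the printed counts", {
  s <- split_tiles(29135, seed = 1)
  expect_equal(s$counts$n_trainval, 19423L)
  expect_equal(s$counts$n_train, 13596L)
  expect_equal(s$counts$n_val, 5827L)
  expect_equal(s$counts$n_test, 9712L)
  expect_equal(split_tiles(3)$counts[, -1],
               tibble::tibble(n_trainval = 2L, n_train = 1L, n_val = 1L,
                              n_test = 1L))
  expect_error(split_tiles(2), "at least 3")
})

test_that("split assignment partitions the tile indices", {
  for (n in c(10L, 57L, 100L)) {
    a <- split_tiles(n, seed = n)$assignment
    expect_setequal(a$index, seq_len(n))
    expect_equal(anyDuplicated(a$index), 0L)
    expect_setequal(unique(a$set), c("train", "val", "test"))
  }
})

test_that("config invariants are enforced", {
  expect_error(unet_config(out_channels = 1), ">= 2")
  expect_error(unet_config(3, encoder_channels = c(8, 16), n_levels = 2),
               "n_levels")
  expect_error(unet_config(3, encoder_channels = c(16, 8), n_levels = 1),
               "increasing")
  expect_error(build_unet(unet_config(3, input_size = 100)), "divisible")
})

test_that("architecture is deterministic and reports default channel widths", {
  cfg <- unet_config(out_channels = 7)
  expect_equal(cfg$encoder_channels, c(32L, 64L, 128L, 256L, 512L))
  a <- build_unet(cfg, seed = 3)
  b <- build_unet(cfg, seed = 3)
  expect_identical(n_params(a), n_params(b))
  expect_identical(a$params, b$params)
})

test_that("a 256-px probe through the default net returns per-pixel scores", {
  cfg <- unet_config(out_channels = 7)
  m <- build_unet(cfg, seed = 1)
  x <- array(stats::runif(256 * 256 * 3), c(256, 256, 3, 1))
  lg <- unet_fwd(m, x)$logits
  expect_equal(dim(lg), c(256L, 256L, 7L, 1L))
  # bottleneck spatial size is input / 2^n_levels = 16
  expect_equal(256L %/% 2L^cfg$n_levels, 16L)
  expect_true(all(is.finite(lg)))
})

test_that("analytic gradients match finite differences", {
  cfg <- unet_config(out_channels = 3, encoder_channels = c(4L, 6L),
                     n_levels = 1L, input_size = 8L)
  m <- build_unet(cfg, seed = 2)
  set.seed(9)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array(sample(c(0:2, 255L), 8 * 8 * 2, replace = TRUE), c(8, 8, 2))
  w <- c(1, 2, 0.5)
  fw <- tmeseg:::unet_fwd(m, x, train = TRUE)
  ls <- tmeseg:::softmax_ce(fw$logits, y, w)
  gr <- tmeseg:::unet_bwd(m, fw$caches, ls$dlogits)
  eps <- 1e-5
  for (nm in c("enc1_u1_W", "bot_u2_g", "dec1_up_W", "dec1_u1_beta",
               "head_W", "enc1_u2_b")) {
    p <- m$params[[nm]]
    for (ii in sample(length(p), min(3, length(p)))) {
      m2 <- m
      m2$params[[nm]][ii] <- p[ii] + eps
      l1 <- tmeseg:::softmax_ce(tmeseg:::unet_fwd(m2, x, TRUE)$logits, y, w)$loss
      m2$params[[nm]][ii] <- p[ii] - eps
      l2 <- tmeseg:::softmax_ce(tmeseg:::unet_fwd(m2, x, TRUE)$logits, y, w)$loss
      num <- (l1 - l2) / (2 * eps)
      ana <- gr[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

make_two_class_tiles <- function(n = 24, edge = 16) {
  xs <- list(); ys <- list()
  for (i in seq_len(n)) {
    lab <- matrix(ifelse(matrix(runif(edge^2), edge) +
                           outer(sin(seq_len(edge) / 2), cos(seq_len(edge) / 3)) > 0.5,
                         1L, 0L), edge, edge)
    img <- array(0, c(edge, edge, 3))
    base0 <- c(130, 80, 170); base1 <- c(205, 175, 115)
    for (c in 1:3) {
      ch <- matrix(base0[c], edge, edge)
      ch[lab == 1L] <- base1[c]
      img[, , c] <- pmin(pmax(ch + rnorm(edge^2, sd = 8), 0), 255)
    }
    xs[[i]] <- img; ys[[i]] <- lab
  }
  list(x = xs, y = ys)
}

test_that("the net learns a two-class color segmentation in ten epochs", {
  set.seed(21)
  d <- make_two_class_tiles()
  cfg <- unet_config(out_channels = 2, encoder_channels = c(6L, 12L),
                     n_levels = 1L, input_size = 16L)
  m <- train_unet(d$x, d$y, cfg, epochs = 10, lr = 5e-3, batch_size = 4,
                  seed = 5)
  expect_true(all(is.finite(m$history$train_loss)))
  expect_gte(max(m$history$val_accuracy), 0.90)
  expect_equal(nrow(tidy(m)), 10L)
  expect_equal(glance(m)$n_params, n_params(m))
})

test_that("training is bitwise reproducible for a fixed seed", {
  set.seed(22)
  d <- make_two_class_tiles(n = 8)
  cfg <- unet_config(out_channels = 2, encoder_channels = c(4L, 8L),
                     n_levels = 1L, input_size = 16L)
  a <- train_unet(d$x, d$y, cfg, epochs = 2, seed = 7)
  b <- train_unet(d$x, d$y, cfg, epochs = 2, seed = 7)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
  expect_error(train_unet(d$x[1:3], d$y[1:3], cfg, epochs = 1, seed = 1,
                          split = local({
                            s <- split_tiles(3, 1)
                            s$assignment$set <- "test"
                            s
                          })),
               "empty training split")
})

test_that("permuted labels learn nothing beyond chance", {
  set.seed(23)
  d <- make_two_class_tiles(n = 16)
  perm <- lapply(d$y, function(m) matrix(sample(m), nrow(m)))
  cfg <- unet_config(out_channels = 2, encoder_channels = c(4L, 8L),
                     n_levels = 1L, input_size = 16L)
  m <- train_unet(d$x, perm, cfg, epochs = 4, seed = 9)
  final <- m$history$val_accuracy[4]
  expect_gt(final, 0.25)
  expect_lt(final, 0.75)
})

test_that("slide prediction stitches tile argmaxes onto the retained grid", {
  sl <- generate_slide(synthetic_slide_config(height = 64, width = 64),
                       seed = 31)
  tiled <- slide_label_tiles(sl, tile_size = 32, downsample = 2)
  cfg <- unet_config(out_channels = 7, encoder_channels = c(4L, 8L),
                     n_levels = 1L, input_size = 16L)
  m <- build_unet(cfg, seed = 1)
  stitched <- predict_slide(m, sl$image, tiled$tile_set)
  keep <- tiled$tile_set$tiles[tiled$tile_set$tiles$retained, ]
  covered <- matrix(FALSE, 64, 64)
  for (i in seq_len(nrow(keep))) {
    covered[(keep$r0[i] + 1):keep$r1[i], (keep$c0[i] + 1):keep$c1[i]] <- TRUE
  }
  expect_true(all(stitched[!covered] == 255L))
  expect_true(all(stitched[covered] != 255L))
  # a single tile equals its own upsampled argmax
  one <- predict_unet(m, tiled$x[1])[[1]]
  i <- 1L
  block <- stitched[(keep$r0[i] + 1):keep$r1[i], (keep$c0[i] + 1):keep$c1[i]]
  expect_equal(block, tmeseg:::upsample_nearest(one, 2L))
})
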