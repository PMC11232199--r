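#' Tile split arithmetic: two-thirds train+validation, then 70/30
#'
#' Splits `n_total` tiles into training, validation and test sets without
#' overlap: two thirds (floored) form the train+validation pool, of which
#' 70% (floored) train and the rest validate; the remaining third tests.
#' At `n_total = 29135` this yields 19423 / 13596 / 5827 / 9712 tiles.
#' Assignment of tile indices to sets is a seeded permutation.
#'
#' @param n_total total number of tiles (>= 3).
#' @param seed integer seed for the permutation.
#' @return a `split_counts` list: `counts` (tibble with `n_total`,
#'   `n_trainval`, `n_train`, `n_val`, `n_test`) and `assignment` (tibble:
#'   `index`, `set` in train/val/test).
#' @examples
#' split_tiles(29135, seed = 1)$counts
#' @export
split_tiles <- function(n_total, seed = 1L) {
  n_total <- as.integer(n_total)
  if (n_total < 3L) stop("need at least 3 tiles to split", call. = FALSE)
  n_trainval <- (2L * n_total) %/% 3L
  n_train <- as.integer(floor(0.7 * n_trainval))
  n_val <- n_trainval - n_train
  n_test <- n_total - n_trainval
  perm <- with_seed(seed, sample.int(n_total))
  set <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  assignment <- tibble::tibble(index = perm, set = set)
  assignment <- assignment[order(assignment$index), ]
  structure(
    list(counts = tibble::tibble(n_total = n_total, n_trainval = n_trainval,
                                 n_train = n_train, n_val = n_val,
                                 n_test = n_test),
         assignment = assignment),
    class = "split_counts"
  )
}

#' @export
print.split_counts <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' U-Net architecture configuration
#'
#' An encoder-decoder with skip connections: `n_levels` encoder levels of
#' two 3x3 convolution blocks (each convolution followed by batch
#' normalization and LeakyReLU), 2x max pooling between levels, a bottleneck
#' block, and a mirrored decoder using 2x nearest-neighbour upsampling,
#' skip concatenation and two further convolution blocks per level, closed
#' by a 1x1 convolution to per-pixel class scores.
#'
#' @param out_channels number of output classes (>= 2).
#' @param encoder_channels widths per level, strictly increasing; length
#'   must be `n_levels + 1` (the last entry is the bottleneck width).
#' @param n_levels number of down/up levels (default 4).
#' @param in_channels input channels (3 for RGB).
#' @param input_size expected tile edge in pixels (default 256, a 512 px
#'   tile downsampled by 2); must be divisible by `2^n_levels`.
#' @param kernel_size convolution kernel edge (3).
#' @param leaky_slope negative slope of the LeakyReLU (default 0.01).
#' @param batch_norm logical; include batch normalization (default TRUE).
#' @return a `unet_config` list.
#' @export
unet_config <- function(out_channels,
                        encoder_channels = c(32L, 64L, 128L, 256L, 512L),
                        n_levels = 4L, in_channels = 3L, input_size = 256L,
                        kernel_size = 3L, leaky_slope = 0.01,
                        batch_norm = TRUE) {
  out_channels <- as.integer(out_channels)
  if (out_channels < 2L) stop("out_channels must be >= 2", call. = FALSE)
  if (length(encoder_channels) != n_levels + 1L) {
    stop("length(encoder_channels) must equal n_levels + 1", call. = FALSE)
  }
  if (any(diff(encoder_channels) <= 0)) {
    stop("encoder_channels must be strictly increasing", call. = FALSE)
  }
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd", call. = FALSE)
  structure(
    list(out_channels = out_channels,
         encoder_channels = as.integer(encoder_channels),
         n_levels = as.integer(n_levels),
         in_channels = as.integer(in_channels),
         input_size = as.integer(input_size),
         kernel_size = as.integer(kernel_size),
         leaky_slope = leaky_slope, batch_norm = isTRUE(batch_norm)),
    class = "unet_config"
  )
}

# ---------------------------------------------------------------------------
# Layer primitives. Activations are 4D arrays [H, W, C, N]; convolution
# weights are (Cin * k^2) x Cout matrices acting on im2col matrices whose
# rows are ordered sample-major, column-major within each sample (R's
# native flattening), so reshapes are loop-free.

ch_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

un_ch_mat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

im2col <- function(x, k) {
  d <- dim(x)  # H W C N
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  cols <- matrix(0, d[1] * d[2] * d[4], d[3] * k * k)
  idx <- 0L
  for (c in seq_len(d[3])) for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    idx <- idx + 1L
    cols[, idx] <- aperm(xp[dr + seq_len(d[1]), dc + seq_len(d[2]), c, ,
                            drop = FALSE], c(1, 2, 4, 3))
  }
  cols
}

col2im <- function(dcols, d, k) {
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  idx <- 0L
  for (c in seq_len(d[3])) for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    idx <- idx + 1L
    dxp[dr + seq_len(d[1]), dc + seq_len(d[2]), c, ] <-
      dxp[dr + seq_len(d[1]), dc + seq_len(d[2]), c, , drop = FALSE] +
      array(dcols[, idx], c(d[1], d[2], 1L, d[4]))
  }
  dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
}

conv_fwd <- function(x, W, b, k) {
  d <- dim(x)
  cols <- im2col(x, k)
  y <- sweep(cols %*% W, 2L, b, `+`)
  list(y = un_ch_mat(y, c(d[1], d[2], ncol(W), d[4])), cols = cols, d_in = d)
}

conv_bwd <- function(cache, dy, W, k) {
  dym <- ch_mat(dy)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dx <- col2im(dym %*% t(W), cache$d_in, k)
  list(dx = dx, dW = dW, db = db)
}

bn_fwd <- function(x, g, beta, run, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  xm <- ch_mat(x)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, g, `*`), 2L, beta, `+`)
  list(y = un_ch_mat(y, d), xhat = xhat, inv = inv, d = d, run = run)
}

bn_bwd <- function(cache, dy, g) {
  dym <- ch_mat(dy)
  dbeta <- colSums(dym)
  dg <- colSums(dym * cache$xhat)
  n <- nrow(dym)
  dxhat <- sweep(dym, 2L, g, `*`)
  dxm <- sweep(
    dxhat - matrix(colMeans(dxhat), n, ncol(dym), byrow = TRUE) -
      cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, ncol(dym), byrow = TRUE),
    2L, cache$inv, `*`
  )
  list(dx = un_ch_mat(dxm, cache$d), dg = dg, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg)
}

lrelu_bwd <- function(cache, dy, slope) {
  dy[cache$neg] <- dy[cache$neg] * slope
  dy
}

pool_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  x11 <- x[ro, co, , , drop = FALSE]; x21 <- x[re, co, , , drop = FALSE]
  x12 <- x[ro, ce, , , drop = FALSE]; x22 <- x[re, ce, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  a1 <- x11 == y
  a2 <- x21 == y & !a1
  a3 <- x12 == y & !(a1 | a2)
  a4 <- !(a1 | a2 | a3)
  list(y = y, args = list(a1, a2, a3, a4), d_in = d)
}

pool_bwd <- function(cache, dy) {
  d <- cache$d_in
  dx <- array(0, d)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  g <- function(a) { z <- dy; z[!a] <- 0; z }
  dx[ro, co, , ] <- g(cache$args[[1]])
  dx[re, co, , ] <- g(cache$args[[2]])
  dx[ro, ce, , ] <- g(cache$args[[3]])
  dx[re, ce, , ] <- g(cache$args[[4]])
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  dy[ro, co, , , drop = FALSE] + dy[re, co, , , drop = FALSE] +
    dy[ro, ce, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Model assembly

unit_names <- function(cfg) {
  L <- cfg$n_levels
  units <- character(0)
  for (l in seq_len(L)) units <- c(units, paste0("enc", l, "_u", 1:2))
  units <- c(units, paste0("bot_u", 1:2))
  for (l in rev(seq_len(L))) {
    units <- c(units, paste0("dec", l, "_up"), paste0("dec", l, "_u", 1:2))
  }
  units
}

unit_channels <- function(cfg) {
  L <- cfg$n_levels
  ch <- cfg$encoder_channels
  io <- list()
  cin <- cfg$in_channels
  for (l in seq_len(L)) {
    io[[paste0("enc", l, "_u1")]] <- c(cin, ch[l])
    io[[paste0("enc", l, "_u2")]] <- c(ch[l], ch[l])
    cin <- ch[l]
  }
  io[[paste0("bot_u1")]] <- c(ch[L], ch[L + 1L])
  io[[paste0("bot_u2")]] <- c(ch[L + 1L], ch[L + 1L])
  above <- ch[L + 1L]
  for (l in rev(seq_len(L))) {
    io[[paste0("dec", l, "_up")]] <- c(above, ch[l])
    io[[paste0("dec", l, "_u1")]] <- c(2L * ch[l], ch[l])
    io[[paste0("dec", l, "_u2")]] <- c(ch[l], ch[l])
    above <- ch[l]
  }
  io
}

#' Build an untrained U-Net
#'
#' Allocates He-initialized weights for the architecture described by the
#' config. Initialization is seeded, so the parameter count and (for a fixed
#' seed) the parameter values are identical across builds.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return a `unet_model`: list with `config`, `params` (named list of
#'   arrays), `bn_run` (running batch-norm statistics), `classes` (output
#'   channel to class-label map, defaults to `0:(out_channels-1)`), and
#'   `history` (empty until trained).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  if (config$input_size %% (2L^config$n_levels) != 0L) {
    stop("input_size must be divisible by 2^n_levels", call. = FALSE)
  }
  k <- config$kernel_size
  io <- unit_channels(config)
  params <- list()
  bn_run <- list()
  with_seed(seed, {
    for (nm in names(io)) {
      cin <- io[[nm]][1]; cout <- io[[nm]][2]
      fan_in <- cin * k * k
      params[[paste0(nm, "_W")]] <- matrix(
        stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
      params[[paste0(nm, "_b")]] <- numeric(cout)
      if (config$batch_norm) {
        params[[paste0(nm, "_g")]] <- rep(1, cout)
        params[[paste0(nm, "_beta")]] <- numeric(cout)
        bn_run[[nm]] <- list(mean = numeric(cout), var = rep(1, cout))
      }
    }
    ch1 <- config$encoder_channels[1]
    params[["head_W"]] <- matrix(
      stats::rnorm(ch1 * config$out_channels, sd = sqrt(2 / ch1)),
      ch1, config$out_channels)
    params[["head_b"]] <- numeric(config$out_channels)
  })
  structure(
    list(config = config, params = params, bn_run = bn_run,
         classes = 0:(config$out_channels - 1L),
         history = tibble::tibble()),
    class = "unet_model"
  )
}

#' Number of trainable parameters of a U-Net
#' @param model a [build_unet()] model.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat("<unet_model> channels (", paste(cfg$encoder_channels, collapse = ", "),
      "), ", cfg$n_levels, " levels, ", cfg$out_channels, " classes, ",
      format(n_params(x), big.mark = ","), " parameters",
      if (nrow(x$history)) paste0(", trained ", nrow(x$history), " epochs"),
      "\n", sep = "")
  invisible(x)
}

# One conv(-bn)-lrelu unit. Returns output, cache and possibly updated
# running stats.
unit_fwd <- function(model, nm, x, train) {
  cfg <- model$config
  p <- model$params
  k <- if (nm == "head") 1L else cfg$kernel_size
  cv <- conv_fwd(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]], k)
  if (nm == "head") return(list(y = cv$y, conv = cv))
  y <- cv$y
  bn <- NULL
  if (cfg$batch_norm) {
    bn <- bn_fwd(y, p[[paste0(nm, "_g")]], p[[paste0(nm, "_beta")]],
                 model$bn_run[[nm]], train)
    model$bn_run[[nm]] <- bn$run
    y <- bn$y
    bn$y <- NULL
  }
  lr <- lrelu_fwd(y, cfg$leaky_slope)
  list(y = lr$y, conv = cv, bn = bn, lrelu = lr, model = model)
}

unit_bwd <- function(model, nm, cache, dy, grads) {
  cfg <- model$config
  p <- model$params
  k <- if (nm == "head") 1L else cfg$kernel_size
  if (nm != "head") {
    dy <- lrelu_bwd(cache$lrelu, dy, cfg$leaky_slope)
    if (cfg$batch_norm) {
      bb <- bn_bwd(cache$bn, dy, p[[paste0(nm, "_g")]])
      grads[[paste0(nm, "_g")]] <- bb$dg
      grads[[paste0(nm, "_beta")]] <- bb$dbeta
      dy <- bb$dx
    }
  }
  cb <- conv_bwd(cache$conv, dy, p[[paste0(nm, "_W")]], k)
  grads[[paste0(nm, "_W")]] <- cb$dW
  grads[[paste0(nm, "_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

# Full forward pass. x: [H, W, Cin, N] on the 0-1 scale.
unet_fwd <- function(model, x, train = FALSE) {
  cfg <- model$config
  L <- cfg$n_levels
  if (dim(x)[1] %% (2L^L) != 0L || dim(x)[2] %% (2L^L) != 0L) {
    stop("input size must be divisible by 2^n_levels", call. = FALSE)
  }
  caches <- list()
  skips <- list()
  for (l in seq_len(L)) {
    for (u in 1:2) {
      nm <- paste0("enc", l, "_u", u)
      r <- unit_fwd(model, nm, x, train)
      if (!is.null(r$model)) model <- r$model
      caches[[nm]] <- r[c("conv", "bn", "lrelu")]
      x <- r$y
    }
    skips[[l]] <- x
    pc <- pool_fwd(x)
    caches[[paste0("pool", l)]] <- pc
    x <- pc$y
  }
  for (u in 1:2) {
    nm <- paste0("bot_u", u)
    r <- unit_fwd(model, nm, x, train)
    if (!is.null(r$model)) model <- r$model
    caches[[nm]] <- r[c("conv", "bn", "lrelu")]
    x <- r$y
  }
  for (l in rev(seq_len(L))) {
    x <- upsample_fwd(x)
    nm <- paste0("dec", l, "_up")
    r <- unit_fwd(model, nm, x, train)
    if (!is.null(r$model)) model <- r$model
    caches[[nm]] <- r[c("conv", "bn", "lrelu")]
    x <- r$y
    skc <- dim(skips[[l]])[3]
    d <- dim(x)
    xc <- array(0, c(d[1], d[2], skc + d[3], d[4]))
    xc[, , seq_len(skc), ] <- skips[[l]]
    xc[, , skc + seq_len(d[3]), ] <- x
    caches[[paste0("cat", l)]] <- skc
    x <- xc
    for (u in 1:2) {
      nm <- paste0("dec", l, "_u", u)
      r <- unit_fwd(model, nm, x, train)
      if (!is.null(r$model)) model <- r$model
      caches[[nm]] <- r[c("conv", "bn", "lrelu")]
      x <- r$y
    }
  }
  r <- unit_fwd(model, "head", x, train)
  caches[["head"]] <- r["conv"]
  list(logits = r$y, caches = caches, model = model)
}

unet_bwd <- function(model, caches, dlogits) {
  cfg <- model$config
  L <- cfg$n_levels
  grads <- list()
  r <- unit_bwd(model, "head", caches[["head"]], dlogits, grads)
  dx <- r$dx; grads <- r$grads
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    for (u in 2:1) {
      nm <- paste0("dec", l, "_u", u)
      r <- unit_bwd(model, nm, caches[[nm]], dx, grads)
      dx <- r$dx; grads <- r$grads
    }
    skc <- caches[[paste0("cat", l)]]
    d <- dim(dx)
    dskips[[l]] <- dx[, , seq_len(skc), , drop = FALSE]
    dx <- dx[, , (skc + 1L):d[3], , drop = FALSE]
    nm <- paste0("dec", l, "_up")
    r <- unit_bwd(model, nm, caches[[nm]], dx, grads)
    grads <- r$grads
    dx <- upsample_bwd(r$dx)
  }
  for (u in 2:1) {
    nm <- paste0("bot_u", u)
    r <- unit_bwd(model, nm, caches[[nm]], dx, grads)
    dx <- r$dx; grads <- r$grads
  }
  for (l in rev(seq_len(L))) {
    dx <- pool_bwd(caches[[paste0("pool", l)]], dx)
    dx <- dx + dskips[[l]]
    for (u in 2:1) {
      nm <- paste0("enc", l, "_u", u)
      r <- unit_bwd(model, nm, caches[[nm]], dx, grads)
      dx <- r$dx; grads <- r$grads
    }
  }
  grads
}

# Class-weighted softmax cross-entropy ignoring `ignore_index` pixels.
# logits: [H, W, C, N]; labels: [H, W, N] with values 0..C-1 or ignore.
# Returns mean weighted loss and dloss/dlogits.
softmax_ce <- function(logits, labels, class_weights = NULL,
                       ignore_index = 255L) {
  d <- dim(logits)
  C <- d[3]
  if (is.null(class_weights)) class_weights <- rep(1, C)
  lm <- ch_mat(logits)
  lab <- as.vector(labels)
  valid <- which(lab != ignore_index)
  if (!length(valid)) stop("no labeled pixels in batch", call. = FALSE)
  lv <- lm[valid, , drop = FALSE]
  y <- lab[valid] + 1L
  mx <- do.call(pmax, as.data.frame(lv))
  e <- exp(lv - mx)
  p <- e / rowSums(e)
  wt <- class_weights[y]
  wsum <- sum(wt)
  py <- p[cbind(seq_along(y), y)]
  loss <- -sum(wt * log(pmax(py, 1e-12))) / wsum
  dp <- p * (wt / wsum)
  dp[cbind(seq_along(y), y)] <- dp[cbind(seq_along(y), y)] - wt / wsum
  dlm <- matrix(0, nrow(lm), C)
  dlm[valid, ] <- dp
  list(loss = loss, dlogits = un_ch_mat(dlm, d),
       n_valid = length(valid))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

stack_batch <- function(lst, idx, scale = 1) {
  d <- dim(lst[[idx[1]]])
  if (length(d) == 2L) d <- c(d, 1L)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (i in seq_along(idx)) {
    xi <- lst[[idx[i]]]
    x[, , , i] <- if (length(dim(xi)) == 2L) array(xi, c(d[1], d[2], 1L)) else xi
  }
  x * scale
}

stack_labels <- function(lst, idx) {
  d <- dim(lst[[idx[1]]])
  y <- array(255L, c(d[1], d[2], length(idx)))
  for (i in seq_along(idx)) y[, , i] <- lst[[idx[i]]]
  y
}

#' Train the U-Net on labeled tiles
#'
#' Minimizes class-weighted softmax cross-entropy (unannotated pixels,
#' labeled `ignore_index`, contribute nothing) with Adam at a fixed learning
#' rate. The validation loss is computed after every epoch and the weights
#' with the best validation loss are retained. Fully seeded: identical data,
#' config and seed reproduce identical weights and history.
#'
#' @param x_tiles list of H x W x 3 arrays (0-255).
#' @param y_tiles list of H x W integer label matrices (`0..out_channels-1`,
#'   `ignore_index` elsewhere).
#' @param config a [unet_config()].
#' @param split a [split_tiles()] result for `length(x_tiles)`; `NULL`
#'   computes one from `seed`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size tiles per gradient step.
#' @param seed integer seed (weights, shuffling, splitting).
#' @param class_weights per-class loss weights; `NULL` uses inverse label
#'   frequency over the training split, normalized to mean 1.
#' @param classes label values corresponding to output channels (for
#'   [predict_slide()]); defaults to `0:(out_channels-1)`.
#' @param ignore_index unannotated-pixel label (255).
#' @param verbose print per-epoch losses.
#' @return the trained `unet_model` with a `history` tibble (epoch,
#'   train_loss, val_loss, val_accuracy).
#' @export
train_unet <- function(x_tiles, y_tiles, config, split = NULL, epochs = 5L,
                       lr = 1e-3, batch_size = 4L, seed = 1L,
                       class_weights = NULL, classes = NULL,
                       ignore_index = 255L, verbose = FALSE) {
  stopifnot(length(x_tiles) == length(y_tiles), length(x_tiles) >= 2)
  if (is.null(split)) split <- split_tiles(length(x_tiles), seed)
  tr <- split$assignment$index[split$assignment$set == "train"]
  va <- split$assignment$index[split$assignment$set == "val"]
  if (!length(tr)) stop("empty training split", call. = FALSE)
  C <- config$out_channels
  if (is.null(class_weights)) {
    cnt <- numeric(C)
    for (i in tr) {
      lab <- y_tiles[[i]]
      lab <- lab[lab != ignore_index]
      cnt <- cnt + tabulate(lab + 1L, nbins = C)
    }
    class_weights <- ifelse(cnt > 0, sum(cnt) / (C * cnt), 0)
    class_weights <- pmin(class_weights, 20)
    pos <- class_weights > 0
    class_weights[pos] <- class_weights[pos] / mean(class_weights[pos])
  }
  model <- build_unet(config, seed)
  if (!is.null(classes)) model$classes <- as.integer(classes)
  state <- list(m = list(), v = list())
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, bn_run = model$bn_run)
  history <- list()
  epoch_seeds <- child_seeds(seed, epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample(tr))
    tl <- 0; tn <- 0L
    for (s in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, length(ord))]
      x <- stack_batch(x_tiles, idx, scale = 1 / 255)
      y <- stack_labels(y_tiles, idx)
      fw <- unet_fwd(model, x, train = TRUE)
      model <- fw$model
      ls <- softmax_ce(fw$logits, y, class_weights, ignore_index)
      grads <- unet_bwd(model, fw$caches, ls$dlogits)
      t_step <- t_step + 1L
      up <- adam_step(model$params, grads, state, lr, t_step)
      model$params <- up$params
      state <- up$state
      tl <- tl + ls$loss * length(idx); tn <- tn + length(idx)
    }
    val <- evaluate_unet(model, x_tiles, y_tiles, va, class_weights,
                         batch_size, ignore_index)
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = tl / tn,
      val_loss = val$loss, val_accuracy = val$accuracy
    )
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f acc %.4f",
                      ep, tl / tn, val$loss, val$accuracy))
    }
    if (!is.na(val$loss) && val$loss < best$loss) {
      best <- list(loss = val$loss, params = model$params, bn_run = model$bn_run)
    }
  }
  if (is.finite(best$loss)) {
    model$params <- best$params
    model$bn_run <- best$bn_run
  }
  model$history <- dplyr::bind_rows(history)
  model$class_weights <- class_weights
  model
}

evaluate_unet <- function(model, x_tiles, y_tiles, idx, class_weights,
                          batch_size = 4L, ignore_index = 255L) {
  if (!length(idx)) return(list(loss = NA_real_, accuracy = NA_real_))
  tl <- 0; tn <- 0L; hit <- 0; tot <- 0
  for (s in seq(1L, length(idx), by = batch_size)) {
    ii <- idx[s:min(s + batch_size - 1L, length(idx))]
    x <- stack_batch(x_tiles, ii, scale = 1 / 255)
    y <- stack_labels(y_tiles, ii)
    fw <- unet_fwd(model, x, train = FALSE)
    ls <- softmax_ce(fw$logits, y, class_weights, ignore_index)
    tl <- tl + ls$loss * length(ii); tn <- tn + length(ii)
    pred <- logits_argmax(fw$logits)
    valid <- y != ignore_index
    hit <- hit + sum(pred[valid] == y[valid])
    tot <- tot + sum(valid)
  }
  list(loss = tl / tn, accuracy = hit / tot)
}

# Per-pixel argmax over the class dimension; ties break to the lowest
# channel index. Returns [H, W, N] of 0-based channel indices.
logits_argmax <- function(logits) {
  d <- dim(logits)
  lm <- ch_mat(logits)
  array(max.col(lm, ties.method = "first") - 1L, c(d[1], d[2], d[4]))
}

#' Segment tiles with a trained U-Net
#'
#' @param model a trained [train_unet()] model.
#' @param x_tiles list of H x W x 3 arrays (0-255).
#' @param batch_size tiles per forward batch.
#' @return list of H x W integer matrices of class labels (via
#'   `model$classes`).
#' @export
predict_unet <- function(model, x_tiles, batch_size = 4L) {
  out <- vector("list", length(x_tiles))
  for (s in seq(1L, length(x_tiles), by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, length(x_tiles))
    x <- stack_batch(x_tiles, idx, scale = 1 / 255)
    fw <- unet_fwd(model, x, train = FALSE)
    am <- logits_argmax(fw$logits)
    for (i in seq_along(idx)) {
      out[[idx[i]]] <- matrix(model$classes[am[, , i] + 1L],
                              dim(am)[1], dim(am)[2])
    }
  }
  out
}

#' Stitch U-Net tile predictions into a full-slide mask
#'
#' Runs the model on every retained tile of a [extract_tiles()] tile set,
#' upsamples each tile's argmax map back to full resolution (nearest
#' neighbour, inverting the tile downsampling) and writes it at the tile's
#' box. Pixels of discarded (glass) tiles and areas outside the grid are set
#' to `ignore_index`.
#'
#' @param model a trained `unet_model`.
#' @param image H x W x 3 slide image (only its size is used).
#' @param tile_set a `tile_set` whose retained tile data match the model's
#'   input size.
#' @param ignore_index fill label (255).
#' @return integer H x W label matrix.
#' @export
predict_slide <- function(model, image, tile_set, ignore_index = 255L) {
  stopifnot(inherits(tile_set, "tile_set"))
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(as.integer(ignore_index), h, w)
  keep <- tile_set$tiles[tile_set$tiles$retained, ]
  if (!nrow(keep)) return(out)
  dat <- tile_set$data[as.character(keep$tile_id)]
  in_sz <- dim(dat[[1]])[1]
  if (in_sz %% (2L^model$config$n_levels) != 0L) {
    stop("tile size incompatible with model depth", call. = FALSE)
  }
  preds <- predict_unet(model, dat)
  f <- tile_set$downsample
  for (i in seq_len(nrow(keep))) {
    up <- upsample_nearest(preds[[i]], f)
    out[(keep$r0[i] + 1L):keep$r1[i], (keep$c0[i] + 1L):keep$c1[i]] <- up
  }
  out
}
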