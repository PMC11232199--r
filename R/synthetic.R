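#' Configuration for one synthetic pseudo-H&E slide
#'
#' The generator emulates a hematoxylin-and-eosin stained lung resection:
#' a tissue blob on white glass, a smooth closed tumor border inside it, and
#' spatially coherent patches of the ten annotation classes inside the border
#' with controllable coarse-class area fractions. Outside the border the
#' tissue is normal lung. Each class is rendered with a distinct base color
#' and procedural texture (dense dark-purple nuclei for carcinoma, pink
#' fibrillar streaks for fibrosis, dark punctate dots for inflammation,
#' red rings with pale lumina for vessels, a pale homogeneous smudge for
#' necrosis, and an alveolar lattice with white airspaces for normal lung),
#' then perturbed with global Gaussian intensity noise.
#'
#' @param height,width slide size in pixels.
#' @param pixel_size physical pixel size in micrometres per pixel
#'   (default 0.25, a 40x scan).
#' @param carcinoma_class `"ADCA"` or `"SCCA"`.
#' @param environment `"fibrotic"` or `"non_fibrotic"`; selects the default
#'   `target_fractions` (fibrosis-rich vs fibrosis-poor tumor bed).
#' @param target_fractions named numeric vector over the coarse classes
#'   (tumor, fibrosis, inflammation, vessels, necrosis, background) giving
#'   the desired area fraction of each inside the tumor border. Must be
#'   non-negative and sum to 1 (within 1e-6). `NULL` uses the
#'   environment-specific default.
#' @param texture_seed integer offset decorrelating texture noise from
#'   placement noise.
#' @param noise_sd standard deviation of the global additive intensity noise
#'   (0-255 scale).
#' @return A `synthetic_slide_config` list.
#' @export
synthetic_slide_config <- function(height = 192, width = 192,
                                   pixel_size = 0.25,
                                   carcinoma_class = c("ADCA", "SCCA"),
                                   environment = c("fibrotic", "non_fibrotic"),
                                   target_fractions = NULL,
                                   texture_seed = 1L,
                                   noise_sd = 6) {
  carcinoma_class <- match.arg(carcinoma_class)
  environment <- match.arg(environment)
  if (is.null(target_fractions)) {
    target_fractions <- if (environment == "fibrotic") {
      c(tumor = 0.35, fibrosis = 0.45, inflammation = 0.07,
        vessels = 0.05, necrosis = 0.04, background = 0.04)
    } else {
      c(tumor = 0.55, fibrosis = 0.15, inflammation = 0.10,
        vessels = 0.07, necrosis = 0.06, background = 0.07)
    }
  }
  cfg <- structure(
    list(height = as.integer(height), width = as.integer(width),
         pixel_size = pixel_size, carcinoma_class = carcinoma_class,
         environment = environment, target_fractions = target_fractions,
         texture_seed = as.integer(texture_seed), noise_sd = noise_sd),
    class = "synthetic_slide_config"
  )
  validate_slide_config(cfg)
}

validate_slide_config <- function(cfg) {
  tf <- cfg$target_fractions
  coarse <- c("tumor", "fibrosis", "inflammation", "vessels", "necrosis", "background")
  if (is.null(names(tf)) || !all(names(tf) %in% coarse)) {
    stop("target_fractions must be named over the coarse classes", call. = FALSE)
  }
  if (any(tf < 0)) stop("target_fractions must be non-negative", call. = FALSE)
  if (abs(sum(tf) - 1) > 1e-6) {
    stop("target_fractions must sum to 1 (got ", signif(sum(tf), 6), ")", call. = FALSE)
  }
  if (cfg$pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (cfg$height < 32 || cfg$width < 32) {
    stop("slide must be at least 32 x 32 pixels", call. = FALSE)
  }
  # complete the vector in canonical order
  full <- stats::setNames(numeric(6), coarse)
  full[names(tf)] <- tf
  cfg$target_fractions <- full
  cfg
}

# Smooth closed curve: a circle with low-order Fourier perturbations of its
# radius. Returns a vertex matrix (x, y) in pixel-center coordinates.
fourier_blob <- function(center, r0, n_vertices = 720, amp = 0.12,
                         harmonics = 2:5) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(1, n_vertices)
  for (k in harmonics) {
    r <- r + amp / length(harmonics) * stats::rnorm(1) * cos(k * theta + stats::runif(1, 0, 2 * pi))
  }
  r <- r0 * pmax(r, 0.4)
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

#' Generate one synthetic annotated slide
#'
#' Deterministic for a fixed `(config, seed)` pair: two calls return
#' byte-identical images and masks. Coarse-class regions inside the tumor
#' border are carved as quantile bands of a smooth random field, so the
#' realized area fractions match `config$target_fractions` to within a pixel
#' of rounding and the regions are spatially coherent blobs rather than salt
#' and pepper.
#'
#' @param config a [synthetic_slide_config()].
#' @param seed integer seed.
#' @param case_id,arm optional labels carried through to manifests.
#' @return An `annotated_slide`: list with `image` (H x W x 3 integer array,
#'   0-255), `truth_mask` (H x W integer fine-class labels, `ignore_index`
#'   outside tissue), `tumor_border` (polygon vertex matrix), `border_mask`
#'   (its rasterization), `tally` (tibble of realized coarse pixel counts
#'   inside the border), `pixel_size`, `case_id`, `arm`, `config`, `seed`.
#' @examples
#' sl <- generate_slide(synthetic_slide_config(height = 96, width = 96), seed = 1)
#' sl$tally
#' @export
generate_slide <- function(config, seed, case_id = "synthetic_1", arm = NA_character_) {
  config <- validate_slide_config(config)
  schema <- tme_schema()
  h <- config$height; w <- config$width
  with_seed(as.numeric(seed) * 2654435 + config$texture_seed, {
    ## tissue blob on glass
    tissue_poly <- fourier_blob(center = c(w / 2, h / 2),
                                r0 = 0.46 * min(h, w), amp = 0.06)
    tissue <- rasterize_polygon(tissue_poly, h, w)

    ## tumor border: smooth closed curve inside the tissue
    center <- c(w / 2 + stats::runif(1, -0.03, 0.03) * w,
                h / 2 + stats::runif(1, -0.03, 0.03) * h)
    border_poly <- fourier_blob(center, r0 = 0.30 * min(h, w), amp = 0.12)
    border_mask <- rasterize_polygon(border_poly, h, w) & tissue

    ## coarse class placement inside the border: quantile bands of a smooth
    ## field give exact target counts with coherent blobs
    n_in <- sum(border_mask)
    if (n_in < 16) stop("degenerate geometry: tumor border encloses almost no tissue")
    field <- smooth_noise(h, w, sigma = min(h, w) / 14)
    vals <- field[border_mask]
    ord <- order(vals)
    tf <- config$target_fractions
    counts <- diff(c(0, round(cumsum(tf) * n_in)))
    coarse_names <- names(tf)
    coarse_assign <- rep(NA_character_, n_in)
    coarse_assign[ord] <- rep(coarse_names, counts)

    coarse_grid <- matrix(NA_character_, h, w)
    coarse_grid[border_mask] <- coarse_assign
    coarse_grid[tissue & !border_mask] <- "background"

    ## refine to fine classes
    truth <- matrix(schema$ignore_index, h, w)
    sub_field <- smooth_noise(h, w, sigma = min(h, w) / 20)
    cls <- schema$classes
    carcinoma_idx <- cls$index[cls$fine == config$carcinoma_class]
    truth[!is.na(coarse_grid) & coarse_grid == "tumor"] <- carcinoma_idx
    split_subtypes <- function(coarse_name, fine_names) {
      sel <- which(!is.na(coarse_grid) & coarse_grid == coarse_name)
      if (!length(sel)) return(invisible(NULL))
      v <- sub_field[sel]
      qs <- stats::quantile(v, probs = seq_len(length(fine_names) - 1L) / length(fine_names))
      band <- findInterval(v, qs) + 1L
      truth[sel] <<- cls$index[match(fine_names, cls$fine)][band]
      invisible(NULL)
    }
    split_subtypes("fibrosis", c("fibrosis_elastotic", "fibrosis_dense", "fibrosis_loose"))
    split_subtypes("inflammation", c("inflammation_macrophage", "inflammation_lymphoplasmacytic"))
    for (nm in c("vessels", "necrosis", "background")) {
      sel <- !is.na(coarse_grid) & coarse_grid == nm
      fine_nm <- switch(nm, vessels = "vessels", necrosis = "necrosis",
                        background = "background_normal")
      truth[sel] <- cls$index[cls$fine == fine_nm]
    }

    ## render
    image <- render_pseudo_he(truth, schema, config, h, w)

    tally <- tibble::tibble(
      class = coarse_names,
      pixels = as.integer(counts),
      fraction = counts / n_in
    )
    structure(
      list(image = image, truth_mask = truth,
           tumor_border = border_poly, border_mask = border_mask,
           tally = tally, pixel_size = config$pixel_size,
           case_id = case_id, arm = arm, config = config, seed = seed),
      class = "annotated_slide"
    )
  })
}

# Procedural H&E-like rendering. Carcinoma: dense dark nuclei blobs on a
# purple base; fibrosis: anisotropic pink streaks; inflammation: punctate
# dark dots; vessels: rings with pale lumina; necrosis: pale smudge; normal
# lung: alveolar lattice with white airspaces. Glass is near-white.
render_pseudo_he <- function(truth, schema, config, h, w) {
  cls <- schema$classes
  img <- array(0, dim = c(h, w, 3))
  glass <- truth == schema$ignore_index
  for (c in 1:3) img[, , c][glass] <- 250

  nuclei <- smooth_noise(h, w, sigma = 1.2)
  streaks <- smooth_noise(h, w, sigma = 1) |> sep_blur(0.6, 5)
  streaks <- (streaks - mean(streaks)) / stats::sd(streaks)
  dots <- upsample_nearest(
    matrix(stats::runif(ceiling(h / 2) * ceiling(w / 2)) < 0.10, ceiling(h / 2)),
    2
  )[seq_len(h), seq_len(w)]
  rings_f <- smooth_noise(h, w, sigma = 6)
  rings <- abs(rings_f) < 0.25
  lumen <- rings_f >= 0.25
  alveoli <- smooth_noise(h, w, sigma = 2.2)

  for (k in seq_len(nrow(cls))) {
    sel <- truth == cls$index[k]
    if (!any(sel)) next
    base <- hex_to_rgb(cls$color[k])
    mod <- matrix(1, h, w)
    coarse <- cls$coarse[k]
    if (coarse == "tumor") {
      mod[nuclei > 0.1] <- 0.55          # dark nuclei blobs
      mod[nuclei <= 0.1] <- 1.25         # eosinophilic cytoplasm between
    } else if (coarse == "fibrosis") {
      mod <- 1 + 0.25 * streaks          # fibrillar pink streaks
    } else if (coarse == "inflammation") {
      mod[dots] <- 0.45                  # punctate dark cells
      mod[!dots] <- 1.15
    } else if (coarse == "vessels") {
      mod[rings] <- 0.65                 # vessel wall ring
      mod[lumen] <- 1.45                 # pale lumen
    } else if (coarse == "necrosis") {
      mod <- 1 + 0.04 * nuclei           # homogeneous pale smudge
    } else {                             # normal lung lattice
      mod[alveoli > 0] <- 1.55           # white airspace
      mod[alveoli <= 0] <- 0.95          # alveolar walls
    }
    for (c in 1:3) {
      ch <- img[, , c]
      ch[sel] <- base[c] * mod[sel]
      img[, , c] <- ch
    }
  }
  ## hue-preserving highlight compression: pale tissue keeps an eosin tint
  ## instead of clipping to pure white (glass must stay the brightest, least
  ## saturated material on the slide)
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  scale <- matrix(1, h, w)
  over <- !glass & mx > 246
  scale[over] <- 246 / mx[over]
  for (c in 1:3) img[, , c] <- img[, , c] * scale
  ## luminance noise everywhere (keeps glass gray); mild chroma noise on
  ## tissue only
  lum <- matrix(stats::rnorm(h * w, sd = config$noise_sd), h, w)
  for (c in 1:3) {
    chroma <- matrix(stats::rnorm(h * w, sd = config$noise_sd / 2), h, w)
    chroma[glass] <- 0
    img[, , c] <- img[, , c] + lum + chroma
  }
  array(as.integer(round(clip255(img))), dim = dim(img))
}

#' @export
print.annotated_slide <- function(x, ...) {
  cat("<annotated_slide> ", x$case_id,
      if (!is.na(x$arm)) paste0(" [", x$arm, "]") else "",
      ": ", nrow(x$truth_mask), "x", ncol(x$truth_mask),
      " px @ ", x$pixel_size, " um/px\n", sep = "")
  print(x$tally)
  invisible(x)
}

#' Generate a seeded synthetic cohort across study arms
#'
#' Arms cross carcinoma type (ADCA/SCCA) with lung environment
#' (fibrotic/non-fibrotic). Per-slide coarse target fractions are drawn from
#' arm-specific distributions; by default the fibrotic arms are fibrosis-rich
#' (mean fibrosis fraction 0.45 inside the tumor bed) and the non-fibrotic
#' arms fibrosis-poor (mean 0.15), so downstream group comparisons have a
#' recoverable planted effect. Default arm sizes mirror a 76-case NSCLC
#' cohort: 28 + 25 ADCA and 19 + 4 SCCA in fibrotic/non-fibrotic lung.
#'
#' @param n_per_arm named integer vector over
#'   `ADCA_fibrotic, ADCA_non_fibrotic, SCCA_fibrotic, SCCA_non_fibrotic`.
#' @param seed integer seed.
#' @param height,width per-slide size in pixels.
#' @param fibrosis_mean named vector (`fibrotic`, `non_fibrotic`) of mean
#'   fibrosis fractions inside the tumor border.
#' @param fraction_sd between-slide standard deviation of the fibrosis
#'   fraction draw.
#' @return list of [generate_slide()] slides with a `manifest` attribute
#'   (tibble: case_id, arm, carcinoma, environment, planted fractions).
#' @export
generate_cohort <- function(n_per_arm = c(ADCA_fibrotic = 28L,
                                          ADCA_non_fibrotic = 25L,
                                          SCCA_fibrotic = 19L,
                                          SCCA_non_fibrotic = 4L),
                            seed = 1L,
                            height = 160, width = 160,
                            fibrosis_mean = c(fibrotic = 0.45, non_fibrotic = 0.15),
                            fraction_sd = 0.05) {
  stopifnot(all(n_per_arm >= 0))
  arms <- names(n_per_arm)
  stopifnot(!is.null(arms), all(grepl("^(ADCA|SCCA)_(fibrotic|non_fibrotic)$", arms)))
  n_total <- sum(n_per_arm)
  if (n_total == 0L) {
    out <- list()
    attr(out, "manifest") <- tibble::tibble(
      case_id = character(), arm = character(),
      carcinoma = character(), environment = character(),
      target_fibrosis = numeric()
    )
    return(out)
  }
  seeds <- child_seeds(seed, n_total + 1L)
  slides <- vector("list", n_total)
  man <- vector("list", n_total)
  i <- 0L
  draw <- with_seed(seeds[n_total + 1L], {
    lapply(seq_along(arms), function(a) {
      env <- sub("^(ADCA|SCCA)_", "", arms[a])
      n <- n_per_arm[a]
      if (n == 0L) return(NULL)
      fib <- pmin(pmax(stats::rnorm(n, fibrosis_mean[[env]], fraction_sd), 0.02), 0.75)
      list(fib = fib)
    })
  })
  for (a in seq_along(arms)) {
    arm <- arms[a]
    carcinoma <- sub("_(fibrotic|non_fibrotic)$", "", arm)
    env <- sub("^(ADCA|SCCA)_", "", arm)
    for (j in seq_len(n_per_arm[a])) {
      i <- i + 1L
      fib <- draw[[a]]$fib[j]
      rest <- 1 - fib
      # split the remainder with fixed relative weights: tumor dominates
      wts <- c(tumor = 0.62, inflammation = 0.12, vessels = 0.09,
               necrosis = 0.09, background = 0.08)
      tf <- c(fibrosis = fib, wts * rest)
      cfg <- synthetic_slide_config(
        height = height, width = width,
        carcinoma_class = carcinoma,
        environment = if (env == "fibrotic") "fibrotic" else "non_fibrotic",
        target_fractions = tf,
        texture_seed = i
      )
      case_id <- sprintf("%s_%02d", arm, j)
      slides[[i]] <- generate_slide(cfg, seed = seeds[i], case_id = case_id, arm = arm)
      man[[i]] <- tibble::tibble(
        case_id = case_id, arm = arm, carcinoma = carcinoma,
        environment = env, target_fibrosis = fib
      )
    }
  }
  attr(slides, "manifest") <- dplyr::bind_rows(man)
  slides
}

#' Sample sparse disc-shaped annotation strokes from the ground truth
#'
#' Emulates a pathologist's initial sparse labeling: for every fine class
#' present on the slide, `strokes_per_class` disc strokes are stamped at
#' random locations within that class's true region. Stroke pixels are
#' clipped to the class region, so every emitted label agrees with the truth
#' mask by construction.
#'
#' @param slide an `annotated_slide`.
#' @param strokes_per_class strokes per present class (>= 1). The default 21
#'   on a 10-class slide yields 210 strokes, matching a realistic per-slide
#'   annotation workload.
#' @param stroke_radius disc radius in pixels.
#' @param seed integer seed.
#' @return integer H x W sparse label grid (`ignore_index` where
#'   unannotated), with attributes `strokes` (tibble: fine class index, row,
#'   col, radius) and `n_strokes`.
#' @export
sparse_annotations <- function(slide, strokes_per_class = 21L,
                               stroke_radius = 4L, seed = 1L) {
  stopifnot(inherits(slide, "annotated_slide"), strokes_per_class >= 1L)
  schema <- tme_schema()
  truth <- slide$truth_mask
  h <- nrow(truth); w <- ncol(truth)
  present <- sort(intersect(unique(as.vector(truth)), schema$classes$index))
  absent <- setdiff(schema$classes$index, present)
  if (length(absent)) {
    warning("classes absent from slide, skipped: ",
            paste(schema$classes$fine[match(absent, schema$classes$index)],
                  collapse = ", "), call. = FALSE)
  }
  sparse <- matrix(schema$ignore_index, h, w)
  strokes <- list()
  with_seed(seed, {
    for (k in present) {
      pix <- which(truth == k)
      centers <- pix[sample.int(length(pix), strokes_per_class,
                                replace = length(pix) < strokes_per_class)]
      for (ci in centers) {
        r0 <- (ci - 1L) %% h + 1L
        c0 <- (ci - 1L) %/% h + 1L
        sparse <- stamp_disc(sparse, truth, r0, c0, stroke_radius, k)
      }
      strokes[[length(strokes) + 1L]] <- tibble::tibble(
        class_index = k,
        row = (centers - 1L) %% h + 1L,
        col = (centers - 1L) %/% h + 1L,
        radius = stroke_radius
      )
    }
  })
  strokes <- if (length(strokes)) dplyr::bind_rows(strokes) else
    tibble::tibble(class_index = integer(), row = integer(),
                   col = integer(), radius = integer())
  attr(sparse, "strokes") <- strokes
  attr(sparse, "n_strokes") <- nrow(strokes)
  sparse
}

# Stamp a disc of label k at (r0, c0), restricted to pixels where the truth
# already carries label k (annotation soundness by construction).
stamp_disc <- function(sparse, truth, r0, c0, radius, k) {
  h <- nrow(sparse); w <- ncol(sparse)
  rr <- max(1L, r0 - radius):min(h, r0 + radius)
  cc <- max(1L, c0 - radius):min(w, c0 + radius)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  sub_t <- truth[rr, cc, drop = FALSE]
  sub_s <- sparse[rr, cc, drop = FALSE]
  hit <- d2 <= radius^2 & sub_t == k
  sub_s[hit] <- k
  sparse[rr, cc] <- sub_s
  sparse
}

#' Programmatic expert oracle: corrective strokes on the worst classes
#'
#' Stands in for the pathologist's review-revise step of the
#' expert-in-the-loop workflow. It scores the predicted mask per class
#' against the ground truth, selects the `k_worst` lowest-accuracy classes
#' present on the slide, and stamps new correct strokes centred on
#' mispredicted pixels of those classes.
#'
#' @param slide an `annotated_slide`.
#' @param predicted_mask integer H x W fine-class prediction.
#' @param k_worst number of worst classes to target per review round.
#' @param strokes strokes per targeted class.
#' @param stroke_radius disc radius in pixels.
#' @param seed integer seed.
#' @return sparse label grid as in [sparse_annotations()]; empty (all
#'   `ignore_index`, `n_strokes` 0) when the prediction is perfect.
#' @export
expert_oracle <- function(slide, predicted_mask, k_worst = 2L, strokes = 10L,
                          stroke_radius = 4L, seed = 1L) {
  stopifnot(inherits(slide, "annotated_slide"))
  truth <- slide$truth_mask
  if (!identical(dim(truth), dim(predicted_mask))) {
    stop("predicted_mask shape must match the slide", call. = FALSE)
  }
  schema <- tme_schema()
  h <- nrow(truth); w <- ncol(truth)
  sparse <- matrix(schema$ignore_index, h, w)
  present <- sort(intersect(unique(as.vector(truth)), schema$classes$index))
  acc <- vapply(present, function(k) {
    sel <- truth == k
    mean(predicted_mask[sel] == k)
  }, numeric(1))
  wrong_any <- present[acc < 1]
  if (!length(wrong_any)) {
    attr(sparse, "strokes") <- tibble::tibble(class_index = integer(),
                                              row = integer(), col = integer(),
                                              radius = integer())
    attr(sparse, "n_strokes") <- 0L
    return(sparse)
  }
  targets <- present[order(acc)][seq_len(min(k_worst, length(wrong_any)))]
  targets <- intersect(targets, wrong_any)
  stroke_rows <- list()
  with_seed(seed, {
    for (k in targets) {
      mis <- which(truth == k & predicted_mask != k)
      if (!length(mis)) next
      centers <- mis[sample.int(length(mis), strokes,
                                replace = length(mis) < strokes)]
      for (ci in centers) {
        r0 <- (ci - 1L) %% h + 1L
        c0 <- (ci - 1L) %/% h + 1L
        sparse <- stamp_disc(sparse, truth, r0, c0, stroke_radius, k)
      }
      stroke_rows[[length(stroke_rows) + 1L]] <- tibble::tibble(
        class_index = k,
        row = (centers - 1L) %% h + 1L,
        col = (centers - 1L) %/% h + 1L,
        radius = stroke_radius
      )
    }
  })
  st <- if (length(stroke_rows)) dplyr::bind_rows(stroke_rows) else
    tibble::tibble(class_index = integer(), row = integer(),
                   col = integer(), radius = integer())
  attr(sparse, "strokes") <- st
  attr(sparse, "n_strokes") <- nrow(st)
  sparse
}

# Merge two sparse grids; error on conflicting labels at the same pixel.
merge_sparse <- function(a, b, ignore_index = 255L) {
  both <- a != ignore_index & b != ignore_index
  if (any(a[both] != b[both])) {
    stop("conflicting annotation labels at ", sum(a[both] != b[both]),
         " pixel(s)", call. = FALSE)
  }
  out <- a
  out[b != ignore_index] <- b[b != ignore_index]
  na <- attr(a, "n_strokes"); nb <- attr(b, "n_strokes")
  attr(out, "strokes") <- dplyr::bind_rows(attr(a, "strokes"), attr(b, "strokes"))
  attr(out, "n_strokes") <- (if (is.null(na)) 0L else na) + (if (is.null(nb)) 0L else nb)
  out
}
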