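#' Random-forest stage configuration
#'
#' The interactive pixel classifier is a 50-tree random forest over a
#' QuPath-style multiscale texture basis: Gaussian-smoothed intensity,
#' gradient magnitude and local standard deviation of the RGB and optical
#' density channels at a small set of scales.
#'
#' @param n_trees number of trees (default 50).
#' @param feature_scales Gaussian sigmas in pixels (default 1, 2, 4).
#' @param max_depth optional tree depth cap (translated to a node-count cap);
#'   `NULL` grows trees fully.
#' @param seed integer seed used at fit time.
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 50L, feature_scales = c(1, 2, 4),
                      max_depth = NULL, seed = 1L) {
  stopifnot(n_trees >= 1, length(feature_scales) >= 1, all(feature_scales > 0))
  structure(list(n_trees = as.integer(n_trees),
                 feature_scales = feature_scales,
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "rf_config")
}

#' Multiscale per-pixel feature stack
#'
#' For each of the six base channels (R, G, B and their optical densities)
#' and each scale sigma, computes the Gaussian-smoothed channel, the gradient
#' magnitude of the smoothed channel (central differences), and the local
#' standard deviation (Gaussian-weighted second moment about the local mean).
#' Feature count is therefore `6 * length(scales) * 3`. Deterministic.
#'
#' @param image H x W x 3 array, 0-255.
#' @param scales Gaussian sigmas in pixels.
#' @return H x W x F numeric array with a `feature_names` attribute.
#' @export
pixel_features <- function(image, scales = c(1, 2, 4)) {
  stopifnot(length(scales) >= 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  chans <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3])
  od <- od_transform(image)
  chans <- c(chans, list(odR = od[, , 1], odG = od[, , 2], odB = od[, , 3]))
  nf <- length(chans) * length(scales) * 3L
  out <- array(0, dim = c(h, w, nf))
  nms <- character(nf)
  i <- 0L
  for (cn in names(chans)) {
    ch <- chans[[cn]]
    for (s in scales) {
      sm <- sep_blur(ch, s)
      # gradient magnitude of the smoothed channel
      pr <- pad_replicate(sm, 1L)
      gy <- (pr[3:(h + 2), 2:(w + 1)] - pr[1:h, 2:(w + 1)]) / 2
      gx <- (pr[2:(h + 1), 3:(w + 2)] - pr[2:(h + 1), 1:w]) / 2
      # local std: smoothed second moment about the local mean
      v <- sep_blur((ch - sm)^2, s)
      for (f in list(sm, sqrt(gx^2 + gy^2), sqrt(pmax(v, 0)))) {
        i <- i + 1L
        out[, , i] <- f
      }
      nms[i - 2:0] <- paste0(cn, "_s", s, c("_smooth", "_grad", "_sd"))
    }
  }
  attr(out, "feature_names") <- nms
  out
}

#' Flatten a feature stack at a set of pixel indices
#'
#' @param feature_stack an H x W x F array from [pixel_features()].
#' @param idx linear pixel indices into the H x W plane.
#' @return an `length(idx)` x F matrix with feature-name columns.
#' @export
features_at <- function(feature_stack, idx) {
  h <- dim(feature_stack)[1]; w <- dim(feature_stack)[2]
  nf <- dim(feature_stack)[3]
  m <- matrix(feature_stack, nrow = h * w, ncol = nf)[idx, , drop = FALSE]
  colnames(m) <- attr(feature_stack, "feature_names")
  m
}

#' Fit the random-forest pixel classifier
#'
#' Trains on sparse-annotation pixels only: `x` holds the feature rows at
#' annotated pixels and `y` their fine-class labels. Fitting is seeded, so a
#' fixed `(data, config)` pair reproduces identical predictions.
#'
#' @param x numeric matrix of features at annotated pixels.
#' @param y integer fine-class labels (at least two distinct classes).
#' @param config an [rf_config()].
#' @return a `tme_rf` model: list with the fitted forest, the class index
#'   vector and the config.
#' @export
rf_fit <- function(x, y, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"), nrow(x) == length(y))
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2) {
    stop("at least two classes are required to train the classifier", call. = FALSE)
  }
  yf <- factor(as.integer(y), levels = classes)
  maxnodes <- if (!is.null(config$max_depth)) 2L^as.integer(config$max_depth) else NULL
  # stratified balanced bootstrap: annotation workloads are very uneven
  # across classes (corrective strokes pile onto a few classes), and an
  # unbalanced bootstrap would let those classes dominate the vote
  nmin <- min(table(yf))
  forest <- with_seed(config$seed, {
    randomForest::randomForest(x = x, y = yf, ntree = config$n_trees,
                               maxnodes = maxnodes,
                               strata = yf,
                               sampsize = rep(nmin, length(classes)))
  })
  structure(list(forest = forest, classes = classes, config = config),
            class = "tme_rf")
}

#' @export
print.tme_rf <- function(x, ...) {
  cat("<tme_rf> ", x$forest$ntree, " trees, ", length(x$classes),
      " classes, ", length(x$forest$forest$xbestsplit) > 0, "\n", sep = "")
  invisible(x)
}

#' Segment a full slide with a fitted random forest
#'
#' Computes the feature stack at the model's configured scales and assigns
#' every tissue pixel the class with the most tree votes; vote ties break to
#' the lowest class index. Non-tissue pixels are set to `ignore_index`.
#'
#' @param model a [rf_fit()] model.
#' @param image H x W x 3 array, 0-255.
#' @param tissue_mask logical mask of pixels to classify; `NULL` classifies
#'   everything.
#' @param ignore_index label for non-tissue pixels (default 255).
#' @param chunk pixels scored per prediction batch.
#' @param feature_stack optional precomputed [pixel_features()] stack.
#' @return integer H x W label matrix.
#' @export
rf_segment <- function(model, image, tissue_mask = NULL, ignore_index = 255L,
                       chunk = 50000L, feature_stack = NULL) {
  stopifnot(inherits(model, "tme_rf"))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(feature_stack)) {
    feature_stack <- pixel_features(image, model$config$feature_scales)
  }
  if (dim(feature_stack)[3] != length(model$forest$forest$ncat)) {
    stop("feature stack does not match the model's feature configuration",
         call. = FALSE)
  }
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, h, w)
  out <- matrix(as.integer(ignore_index), h, w)
  idx <- which(tissue_mask)
  if (!length(idx)) return(out)
  for (start in seq(1L, length(idx), by = chunk)) {
    sl <- idx[start:min(start + chunk - 1L, length(idx))]
    votes <- stats::predict(model$forest, features_at(feature_stack, sl),
                            type = "vote", norm.votes = FALSE)
    # columns are factor levels in increasing class-index order;
    # ties.method = "first" implements lowest-index tie-breaking
    out[sl] <- model$classes[max.col(votes, ties.method = "first")]
  }
  out
}

#' Pixel accuracy of a prediction against a reference mask
#'
#' Computed over annotated pixels only (reference != `ignore_index`).
#'
#' @param pred,truth integer label matrices of equal shape.
#' @param ignore_index unannotated label (255).
#' @return fraction of annotated pixels predicted correctly.
#' @export
pixel_accuracy <- function(pred, truth, ignore_index = 255L) {
  sel <- truth != ignore_index
  mean(pred[sel] == truth[sel])
}

per_class_accuracy <- function(pred, truth, ignore_index = 255L) {
  present <- sort(setdiff(unique(as.vector(truth)), ignore_index))
  tibble::tibble(
    class_index = present,
    accuracy = vapply(present, function(k) mean(pred[truth == k] == k), numeric(1)),
    support = vapply(present, function(k) sum(truth == k), numeric(1))
  )
}

#' Expert-in-the-loop iterative refinement of the random-forest segmentation
#'
#' Implements the review-revise loop: fit the forest on the current sparse
#' annotations, segment the whole slide, score against the slide's ground
#' truth, and either stop (accuracy above target, iteration cap reached, or
#' improvement below the notable-improvement floor) or ask the expert oracle
#' for corrective strokes on the worst-performing classes and repeat. The
#' annotation count never decreases across iterations.
#'
#' @param slide an `annotated_slide`.
#' @param annotations initial sparse label grid (e.g. [sparse_annotations()]).
#' @param oracle function `(slide, predicted_mask, k_worst, strokes, seed)`
#'   returning additional sparse labels; defaults to [expert_oracle()].
#' @param config an [rf_config()].
#' @param max_iter iteration cap (default 5).
#' @param target_accuracy stop once pixel accuracy exceeds this (default 0.80).
#' @param min_improvement smallest accuracy gain regarded as notable
#'   (default 0.005).
#' @param k_worst,oracle_strokes classes targeted and strokes added per
#'   review round.
#' @param seed integer seed for the oracle's stroke sampling.
#' @return an `eitl_result`: list with `mask` (final segmentation), `model`,
#'   `trace` (tibble: iteration, n_strokes, n_annotated_pixels, accuracy,
#'   per_class list-column) and `stop_reason`.
#' @export
eitl_refine <- function(slide, annotations, oracle = expert_oracle,
                        config = rf_config(), max_iter = 5L,
                        target_accuracy = 0.80, min_improvement = 0.005,
                        k_worst = 2L, oracle_strokes = 10L, seed = 1L) {
  stopifnot(inherits(slide, "annotated_slide"), is.function(oracle))
  schema <- tme_schema()
  ign <- schema$ignore_index
  if (!any(annotations != ign)) stop("initial annotations are empty", call. = FALSE)
  feats <- pixel_features(slide$image, config$feature_scales)
  tissue <- slide$truth_mask != ign
  seeds <- child_seeds(seed, max_iter)
  trace <- list()
  prev_acc <- -Inf
  stop_reason <- "max_iterations"
  pred <- NULL; model <- NULL
  for (it in seq_len(max_iter)) {
    ann_idx <- which(annotations != ign)
    model <- rf_fit(features_at(feats, ann_idx), annotations[ann_idx], config)
    pred <- rf_segment(model, slide$image, tissue_mask = tissue,
                       ignore_index = ign, feature_stack = feats)
    acc <- pixel_accuracy(pred, slide$truth_mask, ign)
    trace[[it]] <- tibble::tibble(
      iteration = it,
      n_strokes = attr(annotations, "n_strokes") %||% NA_integer_,
      n_annotated_pixels = length(ann_idx),
      accuracy = acc,
      per_class = list(per_class_accuracy(pred, slide$truth_mask, ign))
    )
    if (acc > target_accuracy) { stop_reason <- "target_reached"; break }
    if (it == max_iter) { stop_reason <- "max_iterations"; break }
    if (acc - prev_acc < min_improvement) { stop_reason <- "no_improvement"; break }
    prev_acc <- acc
    extra <- oracle(slide, pred, k_worst = k_worst, strokes = oracle_strokes,
                    seed = seeds[it])
    if ((attr(extra, "n_strokes") %||% sum(extra != ign)) == 0) {
      stop_reason <- "no_improvement"
      break
    }
    annotations <- merge_sparse(annotations, extra, ign)
  }
  structure(
    list(mask = pred, model = model, trace = dplyr::bind_rows(trace),
         stop_reason = stop_reason, annotations = annotations),
    class = "eitl_result"
  )
}

#' @export
print.eitl_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<eitl_result> ", n, " iteration(s), stop: ", x$stop_reason,
      ", final accuracy ", round(x$trace$accuracy[n], 4), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive the tumor border from a multiclass segmentation
#'
#' Collapses the fine classes to a binary tumor vs non-tumor grid (both
#' carcinoma classes count as tumor), morphologically closes it, fills
#' holes, keeps components of at least `min_area` pixels, and traces the
#' boundary polygon(s) of the result.
#'
#' @param mask integer fine-class label matrix.
#' @param min_area minimum component area in pixels.
#' @param close_size diameter of the closing structuring element.
#' @param schema a [tme_schema()].
#' @return a `tumor_border` object: list with `polygons` (list of vertex
#'   matrices in pixel-center coordinates), `mask` (the processed binary
#'   region) and `area_pixels`. Empty (zero polygons, warning) when the mask
#'   contains no tumor.
#' @export
tumor_border <- function(mask, min_area = 64L, close_size = 7L,
                         schema = tme_schema()) {
  tumor_idx <- schema$classes$index[schema$classes$coarse == "tumor"]
  bin <- matrix(mask %in% tumor_idx, nrow(mask), ncol(mask))
  if (!any(bin)) {
    warning("no tumor pixels in mask; empty border", call. = FALSE)
    return(structure(list(polygons = list(), mask = bin, area_pixels = 0L),
                     class = "tumor_border"))
  }
  bin <- EBImage::closing(bin, EBImage::makeBrush(close_size, "disc")) > 0
  bin <- EBImage::fillHull(bin) > 0
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  bin <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (!any(bin)) {
    warning("no tumor component reaches min_area; empty border", call. = FALSE)
    return(structure(list(polygons = list(), mask = bin, area_pixels = 0L),
                     class = "tumor_border"))
  }
  polys <- trace_boundaries(bin)
  structure(list(polygons = polys, mask = bin, area_pixels = sum(bin)),
            class = "tumor_border")
}

#' @export
print.tumor_border <- function(x, ...) {
  cat("<tumor_border> ", length(x$polygons), " polygon(s), ",
      x$area_pixels, " pixels\n", sep = "")
  invisible(x)
}

# Trace closed 0.5-level contours of a binary matrix in pixel-center
# coordinates (x = col - 0.5, y = row - 0.5). The matrix is zero-padded so
# regions touching the image edge still yield closed polygons.
trace_boundaries <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  z <- matrix(0, h + 2L, w + 2L)
  z[2:(h + 1L), 2:(w + 1L)] <- bin
  # grid coordinates of padded pixel centers
  xs <- (0:(h + 1L)) - 1.5 + 1   # row centers: -0.5 .. h + 0.5
  ys <- (0:(w + 1L)) - 1.5 + 1
  cl <- grDevices::contourLines(x = xs, y = ys, z = z, levels = 0.5)
  lapply(cl, function(ct) cbind(x = ct$y, y = ct$x))
}
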