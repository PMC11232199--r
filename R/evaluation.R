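#' Majority (greatest-coverage) label of a tile
#'
#' @param counts named or unnamed vector of per-class pixel counts; at least
#'   one count must be positive. Ties break to the lowest position (class
#'   index order).
#' @return the winning class: its name if `counts` is named, otherwise its
#'   position.
#' @examples
#' majority_label(c(A = 60, B = 40)) # "A"
#' majority_label(c(A = 50, B = 50)) # "A" (tie -> lowest index)
#' @export
majority_label <- function(counts) {
  if (!length(counts) || all(counts <= 0)) {
    stop("tile has no labeled pixels", call. = FALSE)
  }
  i <- which.max(counts)  # first maximum = lowest index on ties
  if (!is.null(names(counts))) names(counts)[i] else i
}

#' Paired tile labels for the tile-majority evaluation protocol
#'
#' Lays a square tile grid over the mask pair and, for every tile containing
#' at least one annotated ground-truth pixel, assigns one truth label and
#' one predicted label by greatest pixel coverage within the tile. Pixel
#' comparisons use the reporting classes (carcinomas separate, fibrosis and
#' inflammation subtypes merged). Tiles whose prediction is entirely
#' unlabeled (`ignore_index`, e.g. discarded glass tiles) get `NA` as the
#' predicted label.
#'
#' @param truth,pred integer H x W fine-class masks.
#' @param pixel_size µm/pixel of the masks (required).
#' @param tile_edge_um tile edge in µm (default 100, i.e. a 100 µm x 100 µm
#'   square; see `literal_area`).
#' @param literal_area if `TRUE`, `tile_edge_um` is interpreted as a tile
#'   area in µm² and the edge is its square root.
#' @param schema a [tme_schema()].
#' @return tibble: `tile_row`, `tile_col`, `truth`, `pred` (reporting-class
#'   names; `pred` may be `NA`).
#' @export
evaluation_tiles <- function(truth, pred, pixel_size, tile_edge_um = 100,
                             literal_area = FALSE, schema = tme_schema()) {
  if (missing(pixel_size) || is.null(pixel_size) || is.na(pixel_size)) {
    stop("pixel_size is required to size evaluation tiles", call. = FALSE)
  }
  stopifnot(identical(dim(truth), dim(pred)), tile_edge_um > 0)
  edge_um <- if (literal_area) sqrt(tile_edge_um) else tile_edge_um
  edge <- max(1L, as.integer(round(edge_um / pixel_size)))
  h <- nrow(truth); w <- ncol(truth)
  lev <- class_levels(schema, "report")
  ign <- schema$ignore_index
  rows <- list()
  for (tr in seq_len(ceiling(h / edge))) {
    r0 <- (tr - 1L) * edge + 1L; r1 <- min(tr * edge, h)
    for (tc in seq_len(ceiling(w / edge))) {
      c0 <- (tc - 1L) * edge + 1L; c1 <- min(tc * edge, w)
      tt <- truth[r0:r1, c0:c1]
      ann <- tt != ign
      if (!any(ann)) next
      t_counts <- table(factor(fine_to_coarse(tt[ann], schema, "report"),
                               levels = lev))
      pp <- pred[r0:r1, c0:c1]
      pv <- pp[pp != ign]
      p_lab <- if (length(pv)) {
        p_counts <- table(factor(fine_to_coarse(pv, schema, "report"),
                                 levels = lev))
        majority_label(p_counts)
      } else {
        NA_character_
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tile_row = tr, tile_col = tc,
        truth = majority_label(t_counts), pred = p_lab
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(tile_row = integer(), tile_col = integer(),
                          truth = character(), pred = character()))
  }
  dplyr::bind_rows(rows)
}

#' Confusion matrix over tile labels
#'
#' @param truth,pred equal-length label vectors.
#' @param classes class order for rows/columns; defaults to the reporting
#'   classes of [tme_schema()]. Labels outside `classes` are an error;
#'   `NA` predictions are dropped with a warning.
#' @return a `confusion_matrix`: C x C integer matrix, rows = truth,
#'   columns = predicted.
#' @export
confusion <- function(truth, pred, classes = class_levels(tme_schema(), "report")) {
  stopifnot(length(truth) == length(pred))
  drop <- is.na(pred)
  if (any(drop)) {
    warning(sum(drop), " tile(s) with no prediction dropped", call. = FALSE)
    truth <- truth[!drop]; pred <- pred[!drop]
  }
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- as.matrix(table(factor(truth, levels = classes),
                        factor(pred, levels = classes)))
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = list(truth = classes, pred = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class k (one-vs-rest): `TP = C[k,k]`, `FP` = column sum minus TP,
#' `FN` = row sum minus TP; precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`. Classes with an empty denominator get 0 with an
#' explicit `undefined` flag. Weighted averages are support-weighted
#' (support = truth row sums); support-weighted recall equals overall
#' accuracy by construction.
#'
#' @param cm a [confusion()] matrix (or any square count matrix with
#'   dimnames).
#' @return a `metrics_report`: list with `per_class` (tibble: class,
#'   support, precision, recall, f1, undefined flags), `weighted` (one-row
#'   tibble of support-weighted precision/recall/f1), `accuracy`, `cm`.
#' @examples
#' cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), classes = c("a", "b"))
#' precision_recall_f1(cm)$per_class
#' @export
precision_recall_f1 <- function(cm) {
  stopifnot(nrow(cm) == ncol(cm))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec_undef <- predicted == 0
  rec_undef <- support == 0
  precision <- ifelse(prec_undef, 0, tp / pmax(predicted, 1))
  recall <- ifelse(rec_undef, 0, tp / pmax(support, 1))
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    class = rownames(cm), support = as.integer(support),
    precision = as.numeric(precision), recall = as.numeric(recall),
    f1 = as.numeric(f1),
    precision_undefined = prec_undef, recall_undefined = rec_undef
  )
  wt <- support / sum(support)
  weighted <- tibble::tibble(
    precision = sum(wt * precision), recall = sum(wt * recall),
    f1 = sum(wt * f1)
  )
  structure(
    list(per_class = per_class, weighted = weighted,
         accuracy = sum(tp) / sum(cm), cm = cm),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("<metrics_report> accuracy", round(x$accuracy, 4), "\n")
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc[c("class", "support", "precision", "recall", "f1")])
  cat("weighted: P", round(x$weighted$precision, digits),
      " R", round(x$weighted$recall, digits),
      " F1", round(x$weighted$f1, digits), "\n")
  invisible(x)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param precision,recall values in \[0, 1\].
#' @return `2 * precision * recall / (precision + recall)` (0 when both are
#'   0).
#' @examples
#' round(f1_score(0.96, 0.88), 2) # 0.92
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Assign cases to cross-validation folds
#'
#' Case-level assignment: every slide of a case lands in the same fold, so
#' each fold's evaluation is on held-out cases.
#'
#' @param case_ids character vector (one per slide; duplicates share a fold).
#' @param k_folds number of folds.
#' @param seed integer seed.
#' @return tibble: `case_id`, `fold`.
#' @export
fold_assignment <- function(case_ids, k_folds = 3L, seed = 1L) {
  cases <- unique(case_ids)
  if (length(cases) < k_folds) {
    stop("fewer cases than folds", call. = FALSE)
  }
  perm <- with_seed(seed, sample(cases))
  fold <- rep(seq_len(k_folds), length.out = length(perm))
  tibble::tibble(case_id = perm, fold = fold[order(seq_along(perm))]) |>
    dplyr::arrange(.data$case_id)
}

#' Case-grouped k-fold cross-validation of the segmentation pipeline
#'
#' Each fold holds out one group of cases, trains on the remainder, segments
#' the held-out slides and scores them with the tile-majority protocol.
#' Pooled metrics aggregate the per-fold confusion matrices by summation.
#' The default learner is the random-forest pixel classifier trained on the
#' pooled sparse annotations of the training slides.
#'
#' @param slides list of `annotated_slide`s.
#' @param k_folds number of folds (default 3).
#' @param seed integer seed.
#' @param fit_fn `function(train_slides, seed)` returning a model.
#' @param predict_fn `function(model, slide)` returning a fine-class mask.
#' @param tile_edge_um evaluation tile edge (µm).
#' @param schema a [tme_schema()].
#' @param ... passed to the default `fit_fn` ([rf_config()] arguments).
#' @return list with `folds` (tibble: fold, metrics_report list-column),
#'   `pooled` (a [precision_recall_f1()] report over the summed confusion)
#'   and `assignment`.
#' @export
crossval <- function(slides, k_folds = 3L, seed = 1L,
                     fit_fn = NULL, predict_fn = NULL,
                     tile_edge_um = 100, schema = tme_schema(), ...) {
  stopifnot(length(slides) >= k_folds)
  ids <- vapply(slides, `[[`, character(1), "case_id")
  assign <- fold_assignment(ids, k_folds, seed)
  fold_of <- assign$fold[match(ids, assign$case_id)]
  if (is.null(fit_fn)) fit_fn <- rf_cohort_fit(...)
  if (is.null(predict_fn)) {
    predict_fn <- function(model, slide) {
      rf_segment(model, slide$image,
                 tissue_mask = slide$truth_mask != schema$ignore_index)
    }
  }
  seeds <- child_seeds(seed, k_folds)
  folds <- list()
  pooled_cm <- NULL
  for (f in seq_len(k_folds)) {
    model <- fit_fn(slides[fold_of != f], seed = seeds[f])
    labs <- dplyr::bind_rows(lapply(slides[fold_of == f], function(sl) {
      pred <- predict_fn(model, sl)
      evaluation_tiles(sl$truth_mask, pred, pixel_size = sl$pixel_size,
                       tile_edge_um = tile_edge_um, schema = schema)
    }))
    cm <- confusion(labs$truth, labs$pred)
    pooled_cm <- if (is.null(pooled_cm)) cm else {
      s <- unclass(pooled_cm) + unclass(cm)
      class(s) <- class(cm)
      s
    }
    folds[[f]] <- tibble::tibble(fold = f, n_tiles = nrow(labs),
                                 report = list(precision_recall_f1(cm)))
  }
  list(folds = dplyr::bind_rows(folds),
       pooled = precision_recall_f1(pooled_cm),
       assignment = assign)
}

# Default cross-validation learner: pooled-annotation random forest.
rf_cohort_fit <- function(strokes_per_class = 21L, stroke_radius = 4L, ...) {
  cfg_args <- list(...)
  function(train_slides, seed) {
    cfg <- do.call(rf_config, c(cfg_args, list(seed = seed)))
    seeds <- child_seeds(seed, length(train_slides))
    xs <- list(); ys <- list()
    for (i in seq_along(train_slides)) {
      sl <- train_slides[[i]]
      sp <- suppressWarnings(
        sparse_annotations(sl, strokes_per_class, stroke_radius, seeds[i]))
      idx <- which(sp != 255L)
      feats <- pixel_features(sl$image, cfg$feature_scales)
      xs[[i]] <- features_at(feats, idx)
      ys[[i]] <- sp[idx]
    }
    rf_fit(do.call(rbind, xs), unlist(ys), cfg)
  }
}
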