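# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the expert-in-the-loop refinement trace
#'
#' @param x an `eitl_result`.
#' @param ... unused.
#' @return the per-iteration trace tibble (iteration, stroke and annotated
#'   pixel counts, pixel accuracy).
#' @export
tidy.eitl_result <- function(x, ...) {
  dplyr::select(x$trace, -"per_class")
}

#' @rdname tidy.eitl_result
#' @export
glance.eitl_result <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(
    iterations = n,
    stop_reason = x$stop_reason,
    initial_accuracy = x$trace$accuracy[1],
    final_accuracy = x$trace$accuracy[n],
    final_annotations = x$trace$n_annotated_pixels[n]
  )
}

#' Tidy a tile-classification metrics report
#'
#' @param x a `metrics_report` from [precision_recall_f1()].
#' @param ... unused.
#' @return per-class tibble with precision, recall, F1 and support.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(x$weighted, tibble::tibble(accuracy = x$accuracy))
}

#' Tidy a U-Net training history
#'
#' @param x a trained `unet_model`.
#' @param ... unused.
#' @return the epoch history tibble.
#' @export
tidy.unet_model <- function(x, ...) x$history

#' @rdname tidy.unet_model
#' @export
glance.unet_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    n_params = n_params(x),
    best_val_loss = if (nrow(h)) min(h$val_loss, na.rm = TRUE) else NA_real_,
    final_val_accuracy = if (nrow(h)) h$val_accuracy[nrow(h)] else NA_real_
  )
}

#' Plot TME ratios
#'
#' @param object a `tme_report` (possibly multi-slide, from [cohort_tme()]).
#' @param ... unused.
#' @return a ggplot: one bar per metric (faceted by case when present).
#' @export
autoplot.tme_report <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::labs(x = NULL, y = "ratio (%)") +
    ggplot2::theme_minimal()
  if ("arm" %in% names(object) && dplyr::n_distinct(object$case_id) > 1) {
    p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$arm)) +
      ggplot2::scale_fill_brewer(palette = "Set2")
  } else {
    p + ggplot2::geom_col(fill = "#8250AA")
  }
}

#' Plot a confusion matrix as a heat map
#'
#' @param object a `confusion_matrix`.
#' @param normalize show row-normalized proportions instead of counts.
#' @param ... unused.
#' @return a ggplot tile heat map (rows = truth, columns = predicted).
#' @export
autoplot.confusion_matrix <- function(object, normalize = FALSE, ...) {
  m <- unclass(object)
  if (normalize) m <- m / pmax(rowSums(m), 1)
  df <- as.data.frame.table(m, responseName = "value")
  names(df)[1:2] <- c("truth", "pred")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.2f", .data$value) else .data$value),
      color = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted", y = "truth",
                  fill = if (normalize) "prop." else "tiles") +
    ggplot2::theme_minimal()
}

#' Plot the expert-in-the-loop accuracy trajectory
#'
#' @param object an `eitl_result`.
#' @param ... unused.
#' @return a ggplot of pixel accuracy against iteration.
#' @export
autoplot.eitl_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_annotated_pixels)) +
    ggplot2::scale_size_continuous(name = "annotated px") +
    ggplot2::labs(x = "iteration", y = "pixel accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a U-Net training history
#'
#' @param object a trained `unet_model`.
#' @param ... unused.
#' @return a ggplot of training and validation loss per epoch.
#' @export
autoplot.unet_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' Render a slide or mask for inspection
#'
#' @param slide an `annotated_slide`.
#' @param what `"image"` renders the pseudo-H&E RGB image, `"truth"` the
#'   ground-truth classes in schema colors.
#' @param schema a [tme_schema()].
#' @return a ggplot raster.
#' @export
plot_slide <- function(slide, what = c("image", "truth"),
                       schema = tme_schema()) {
  what <- match.arg(what)
  h <- nrow(slide$truth_mask); w <- ncol(slide$truth_mask)
  if (what == "image") {
    col <- grDevices::rgb(slide$image[, , 1], slide$image[, , 2],
                          slide$image[, , 3], maxColorValue = 255)
  } else {
    col <- rep("#FFFFFF", h * w)
    for (k in seq_len(nrow(schema$classes))) {
      col[slide$truth_mask == schema$classes$index[k]] <- schema$classes$color[k]
    }
  }
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$fill <- col
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
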