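#' Labeled training tiles from an annotated slide
#'
#' Preprocesses a slide (foreground, tiling, glass filtering, downsampling)
#' and pairs every retained tile with the matching crop of the ground-truth
#' mask, collapsed to reporting classes and re-indexed as 0-based U-Net
#' channel labels. Labels are downsampled by taking every `downsample`-th
#' pixel (nearest neighbour), keeping them hard.
#'
#' @param slide an `annotated_slide`.
#' @param tile_size full-resolution tile edge in pixels.
#' @param downsample integer factor.
#' @param glass_threshold minimum tissue fraction.
#' @param schema a [tme_schema()].
#' @return list with `x` (list of downsampled RGB tiles), `y` (list of
#'   label matrices), `tile_set`, and `classes` (reporting-class names in
#'   channel order).
#' @export
slide_label_tiles <- function(slide, tile_size = 64L, downsample = 2L,
                              glass_threshold = 0.30, schema = tme_schema()) {
  lev <- class_levels(schema, "report")
  fg <- segment_foreground(slide$image)
  tset <- extract_tiles(slide$image, fg, tile_grid(fg, tile_size),
                        downsample = downsample,
                        glass_threshold = glass_threshold,
                        slide_id = slide$case_id,
                        pixel_size = slide$pixel_size)
  keep <- tset$tiles[tset$tiles$retained, ]
  xs <- list(); ys <- list()
  sub <- seq(1L, tile_size, by = downsample)
  for (i in seq_len(nrow(keep))) {
    lab <- slide$truth_mask[(keep$r0[i] + 1L):keep$r1[i],
                            (keep$c0[i] + 1L):keep$c1[i]]
    rl <- matrix(schema$ignore_index, tile_size, tile_size)
    ok <- lab != schema$ignore_index
    rl[ok] <- match(fine_to_coarse(lab[ok], schema, "report"), lev) - 1L
    xs[[i]] <- tset$data[[as.character(keep$tile_id[i])]]
    ys[[i]] <- rl[sub, sub]
  }
  list(x = xs, y = ys, tile_set = tset, classes = lev)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings with the defaults used throughout:
#' 512 px tiles downsampled by 2, a 30% glass threshold, a 50-tree forest
#' refined for up to 5 expert-in-the-loop iterations towards 80% accuracy,
#' and U-Net channels growing from the first encoder width. The demo-scale
#' defaults (slide size, tile size, U-Net width, epochs) are chosen so the
#' whole pipeline runs on one CPU in minutes; see
#' `vignette("tmeseg-methods")`.
#'
#' @param out_dir output directory for the run.
#' @param n_slides synthetic slides to generate (when no inputs given).
#' @param slide_px synthetic slide edge in pixels.
#' @param tile_size,downsample,glass_threshold preprocessing settings.
#' @param rf an [rf_config()].
#' @param max_iter,target_accuracy expert-in-the-loop stopping settings.
#' @param unet_channels,unet_levels,epochs,lr,batch_size U-Net settings.
#' @param tile_edge_um evaluation tile edge (µm).
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("tmeseg_run_"),
                            n_slides = 4L, slide_px = 640L,
                            tile_size = 64L, downsample = 2L,
                            glass_threshold = 0.30,
                            rf = rf_config(),
                            max_iter = 5L, target_accuracy = 0.80,
                            unet_channels = c(16L, 32L, 64L),
                            unet_levels = 2L, epochs = 5L, lr = 2e-3,
                            batch_size = 2L, tile_edge_um = 100,
                            seed = 1L) {
  stopifnot(glass_threshold >= 0, glass_threshold <= 1,
            target_accuracy >= 0, target_accuracy <= 1)
  structure(
    list(out_dir = out_dir, n_slides = as.integer(n_slides),
         slide_px = as.integer(slide_px), tile_size = as.integer(tile_size),
         downsample = as.integer(downsample),
         glass_threshold = glass_threshold, rf = rf,
         max_iter = as.integer(max_iter), target_accuracy = target_accuracy,
         unet_channels = as.integer(unet_channels),
         unet_levels = as.integer(unet_levels), epochs = as.integer(epochs),
         lr = lr, batch_size = as.integer(batch_size),
         tile_edge_um = tile_edge_um, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-to-metrics pipeline
#'
#' Executes the end-to-end workflow: generate seeded synthetic slides,
#' preprocess and tile them, refine a random-forest segmentation through
#' the expert-in-the-loop loop on the first slide, train the U-Net on the
#' cohort's labeled tiles, segment every slide, derive tumor borders,
#' compute TME ratios, and evaluate with the tile-majority protocol.
#' Writes `manifest.json`, `tme.csv` and `metrics.json` (plus masks) under
#' `config$out_dir`. Fully seeded and deterministic.
#'
#' @param config a [pipeline_config()].
#' @param slides optional list of `annotated_slide`s to use instead of
#'   generating synthetic ones.
#' @return a `pipeline_result`: list with `slides`, `eitl`, `unet`,
#'   `masks`, `borders`, `tme` (tibble), `evaluation` (a `metrics_report`),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), slides = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "masks"), showWarnings = FALSE)
  schema <- tme_schema()
  seeds <- child_seeds(config$seed, 6L)
  stages <- list()

  ## stage 1: slides
  if (is.null(slides)) {
    slides <- lapply(seq_len(config$n_slides), function(s) {
      generate_slide(
        synthetic_slide_config(height = config$slide_px,
                               width = config$slide_px,
                               carcinoma_class = if (s %% 2) "ADCA" else "SCCA",
                               environment = if (s <= config$n_slides / 2)
                                 "fibrotic" else "non_fibrotic",
                               texture_seed = s),
        seed = seeds[1] + s,
        case_id = sprintf("case_%02d", s),
        arm = paste0(if (s %% 2) "ADCA" else "SCCA", "_",
                     if (s <= config$n_slides / 2) "fibrotic" else "non_fibrotic"))
    })
  }
  stages$generate <- list(n_slides = length(slides))

  ## stage 2: tiles + labels
  tiled <- lapply(slides, slide_label_tiles,
                  tile_size = config$tile_size,
                  downsample = config$downsample,
                  glass_threshold = config$glass_threshold, schema = schema)
  xs <- unlist(lapply(tiled, `[[`, "x"), recursive = FALSE)
  ys <- unlist(lapply(tiled, `[[`, "y"), recursive = FALSE)
  stages$preprocess <- list(n_tiles = length(xs))

  ## stage 3: expert-in-the-loop RF on the first slide
  init <- suppressWarnings(sparse_annotations(slides[[1]], seed = seeds[2]))
  eitl <- eitl_refine(slides[[1]], init, config = config$rf,
                      max_iter = config$max_iter,
                      target_accuracy = config$target_accuracy,
                      seed = seeds[3])
  stages$eitl <- list(iterations = nrow(eitl$trace),
                      stop_reason = eitl$stop_reason,
                      final_accuracy = eitl$trace$accuracy[nrow(eitl$trace)])

  ## stage 4: U-Net training
  lev <- tiled[[1]]$classes
  ucfg <- unet_config(out_channels = length(lev),
                      encoder_channels = config$unet_channels,
                      n_levels = config$unet_levels,
                      input_size = config$tile_size %/% config$downsample)
  split <- split_tiles(length(xs), seeds[4])
  unet <- train_unet(xs, ys, ucfg, split = split, epochs = config$epochs,
                     lr = config$lr, batch_size = config$batch_size,
                     seed = seeds[4])
  stages$unet <- list(epochs = config$epochs,
                      best_val_loss = min(unet$history$val_loss, na.rm = TRUE))

  ## stage 5: full-slide segmentation + borders + TME
  masks <- list(); borders <- list(); tme <- list()
  for (i in seq_along(slides)) {
    sl <- slides[[i]]
    pred_rep <- predict_slide(unet, sl$image, tiled[[i]]$tile_set)
    # map reporting-class channels back to representative fine indices
    fine_map <- schema$classes$index[match(lev, schema$classes$report)]
    mask <- pred_rep
    ok <- pred_rep != schema$ignore_index
    mask[ok] <- fine_map[pred_rep[ok] + 1L]
    masks[[sl$case_id]] <- mask
    write_mask_png(mask, file.path(config$out_dir, "masks",
                                   paste0(sl$case_id, ".png")))
    borders[[sl$case_id]] <- tumor_border(mask, schema = schema)
    areas <- class_areas(mask, sl, schema, pixel_size = sl$pixel_size)
    tme[[i]] <- tme_ratios(areas, case_id = sl$case_id, arm = sl$arm)
  }
  tme <- dplyr::bind_rows(tme)
  readr::write_csv(tme, file.path(config$out_dir, "tme.csv"))
  stages$tme <- list(n_rows = nrow(tme))

  ## stage 6: tile-majority evaluation on the held-out test tiles
  labs <- list()
  offset <- 0L
  for (i in seq_along(slides)) {
    n_i <- length(tiled[[i]]$x)
    test_local <- split$assignment$index[split$assignment$set == "test"]
    test_local <- test_local[test_local > offset & test_local <= offset + n_i] - offset
    if (length(test_local)) {
      keep <- tiled[[i]]$tile_set$tiles[tiled[[i]]$tile_set$tiles$retained, ]
      preds <- predict_unet(unet, tiled[[i]]$x[test_local])
      for (j in seq_along(test_local)) {
        yv <- tiled[[i]]$y[[test_local[j]]]
        pv <- preds[[j]]
        ann <- yv != schema$ignore_index
        if (!any(ann)) next
        labs[[length(labs) + 1L]] <- tibble::tibble(
          truth = majority_label(table(factor(lev[yv[ann] + 1L], levels = lev))),
          pred = majority_label(table(factor(lev[pv[ann] + 1L], levels = lev)))
        )
      }
    }
    offset <- offset + n_i
  }
  labs <- dplyr::bind_rows(labs)
  evaluation <- precision_recall_f1(confusion(labs$truth, labs$pred, lev))
  stages$evaluation <- list(n_test_tiles = nrow(labs),
                            weighted_f1 = evaluation$weighted$f1)
  jsonlite::write_json(
    list(per_class = evaluation$per_class, weighted = evaluation$weighted,
         accuracy = evaluation$accuracy),
    file.path(config$out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tmeseg")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(
    list(slides = slides, eitl = eitl, unet = unet, masks = masks,
         borders = borders, tme = tme, evaluation = evaluation,
         manifest = manifest, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$slides), " slides, U-Net weighted F1 ",
      round(x$evaluation$weighted$f1, 3), ", outputs in ", x$config$out_dir,
      "\n", sep = "")
  invisible(x)
}
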