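#' Per-class pixel areas inside the tumor border
#'
#' Counts mask pixels whose centers fall inside the tumor-border polygon(s)
#' (even-odd rule), collapsing fine classes to the coarse reporting classes:
#' both carcinoma classes count as Tumor; the fibrosis and inflammation
#' subtypes collapse to Fibrosis and Inflammation; Stroma is the sum of
#' Fibrosis, Inflammation and Vessels.
#'
#' @param mask integer H x W fine-class label matrix.
#' @param border the tumor border: a polygon vertex matrix (columns x, y in
#'   pixel-center coordinates), a list of such matrices, a [tumor_border()]
#'   object, or an `annotated_slide` (its generator border is used).
#' @param schema a [tme_schema()].
#' @param pixel_size optional µm/pixel for µm² areas.
#' @return a `class_area_table` tibble: `class` (tumor, fibrosis,
#'   inflammation, vessels, necrosis, background, stroma), `pixels`, and
#'   `area_um2` when `pixel_size` is given. Attributes: `n_inside` (pixels
#'   inside the border), `n_unlabeled` (inside pixels carrying
#'   `ignore_index`, e.g. glass-tile fill in stitched predictions).
#' @export
class_areas <- function(mask, border, schema = tme_schema(),
                        pixel_size = NULL) {
  polys <- border_polygons(border)
  if (!length(polys)) stop("empty tumor border", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  inside <- Reduce(`|`, lapply(polys, function(p) rasterize_polygon(p, h, w)))
  if (!any(inside)) stop("tumor border encloses no pixel centers", call. = FALSE)
  lab <- mask[inside]
  unlabeled <- sum(lab == schema$ignore_index)
  coarse <- fine_to_coarse(lab, schema, "coarse")
  lev <- class_levels(schema, "coarse")
  counts <- table(factor(coarse, levels = lev))
  out <- tibble::tibble(class = lev, pixels = as.integer(counts))
  stroma <- sum(out$pixels[out$class %in% schema$stroma_members])
  out <- dplyr::bind_rows(out, tibble::tibble(class = "stroma",
                                              pixels = as.integer(stroma)))
  if (!is.null(pixel_size)) out$area_um2 <- out$pixels * pixel_size^2
  attr(out, "n_inside") <- sum(inside)
  attr(out, "n_unlabeled") <- unlabeled
  class(out) <- c("class_area_table", class(out))
  out
}

border_polygons <- function(border) {
  if (inherits(border, "annotated_slide")) return(list(border$tumor_border))
  if (inherits(border, "tumor_border")) return(border$polygons)
  if (is.matrix(border)) return(list(border))
  if (is.list(border)) return(border)
  stop("unrecognized tumor border representation", call. = FALSE)
}

#' Tumor microenvironment ratios
#'
#' Each ratio relates one microenvironment component to the tumor area:
#' \deqn{TSR = Stroma / (Stroma + Tumor) \times 100}
#' and likewise TFR (fibrosis), TIR (inflammation), TVR (vessels), TNR
#' (necrosis) and TBR (background, i.e. non-neoplastic non-fibrotic lung).
#' A ratio whose numerator and Tumor are both zero is undefined (0/0) and is
#' flagged rather than silently reported as 0.
#'
#' @param areas a [class_areas()] table (or any tibble with `class` and
#'   `pixels` covering the six coarse classes).
#' @param case_id,arm optional labels attached to the report.
#' @return a `tme_report` tibble: `metric` (TSR, TFR, TIR, TVR, TNR, TBR),
#'   `value` (percent, 0-100 or `NA` when undefined), `undefined` flag.
#' @examples
#' areas <- tibble::tibble(
#'   class = c("tumor", "fibrosis", "inflammation", "vessels", "necrosis",
#'             "background", "stroma"),
#'   pixels = c(50L, 30L, 10L, 10L, 0L, 0L, 50L)
#' )
#' tme_ratios(areas)
#' @export
tme_ratios <- function(areas, case_id = NULL, arm = NULL) {
  px <- function(cl) {
    i <- match(cl, areas$class)
    if (is.na(i)) 0 else as.numeric(areas$pixels[i])
  }
  tumor <- px("tumor")
  stroma <- if ("stroma" %in% areas$class) px("stroma") else
    px("fibrosis") + px("inflammation") + px("vessels")
  comp <- c(TSR = stroma, TFR = px("fibrosis"), TIR = px("inflammation"),
            TVR = px("vessels"), TNR = px("necrosis"), TBR = px("background"))
  denom <- comp + tumor
  value <- ifelse(denom > 0, comp / denom * 100, NA_real_)
  out <- tibble::tibble(
    metric = names(comp),
    value = as.numeric(value),
    undefined = denom == 0
  )
  if (!is.null(case_id)) out$case_id <- case_id
  if (!is.null(arm)) out$arm <- arm
  class(out) <- c("tme_report", class(out))
  out
}

#' TME ratios for a whole cohort of segmented slides
#'
#' Computes [class_areas()] + [tme_ratios()] per slide against each slide's
#' tumor border, returning one row per slide and metric. With
#' `by_case = TRUE`, pixel counts are pooled (area-weighted) across a case's
#' slides before the ratios are formed.
#'
#' @param slides list of `annotated_slide`s.
#' @param masks list of label matrices (defaults to the slides' truth masks).
#' @param schema a [tme_schema()].
#' @param by_case pool counts per case before computing ratios.
#' @return tibble with `case_id`, `arm`, `metric`, `value`, `undefined`.
#' @export
cohort_tme <- function(slides, masks = NULL, schema = tme_schema(),
                       by_case = FALSE) {
  if (is.null(masks)) masks <- lapply(slides, `[[`, "truth_mask")
  stopifnot(length(masks) == length(slides))
  per <- purrr::map2(slides, masks, function(sl, mk) {
    ar <- class_areas(mk, sl, schema)
    ar$case_id <- sl$case_id
    ar$arm <- sl$arm
    ar
  })
  if (!by_case) {
    return(dplyr::bind_rows(purrr::map(per, function(ar) {
      tme_ratios(ar, case_id = ar$case_id[1], arm = ar$arm[1])
    })))
  }
  pooled <- dplyr::bind_rows(per) |>
    dplyr::group_by(.data$case_id, .data$arm, .data$class) |>
    dplyr::summarise(pixels = sum(.data$pixels), .groups = "drop")
  dplyr::bind_rows(lapply(split(pooled, pooled$case_id), function(g) {
    tme_ratios(g, case_id = g$case_id[1], arm = g$arm[1])
  }))
}

#' Schwartz volume doubling time from two dated diameter measurements
#'
#' Assumes exponential volume growth of a sphere-like lesion:
#' \deqn{DT = \Delta t \cdot \ln 2 / (3 \ln(d_2 / d_1))}
#' with \eqn{\Delta t} in days. A shrinking lesion gives a negative DT and
#' is flagged; equal diameters (infinite DT) are an error.
#'
#' @param d1,d2 diameters (same unit, typically mm), positive.
#' @param date_1,date_2 `Date`s (or anything coercible); `date_2` must be
#'   after `date_1`.
#' @return tibble: `dt_days`, `shrinking` flag, `delta_days`.
#' @examples
#' doubling_time(10, 20, as.Date("2020-01-01"), as.Date("2020-03-31"))
#' @export
doubling_time <- function(d1, d2, date_1, date_2) {
  date_1 <- as.Date(date_1); date_2 <- as.Date(date_2)
  if (any(d1 <= 0) || any(d2 <= 0)) stop("diameters must be positive", call. = FALSE)
  if (any(date_2 <= date_1)) stop("date_2 must be after date_1", call. = FALSE)
  if (any(d1 == d2)) {
    stop("equal diameters give an infinite doubling time", call. = FALSE)
  }
  dt_days <- as.numeric(date_2 - date_1, units = "days")
  tibble::tibble(
    dt_days = dt_days * log(2) / (3 * log(d2 / d1)),
    shrinking = d2 < d1,
    delta_days = dt_days
  )
}

#' Doubling times for a measurement table
#'
#' @param measurements tibble with columns `case_id`, `d1_mm`, `d2_mm`,
#'   `date_1`, `date_2`.
#' @return the input with `dt_days` and `shrinking` columns added.
#' @export
cohort_doubling_times <- function(measurements) {
  dt <- doubling_time(measurements$d1_mm, measurements$d2_mm,
                      measurements$date_1, measurements$date_2)
  dplyr::bind_cols(measurements, dt[c("dt_days", "shrinking")])
}

#' Two-group comparison with a normality screen
#'
#' Shapiro-Wilk (alpha = 0.05) on both groups decides the test: if both are
#' compatible with normality, Welch's unpaired t-test; otherwise the
#' Wilcoxon rank-sum test. Two-sided throughout, significance at p < 0.05.
#'
#' @param values_a,values_b numeric vectors (each n >= 3).
#' @param alpha normality-screen level (0.05).
#' @return one-row tibble: `test` ("welch_t" or "wilcoxon"), `statistic`,
#'   `p_value`, `shapiro_p_a`, `shapiro_p_b`, `n_a`, `n_b`.
#' @examples
#' compare_groups(rnorm(30), rnorm(30, 1))
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(values_a); pb <- sw(values_b)
  if (pa > alpha && pb > alpha) {
    tst <- stats::t.test(values_a, values_b, var.equal = FALSE)
    nm <- "welch_t"
  } else {
    tst <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = FALSE))
    nm <- "wilcoxon"
  }
  tibble::tibble(
    test = nm,
    statistic = unname(tst$statistic),
    p_value = tst$p.value,
    shapiro_p_a = pa, shapiro_p_b = pb,
    n_a = length(values_a), n_b = length(values_b)
  )
}
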