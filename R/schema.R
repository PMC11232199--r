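#' The ten-class annotation schema for NSCLC tumor-microenvironment analysis
#'
#' Defines the fine annotation classes used throughout the pipeline, their
#' coarse groupings, render colors for pseudo-H&E synthesis, and the integer
#' label conventions. Fine class indices run 0-9 in the order listed below;
#' unannotated / non-tissue pixels carry `ignore_index` (255).
#'
#' The fine classes are the two carcinoma types (adenocarcinoma ADCA and
#' squamous cell carcinoma SCCA), three fibrosis subtypes (elastotic, dense,
#' loose), vessels, two inflammation subtypes (macrophage-rich and
#' lymphoplasmacytic), necrosis, and normal lung ("background"). Coarsely,
#' the fibrosis and inflammation subtypes collapse to single fibrosis and
#' inflammation classes, and both carcinomas collapse to tumor. Stroma is the
#' union of fibrosis, inflammation and vessels.
#'
#' @return An object of class `label_schema`: a list with
#'   \describe{
#'     \item{classes}{tibble with columns `index` (0-based), `fine`, `coarse`,
#'       `report` (evaluation reporting class: carcinomas kept separate,
#'       fibrosis/inflammation subtypes merged) and `color` (hex RGB used by
#'       the synthetic renderer).}
#'     \item{stroma_members}{coarse classes summed into stroma.}
#'     \item{ignore_index}{integer label for unannotated pixels (255).}
#'   }
#' @examples
#' sch <- tme_schema()
#' sch$classes
#' @export
tme_schema <- function() {
  classes <- tibble::tibble(
    index = 0:9,
    fine = c(
      "ADCA", "SCCA",
      "fibrosis_elastotic", "fibrosis_dense", "fibrosis_loose",
      "vessels",
      "inflammation_macrophage", "inflammation_lymphoplasmacytic",
      "necrosis", "background_normal"
    ),
    coarse = c(
      "tumor", "tumor",
      "fibrosis", "fibrosis", "fibrosis",
      "vessels",
      "inflammation", "inflammation",
      "necrosis", "background"
    ),
    report = c(
      "ADCA", "SCCA",
      "fibrosis", "fibrosis", "fibrosis",
      "vessels",
      "inflammation", "inflammation",
      "necrosis", "background"
    ),
    color = c(
      "#8250AA", "#AA5596",            # carcinoma: blue-purple vs red-purple
      "#E6828C", "#DC737D", "#F096A0", # fibrosis: pinks
      "#C36E55",                       # vessels: brick red rings
      "#5F73AA", "#5569A0",            # inflammation: slate blue punctate
      "#CDAF73",                       # necrosis: pale tan smudge
      "#BE96C8"                        # normal lung: pale lavender lattice
    )
  )
  structure(
    list(
      classes = classes,
      stroma_members = c("fibrosis", "inflammation", "vessels"),
      ignore_index = 255L
    ),
    class = "label_schema"
  )
}

#' @export
print.label_schema <- function(x, ...) {
  cat("<label_schema> 10 fine classes, ignore_index =", x$ignore_index, "\n")
  print(x$classes, n = 10)
  invisible(x)
}

#' @export
format.label_schema <- function(x, ...) {
  paste0("<label_schema: ", nrow(x$classes), " fine classes>")
}

# Internal validators -------------------------------------------------------

assert_schema <- function(schema) {
  stopifnot(inherits(schema, "label_schema"))
  if (nrow(schema$classes) != 10L) {
    stop("schema must define exactly 10 fine classes", call. = FALSE)
  }
  if (anyNA(schema$classes$coarse)) {
    stop("coarse_map must be total on fine classes", call. = FALSE)
  }
  if (!all(schema$stroma_members %in% schema$classes$coarse)) {
    stop("stroma members must be coarse classes", call. = FALSE)
  }
  if (schema$ignore_index %in% schema$classes$index) {
    stop("ignore_index collides with a class index", call. = FALSE)
  }
  invisible(schema)
}

#' Map fine class indices to coarse class names
#'
#' @param idx integer vector of fine class indices (0-9; `ignore_index`
#'   passes through as `NA`).
#' @param schema a [tme_schema()] object.
#' @param level `"coarse"` (tumor/fibrosis/inflammation/vessels/necrosis/
#'   background) or `"report"` (ADCA and SCCA kept separate).
#' @return character vector of class names.
#' @export
fine_to_coarse <- function(idx, schema = tme_schema(), level = c("coarse", "report")) {
  level <- match.arg(level)
  map <- schema$classes[[level]]
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx) & idx %in% schema$classes$index
  out[ok] <- map[match(idx[ok], schema$classes$index)]
  out
}

#' Coarse class order used for reporting
#' @param schema a [tme_schema()] object.
#' @param level `"coarse"` or `"report"`.
#' @return character vector of unique class names in schema order.
#' @export
class_levels <- function(schema = tme_schema(), level = c("coarse", "report")) {
  level <- match.arg(level)
  unique(schema$classes[[level]])
}
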