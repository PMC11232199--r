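# Shared small fixtures, built in code and cached per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A 128 px fibrotic ADCA slide with all default fractions.
small_slide <- function() {
  fixture("small_slide", function() {
    generate_slide(synthetic_slide_config(height = 128, width = 128),
                   seed = 7, case_id = "fix_small", arm = "ADCA_fibrotic")
  })
}

# Its feature stack at the default scales (expensive, reused by RF tests).
small_features <- function() {
  fixture("small_features", function() pixel_features(small_slide()$image))
}

small_sparse <- function() {
  fixture("small_sparse", function() {
    suppressWarnings(sparse_annotations(small_slide(), seed = 3))
  })
}

# Deterministic random fine-class mask with ignore border, for the
# brute-force oracle comparisons.
random_fine_mask <- function(h, w, n_classes = 10L, p_ignore = 0.2) {
  vals <- sample(c(0:(n_classes - 1L), 255L), h * w, replace = TRUE,
                 prob = c(rep((1 - p_ignore) / n_classes, n_classes), p_ignore))
  matrix(as.integer(vals), h, w)
}
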