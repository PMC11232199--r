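square_border <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

test_that("class areas count pixel centers inside the border by coarse class", {
  mask <- matrix(9L, 20, 20)          # background_normal everywhere
  mask[5:12, 5:12] <- 0L              # ADCA block
  mask[5:8, 13:16] <- 3L              # dense fibrosis block
  border <- square_border(4, 16, 4, 16)  # covers cols/rows 5..16
  ar <- class_areas(mask, border)
  expect_s3_class(ar, "class_area_table")
  px <- function(cl) ar$pixels[ar$class == cl]
  expect_equal(px("tumor"), 64L)
  expect_equal(px("fibrosis"), 16L)
  expect_equal(px("background"), 144L - 64L - 16L)
  expect_equal(px("stroma"),
               px("fibrosis") + px("inflammation") + px("vessels"))
  # conservation: class counts sum to the pixels inside the border
  core <- ar$pixels[ar$class != "stroma"]
  expect_equal(sum(core) + attr(ar, "n_unlabeled"), attr(ar, "n_inside"))
  expect_error(class_areas(mask, square_border(0, 0.2, 0, 0.2)), "no pixel")
})

test_that("a border over pure tumor yields zero non-tumor counts", {
  mask <- matrix(0L, 16, 16)
  ar <- class_areas(mask, square_border(2, 14, 2, 14))
  expect_true(all(ar$pixels[!ar$class %in% c("tumor")] == 0L))
  expect_gt(ar$pixels[ar$class == "tumor"], 0L)
})

test_that("truth-mask areas match the generator's own tally exactly", {
  sl <- small_slide()
  ar <- class_areas(sl$truth_mask, sl)
  for (cl in sl$tally$class) {
    expect_equal(ar$pixels[ar$class == cl],
                 sl$tally$pixels[sl$tally$class == cl])
  }
})

test_that("TME ratios follow their defining formulas", {
  mk <- function(t, f, i, v, n, b) tibble::tibble(
    class = c("tumor", "fibrosis", "inflammation", "vessels", "necrosis",
              "background", "stroma"),
    pixels = c(t, f, i, v, n, b, f + i + v))
  r <- tme_ratios(mk(50, 30, 10, 10, 0, 0))
  val <- function(m) r$value[r$metric == m]
  expect_equal(val("TSR"), 50)
  expect_equal(val("TFR"), 37.5)
  expect_equal(val("TIR"), 100 * 10 / 60)
  expect_equal(val("TVR"), 100 * 10 / 60)
  expect_equal(val("TNR"), 0)
  expect_false(any(r$undefined))
  # symmetry: equal component and tumor give 50%
  r2 <- tme_ratios(mk(40, 40, 0, 0, 0, 0))
  expect_equal(r2$value[r2$metric == "TFR"], 50)
  # 0/0 is undefined and flagged, not zeroed
  r3 <- tme_ratios(mk(0, 0, 5, 0, 0, 0))
  expect_true(r3$undefined[r3$metric == "TFR"])
  expect_true(is.na(r3$value[r3$metric == "TFR"]))
  expect_false(r3$undefined[r3$metric == "TIR"])
  # bounds
  ok <- !r$undefined
  expect_true(all(r$value[ok] >= 0 & r$value[ok] <= 100))
})

test_that("adding fibrosis strictly increases TFR and TSR", {
  base <- c(t = 50, f = 10, i = 5, v = 5, n = 2, b = 3)
  mk <- function(p) tibble::tibble(
    class = c("tumor", "fibrosis", "inflammation", "vessels", "necrosis",
              "background", "stroma"),
    pixels = c(p[["t"]], p[["f"]], p[["i"]], p[["v"]], p[["n"]], p[["b"]],
               p[["f"]] + p[["i"]] + p[["v"]]))
  r0 <- tme_ratios(mk(base))
  more <- base; more[["f"]] <- base[["f"]] + 10
  r1 <- tme_ratios(mk(more))
  expect_gt(r1$value[r1$metric == "TFR"], r0$value[r0$metric == "TFR"])
  expect_gt(r1$value[r1$metric == "TSR"], r0$value[r0$metric == "TSR"])
  # TSR from the stroma row equals the recomputation from members
  stroma <- more[["f"]] + more[["i"]] + more[["v"]]
  expect_equal(r1$value[r1$metric == "TSR"],
               100 * stroma / (stroma + more[["t"]]))
})

test_that("doubling times follow the Schwartz closed form", {
  d1 <- as.Date("2021-01-01")
  # diameter doubling over 90 days: volume doubles three times -> DT 30
  expect_equal(doubling_time(10, 20, d1, d1 + 90)$dt_days, 30)
  # diameter factor 2^(1/3): exactly one volume doubling -> DT = elapsed
  expect_equal(doubling_time(10, 10 * 2^(1 / 3), d1, d1 + 139)$dt_days, 139)
  # shrinking lesion: negative DT, flagged
  shr <- doubling_time(20, 15, d1, d1 + 60)
  expect_lt(shr$dt_days, 0)
  expect_true(shr$shrinking)
  expect_error(doubling_time(10, 10, d1, d1 + 30), "infinite")
  expect_error(doubling_time(10, 12, d1 + 30, d1), "after")
  expect_error(doubling_time(-1, 12, d1, d1 + 30), "positive")
  tab <- cohort_doubling_times(tibble::tibble(
    case_id = c("a", "b"), d1_mm = c(8, 12), d2_mm = c(16, 15),
    date_1 = d1, date_2 = d1 + c(90, 200)))
  expect_equal(tab$dt_days[1], 30)
})

test_that("the normality screen selects the right two-group test", {
  set.seed(1)
  a <- rnorm(30); b <- rnorm(30, 1)
  r <- compare_groups(a, b)
  expect_equal(r$test, "welch_t")
  expect_lt(r$p_value, 0.05)
  # oracle: direct Welch t-test
  expect_equal(r$p_value, t.test(a, b)$p.value)
  expect_equal(r$statistic, unname(t.test(a, b)$statistic))
  # heavy tails: Wilcoxon, matching a direct normality recomputation
  h1 <- rcauchy(40); h2 <- rcauchy(40)
  r2 <- compare_groups(h1, h2)
  sw <- shapiro.test(h1)$p.value <= 0.05 || shapiro.test(h2)$p.value <= 0.05
  expect_equal(r2$test, if (sw) "wilcoxon" else "welch_t")
  # identical groups: no evidence of difference
  x <- c(1, 2, 3, 4, 5)
  r3 <- compare_groups(x, x)
  expect_gt(r3$p_value, 0.95)
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("cohort ratios pool counts per case when requested", {
  slides <- list(
    generate_slide(synthetic_slide_config(height = 64, width = 64),
                   seed = 41, case_id = "c1", arm = "ADCA_fibrotic"),
    generate_slide(synthetic_slide_config(height = 64, width = 64,
                                          texture_seed = 2),
                   seed = 42, case_id = "c1", arm = "ADCA_fibrotic"),
    generate_slide(synthetic_slide_config(height = 64, width = 64,
                                          environment = "non_fibrotic",
                                          texture_seed = 3),
                   seed = 43, case_id = "c2", arm = "ADCA_non_fibrotic"))
  per_slide <- cohort_tme(slides)
  expect_equal(nrow(per_slide), 18L)
  per_case <- cohort_tme(slides, by_case = TRUE)
  expect_equal(sort(unique(per_case$case_id)), c("c1", "c2"))
  expect_equal(nrow(per_case), 12L)
  # pooled c1 TFR equals the ratio of summed counts, not the mean of ratios
  a1 <- class_areas(slides[[1]]$truth_mask, slides[[1]])
  a2 <- class_areas(slides[[2]]$truth_mask, slides[[2]])
  f <- sum(a1$pixels[a1$class == "fibrosis"], a2$pixels[a2$class == "fibrosis"])
  t <- sum(a1$pixels[a1$class == "tumor"], a2$pixels[a2$class == "tumor"])
  expect_equal(per_case$value[per_case$case_id == "c1" &
                                per_case$metric == "TFR"],
               100 * f / (f + t))
})
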