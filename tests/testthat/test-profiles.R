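stack8_from <- function(planes, names = paste0("ch", seq_along(planes))) {
  arr <- array(0, c(length(planes), 1, nrow(planes[[1]]), ncol(planes[[1]])))
  for (i in seq_along(planes)) arr[i, 1, , ] <- planes[[i]]
  image_stack(arr, bit_depth = 8L, channel_names = names)
}

test_that("profiles over a constant image are constant", {
  s <- stack8_from(list(matrix(7, 64, 64)))
  p <- extract_line_profile(s, c(30, 30), c(1, 0.3), length_px = 40)
  expect_equal(unname(p$samples[, 1]), rep(7, 40))
})

test_that("bilinear interpolation across a 1-px stripe matches hand values", {
  m <- matrix(0, 16, 16); m[, 6] <- 200   # vertical stripe at x = 5 (0-based)
  s <- stack8_from(list(m))
  # anchored on the stripe: only the sample exactly on it exceeds 100
  p <- extract_line_profile(s, c(5, 8), c(1, 0), length_px = 7)
  expect_equal(unname(p$samples[, 1]), c(0, 0, 0, 200, 0, 0, 0))
  # anchored half a pixel off: both adjacent samples are exactly 100
  p2 <- extract_line_profile(s, c(5.5, 8), c(1, 0), length_px = 7)
  expect_equal(unname(p2$samples[, 1]), c(0, 0, 100, 100, 0, 0, 0))
  expect_equal(nrow(find_signal_peaks(p2$samples[, 1], cutoff = 100)), 0)
})

test_that("reversing direction reverses samples and preserves peak metrics", {
  set.seed(3)
  m <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  s <- stack8_from(list(m))
  pf <- extract_line_profile(s, c(31, 29), c(0.6, 0.8), length_px = 40)
  pb <- extract_line_profile(s, c(31, 29), c(-0.6, -0.8), length_px = 40)
  expect_equal(pf$samples[, 1], rev(pb$samples[, 1]))
  a <- find_signal_peaks(pf$samples[, 1], 100)
  b <- find_signal_peaks(pb$samples[, 1], 100)
  expect_equal(sort(a$area), sort(b$area))
  expect_equal(sort(a$max_intensity), sort(b$max_intensity))
})

test_that("line anchors outside the image raise a geometry error, clipped samples are NA", {
  s <- stack8_from(list(matrix(10, 32, 32)))
  expect_error(extract_line_profile(s, c(40, 10), c(1, 0), 40),
               class = "vesicoloc_geometry_error")
  p <- extract_line_profile(s, c(2, 16), c(1, 0), length_px = 40)
  expect_true(any(is.na(p$samples[, 1])))   # left end clipped
  expect_equal(nrow(find_signal_peaks(p$samples[, 1], 5)), 1)  # NA breaks runs
})

test_that("find_signal_peaks applies the strict cutoff and sums raw areas", {
  v <- c(rep(0, 10), 120, 130, 120, rep(0, 10))
  pk <- find_signal_peaks(v, cutoff = 100)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, 370)
  expect_equal(pk$max_intensity, 130)
  expect_equal(pk$start_idx, 10); expect_equal(pk$end_idx, 13)
  expect_equal(nrow(find_signal_peaks(rep(0, 40), 100)), 0)
  expect_equal(nrow(find_signal_peaks(rep(100, 40), 100)), 0)  # strictly above
  expect_equal(find_signal_peaks(c(0, 101, 0, 102, 0), 100)$length, c(1, 1))
})

test_that("classification follows the peak-overlap rule on hand-built cases", {
  cfg <- profile_config(length_px = 10)
  # marker support inside vesicle support, marker <= vesicle: share 1
  ves <- c(0, 0, 150, 150, 150, 150, 150, 0, 0, 0)
  mar <- c(0, 0, 0, 120, 120, 120, 0, 0, 0, 0)
  call <- classify_marker_positive(ves, mar, cfg)
  expect_true(call$is_positive)
  expect_equal(call$overlap_share, 1)
  # no supra-cutoff marker: negative, share 0
  call2 <- classify_marker_positive(ves, rep(0, 10), cfg)
  expect_false(call2$is_positive)
  expect_equal(call2$overlap_share, 0)
  # no vesicle peak at all: negative even with a marker peak
  call3 <- classify_marker_positive(rep(0, 10), mar, cfg)
  expect_false(call3$is_positive)
})

test_that("positivity flips exactly at an overlap share of one half", {
  cfg <- profile_config(length_px = 10)
  ves <- c(rep(150, 5), rep(0, 5))
  mar_eq <- c(0, 0, 0, 120, 120, 120, 120, 0, 0, 0)   # overlap 240 = 0.5*480
  call_eq <- classify_marker_positive(ves, mar_eq, cfg)
  expect_equal(call_eq$overlap_share, 0.5)
  expect_false(call_eq$is_positive)                    # tie is negative
  mar_up <- c(0, 0, 0, 120, 121, 120, 120, 0, 0, 0)   # overlap 241 > 240.5
  call_up <- classify_marker_positive(ves, mar_up, cfg)
  expect_gt(call_up$overlap_share, 0.5)
  expect_true(call_up$is_positive)
})

test_that("classification agrees with the brute-force oracle on random profiles", {
  set.seed(99)
  cfg <- profile_config(length_px = 40)
  lv <- c(0, 60, 90, 101, 120, 128, 200, 255)
  for (rep in 1:500) {
    ves <- sample(lv, 40, TRUE)
    mar <- sample(lv, 40, TRUE)
    got <- classify_core(ves, mar, 100, 0.5)
    ora <- oracle_classify(ves, mar, 100, 0.5)
    expect_identical(got[["is_positive"]] > 0, ora$pos)
    expect_equal(got[["overlap_share"]], ora$share, tolerance = 1e-12)
  }
})

test_that("mismatched profile geometries are a contract error", {
  expect_error(classify_marker_positive(rep(0, 10), rep(0, 12)),
               class = "vesicoloc_contract_error")
})

test_that("percent_marker_positive computes a percentage and is missing when empty", {
  calls <- tibble::tibble(is_positive = c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(percent_marker_positive(calls), 30)
  expect_equal(percent_marker_positive(tibble::tibble(is_positive = rep(TRUE, 4))), 100)
  expect_true(is.na(percent_marker_positive(calls[0, ])))
})

test_that("reporter quantification returns overlapping peak area and scales linearly", {
  cfg <- profile_config(length_px = 12)
  ves <- c(0, 0, 0, 150, 160, 150, 140, 0, 0, 0, 0, 0)
  expect_equal(quantify_profile_intensity(ves, rep(0, 12), cfg)$area, 0)
  self <- quantify_profile_intensity(ves, ves, cfg)
  expect_equal(self$area, sum(c(150, 160, 150, 140)))  # self-overlap = peak area
  rep1 <- c(0, 0, 0, 0, 105, 110, 108, 0, 0, 0, 0, 0)
  q1 <- quantify_profile_intensity(ves, rep1, cfg)
  q2 <- quantify_profile_intensity(ves, 2 * rep1, cfg)
  expect_equal(q2$area, 2 * q1$area)
})

test_that("the positive-fraction estimator is consistent in the number of vesicles", {
  # simulate classification over profile draws at increasing n
  cfg <- profile_config(length_px = 40)
  sim_err <- function(n, seed) {
    set.seed(seed)
    truth <- runif(n) < 0.45
    calls <- vapply(truth, function(pos) {
      ves <- c(rep(0, 17), 150, 180, 150, rep(0, 20))
      mar <- if (pos) c(rep(0, 16 + sample(0:2, 1)), 120, 140, 120,
                        rep(0, 30))[1:40] else sample(c(0, 40, 90), 40, TRUE)
      classify_core(ves, mar, 100, 0.5)[["is_positive"]] > 0
    }, logical(1))
    abs(mean(calls) - 0.45)   # error w.r.t. the generating fraction
  }
  errs <- vapply(c(50, 200, 800), function(n) {
    mean(vapply(1:20, function(s) sim_err(n, 1000 * n + s), numeric(1)))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lte(errs[2], errs[1] + 0.01)
})

test_that("score_vesicles finds offset markers via the marker-seeking direction", {
  # vesicle blob with a marker punctum offset perpendicular to the x axis
  ves <- vesicoloc:::add_gaussian_spot(matrix(0, 64, 64), 31, 31, 3.5, 200)
  mar <- vesicoloc:::add_gaussian_spot(matrix(0, 64, 64), 31, 34, 1.5, 200)
  s <- stack8_from(list(round(ves), round(mar)), names = c("v", "m"))
  det <- tibble::tibble(x = 31, y = 31)
  got <- score_vesicles(det, s, "v", "m",
                        profile_config(direction_mode = "toward-marker"))
  expect_true(got$is_positive[1])
  fixed <- score_vesicles(det, s, "v", "m",
                          profile_config(direction_mode = "fixed-angle",
                                         fixed_angle = 0))
  expect_false(fixed$is_positive[1])   # horizontal line misses the marker
})
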