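test_that("LoG response of a constant image is zero", {
  resp <- log_response(matrix(7, 48, 48), diameter_px = 10)
  expect_lt(max(abs(resp)), 1e-9)
})

test_that("LoG response matches a direct-convolution oracle on a matched spot", {
  sigma_b <- 10 / (2 * sqrt(2))
  img <- make_spot_image(64, 64, matrix(c(31.5, 31.5), 1), sigma_b,
                         amplitude = 200)
  resp <- log_response(img, diameter_px = 10)
  oracle <- oracle_convolve(img, vesicoloc:::log_kernel(10))
  expect_lt(max(abs(resp - oracle)), 1e-8)
  # maximum sits at the spot center
  mx <- which(resp == max(resp), arr.ind = TRUE)
  expect_lt(abs(mx[1, 1] - 1 - 31.5), 1)
  expect_lt(abs(mx[1, 2] - 1 - 31.5), 1)
})

test_that("scale normalization peaks when diameter matches 2*sqrt(2)*sigma_b", {
  sigma_b <- 3
  img <- make_spot_image(64, 64, matrix(c(31.5, 31.5), 1), sigma_b,
                         amplitude = 200)
  diams <- seq(4, 14, by = 0.5)
  peak <- vapply(diams, function(d) max(log_response(img, d)), numeric(1))
  best <- diams[which.max(peak)]
  expect_lte(abs(best - 2 * sqrt(2) * sigma_b), 0.5)
})

test_that("detect_spots matches the exhaustive oracle and finds true spots", {
  set.seed(42)
  sigma_b <- 10 / (2 * sqrt(2))
  centers <- random_centers(5, 128, 128, margin = 15, min_sep = 40)
  img <- make_spot_image(128, 128, centers, sigma_b,
                         amplitude = runif(5, 150, 250), noise_sd = 2)
  cfg <- detector_config(diameter_px = 10, quality_threshold = 5)
  det <- detect_spots(img, cfg)
  ora <- oracle_detect(img, 10, 5)
  expect_equal(nrow(det), 5)
  expect_equal(nrow(det), nrow(ora))
  for (i in seq_len(nrow(det))) {
    expect_lt(min(sqrt((ora$x - det$x[i])^2 + (ora$y - det$y[i])^2)), 1)
    expect_lt(min(sqrt((centers[, 1] - det$x[i])^2 +
                         (centers[, 2] - det$y[i])^2)), 1)
  }
})

test_that("quality threshold excludes weak spots and empty images give no hits", {
  sigma_b <- 10 / (2 * sqrt(2))
  img <- make_spot_image(96, 96, rbind(c(25, 48), c(70, 48)), sigma_b,
                         amplitude = c(200, 20))
  cfg <- detector_config(10, quality_threshold = 30)
  det <- detect_spots(img, cfg)
  ora <- oracle_detect(img, 10, 30)
  expect_equal(nrow(det), 1)
  expect_equal(nrow(ora), 1)
  expect_lt(abs(det$x[1] - 25), 1)
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), cfg)), 0)
})

test_that("detection is equivariant to integer translation", {
  set.seed(7)
  img <- make_spot_image(96, 96, rbind(c(30, 40), c(60, 55)),
                         10 / (2 * sqrt(2)), amplitude = c(180, 220))
  cfg <- detector_config(10, 5)
  d0 <- detect_spots(img, cfg)
  shifted <- matrix(0, 96, 96)
  shifted[11:96, 6:96] <- img[1:86, 1:91]  # shift +10 rows (y), +5 cols (x)
  d1 <- detect_spots(shifted, cfg)
  d0s <- d0[order(d0$x), ]; d1s <- d1[order(d1$x), ]
  expect_equal(d1s$x, d0s$x + 5, tolerance = 1e-8)
  expect_equal(d1s$y, d0s$y + 10, tolerance = 1e-8)
})

test_that("raising the quality threshold never increases detections", {
  set.seed(13)
  img <- make_spot_image(128, 128, random_centers(8, 128, 128, 12, 25),
                         10 / (2 * sqrt(2)),
                         amplitude = runif(8, 30, 250), noise_sd = 3)
  counts <- vapply(c(0.5, 2, 10, 40, 80, 200), function(q) {
    nrow(detect_spots(img, detector_config(10, q)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unresolved doublets are flagged as merged", {
  # spacing-violating pair whose maxima are suppressed into one detection:
  # the supra-half-maximum support spans both lobes and trips the flag
  sigma_b <- 10 / (2 * sqrt(2))
  single <- make_spot_image(72, 72, matrix(c(35.5, 35.5), 1), sigma_b, 200)
  pair <- make_spot_image(72, 72, rbind(c(31.5, 35.5), c(39.5, 35.5)),
                          sigma_b, c(200, 180))
  cfg <- detector_config(10, 5, min_separation_px = 10)
  ds <- detect_spots(single, cfg)
  dp <- detect_spots(pair, cfg)
  expect_false(any(ds$merged_flag))
  expect_equal(nrow(dp), 1)
  expect_true(dp$merged_flag[1])
})

test_that("count_vesicles merges z-duplicates and respects the cell mask", {
  expect_equal(count_vesicles(tibble::tibble(x = numeric(), y = numeric(),
                                             quality = numeric())), 0L)
  det <- tibble::tibble(x = c(10, 10.4, 50), y = c(10, 10.2, 50),
                        z = c(1L, 2L, 1L), quality = c(9, 8, 7))
  expect_equal(count_vesicles(det, min_separation_px = 5), 2)
  mask <- matrix(FALSE, 64, 64); mask[1:32, 1:32] <- TRUE
  expect_equal(count_vesicles(det, mask, min_separation_px = 5), 1)
})

test_that("detector recovers all vesicles of a well-spaced synthetic scene", {
  p <- scene_params(n_vesicles = 30, contact_fraction = 0, n_mito = 0,
                    seed = 31)
  g <- generate_scene(p)
  ranges <- auto_display_range(g$stack)
  s8 <- to_8bit(g$stack, ranges)
  rv <- ranges[["CD63"]]
  blank <- render_blank_plane(p, seed = 777)
  blank8 <- pmin(pmax(floor(255 * (blank - rv$low) /
                              (rv$high - rv$low) + 0.5), 0), 255)
  thr <- calibrate_quality_threshold(blank8, 10)
  det <- detect_spots(get_plane(s8, "CD63"), detector_config(10, thr))
  truth <- scene_truth_table(g$scene)
  expect_equal(count_vesicles(det, g$scene$cell_mask), 30)
  matched <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((truth$x - det$x[i])^2 + (truth$y - det$y[i])^2)) <= 2
  }, logical(1))
  expect_true(all(matched))                       # precision 1
  expect_equal(nrow(det), nrow(truth))            # recall 1
})
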