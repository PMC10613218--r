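test_that("nearest structure direction and distance follow the tie-break rules", {
  mask <- matrix(FALSE, 32, 32)
  mask[11, 21] <- TRUE                       # (x, y) = (20, 10)
  nd <- nearest_structure_direction(c(10, 10), mask)
  expect_equal(nd$direction, c(1, 0))
  expect_equal(nd$distance, 10)
  expect_error(nearest_structure_direction(c(1, 1), matrix(FALSE, 4, 4)),
               class = "vesicoloc_geometry_error")
  # point inside the mask: zero distance, outward direction defined
  blk <- matrix(FALSE, 16, 16); blk[6:10, 6:10] <- TRUE
  nd0 <- nearest_structure_direction(c(7, 7), blk)
  expect_equal(nd0$distance, 0)
  expect_equal(sqrt(sum(nd0$direction^2)), 1, tolerance = 1e-12)
})

test_that("nearest target matches exhaustive search on random sparse masks", {
  set.seed(21)
  for (rep in 1:20) {
    mask <- matrix(runif(40 * 40) < 0.01, 40, 40)
    if (!any(mask)) next
    pt <- c(runif(1, 0, 39), runif(1, 0, 39))
    nd <- nearest_structure_direction(pt, mask)
    idx <- which(mask, arr.ind = TRUE)
    d <- sqrt((idx[, 2] - 1 - pt[1])^2 + (idx[, 1] - 1 - pt[2])^2)
    expect_equal(nd$distance, min(d), tolerance = 1e-12)
  }
})

test_that("region partition implements the twice-nuclear-diameter disk", {
  # circular nucleus of diameter 20 px -> perinuclear disk of diameter 40
  nuc <- vesicoloc:::ellipse_mask(128, 128, 63.5, 63.5, 10, 10)
  cell <- matrix(TRUE, 128, 128)
  part <- partition_cell_regions(nuc, cell)
  expect_equal(part$nuclear_diameter_px, 20, tolerance = 0.05)
  pts <- tibble::tibble(x = c(63.5 + 19, 63.5 + 21), y = c(63.5, 63.5))
  reg <- assign_regions(pts, part)
  expect_equal(reg$region, c("perinuclear", "peripheral"))
  # exact set partition of the cell mask
  expect_true(all((part$perinuclear_mask | part$peripheral_mask) == cell))
  expect_false(any(part$perinuclear_mask & part$peripheral_mask))
  expect_error(partition_cell_regions(matrix(FALSE, 4, 4), matrix(TRUE, 4, 4)),
               class = "vesicoloc_geometry_error")
})

test_that("elliptical nuclei use the equivalent-area diameter", {
  # ellipse with semi-axes 15 x 6 px: equivalent diameter 2*sqrt(15*6)
  nuc <- vesicoloc:::ellipse_mask(160, 160, 79.5, 79.5, 15, 6)
  part <- partition_cell_regions(nuc, matrix(TRUE, 160, 160))
  expect_equal(part$nuclear_diameter_px, 2 * sqrt(15 * 6), tolerance = 0.03)
  expect_equal(part$perinuclear_radius_px, part$nuclear_diameter_px)
})

test_that("contact detection requires overlapping supra-background runs", {
  h <- 96; w <- 96
  ves <- vesicoloc:::add_gaussian_spot(matrix(0, h, w), 30, 48, 3.5, 200)
  mito_mask <- matrix(FALSE, h, w)
  # flat mitochondria channel: never a contact
  arr <- array(0, c(2, 1, h, w)); arr[1, 1, , ] <- round(ves)
  s <- image_stack(arr, bit_depth = 8L, channel_names = c("CD63", "mito"))
  mito_mask[, 90] <- TRUE
  res <- detect_mmcs(tibble::tibble(x = 30, y = 48), s, "CD63", "mito",
                     mito_mask, background = 100)
  expect_false(res$is_contact[1])

  # filament touching the vesicle: contact with a recorded overlap range
  mcol <- 34
  mchan <- matrix(0, h, w); mchan[, mcol + 1] <- 600
  mchan <- vesicoloc:::gaussian_blur(mchan, 1)
  mask2 <- matrix(FALSE, h, w); mask2[, mcol + 1] <- TRUE
  arr2 <- array(0, c(2, 1, h, w))
  arr2[1, 1, , ] <- pmin(round(ves), 255); arr2[2, 1, , ] <- pmin(round(mchan), 255)
  s2 <- image_stack(arr2, bit_depth = 8L, channel_names = c("CD63", "mito"))
  res2 <- detect_mmcs(tibble::tibble(x = 30, y = 48), s2, "CD63", "mito",
                      mask2, background = 100)
  expect_true(res2$is_contact[1])
  expect_true(res2$overlap_end > res2$overlap_start)

  # signals on disjoint ranges: no contact
  mcol3 <- 70
  mchan3 <- matrix(0, h, w); mchan3[, mcol3 + 1] <- 600
  mchan3 <- vesicoloc:::gaussian_blur(mchan3, 1)
  mask3 <- matrix(FALSE, h, w); mask3[, mcol3 + 1] <- TRUE
  arr3 <- arr2; arr3[2, 1, , ] <- pmin(round(mchan3), 255)
  s3 <- image_stack(arr3, bit_depth = 8L, channel_names = c("CD63", "mito"))
  res3 <- detect_mmcs(tibble::tibble(x = 30, y = 48), s3, "CD63", "mito",
                      mask3, background = 100)
  expect_false(res3$is_contact[1])
})

test_that("contact truth is recovered on synthetic scenes", {
  p <- scene_params(seed = 61)
  g <- generate_scene(p)
  s8 <- to_8bit(g$stack, auto_display_range(g$stack))
  truth <- scene_truth_table(g$scene)
  res <- detect_mmcs(truth, s8, "CD63", "mito", g$scene$mito_mask)
  sens <- sum(res$is_contact & truth$is_contacting) / sum(truth$is_contacting)
  fpr <- sum(res$is_contact & !truth$is_contacting) / sum(!truth$is_contacting)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.1)
})

test_that("contacts are counted by region with whole-cell additivity", {
  nuc <- vesicoloc:::ellipse_mask(128, 128, 63.5, 63.5, 10, 10)
  part <- partition_cell_regions(nuc, matrix(TRUE, 128, 128))
  contacts <- tibble::tibble(
    x = c(63.5, 70, 55, 110, 5), y = c(63.5, 60, 70, 110, 5),
    is_contact = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cnt <- count_contacts_by_region(contacts, part)
  expect_equal(cnt$perinuclear, 3)
  expect_equal(cnt$peripheral, 1)
  expect_equal(cnt$whole_cell, cnt$perinuclear + cnt$peripheral)
  empty <- count_contacts_by_region(contacts[contacts$x > 1e6, ], part)
  expect_equal(unlist(empty), c(perinuclear = 0, peripheral = 0, whole_cell = 0))
})

test_that("EM direct-contact rule reproduces hand-computed contact sets", {
  ann <- tibble::tibble(
    object_class = c("MVE", "MVE", "mitochondrion", "mitochondrion"),
    id = c("m1", "m2", "t1", "t2"),
    x_um = c(0, 10, 0.85, 10.95),
    y_um = c(0, 0, 0, 0),
    radius_um = c(0.2, 0.4, 0.4, 0.2))
  # mean MVE radius 0.3; gaps: m1-t1 0.25 (<0.3), m1-t2 10.35, m2-t1 8.35,
  # m2-t2 0.35 (>= 0.3)
  res <- em_direct_contacts(ann)
  expect_equal(res$mean_mve_radius_um, 0.3)
  expect_equal(res$n_contacts, 1)
  hit <- res$pairs[res$pairs$is_contact, ]
  expect_equal(hit$mve_id, "m1"); expect_equal(hit$mito_id, "t1")
  expect_equal(hit$gap_um, 0.25, tolerance = 1e-12)

  # overlapping boundaries (negative gap) always contact
  ann2 <- ann; ann2$x_um[3] <- 0.3
  expect_true(any(tidy(em_direct_contacts(ann2))$gap_um < 0))
  expect_equal(em_direct_contacts(ann2)$n_contacts, 1)

  expect_error(em_direct_contacts(ann[ann$object_class != "MVE", ]),
               class = "vesicoloc_contract_error")
})

test_that("adding a larger MVE never removes existing EM contacts", {
  set.seed(5)
  ann <- tibble::tibble(
    object_class = rep(c("MVE", "mitochondrion"), each = 6),
    id = paste0("o", 1:12),
    x_um = runif(12, 0, 5), y_um = runif(12, 0, 5),
    radius_um = runif(12, 0.1, 0.5))
  before <- em_direct_contacts(ann)
  grown <- dplyr::bind_rows(ann, tibble::tibble(
    object_class = "MVE", id = "big", x_um = 50, y_um = 50, radius_um = 5))
  after <- em_direct_contacts(grown)
  expect_gte(after$mean_mve_radius_um, before$mean_mve_radius_um)
  key <- function(p) paste(p$mve_id, p$mito_id)[p$is_contact]
  expect_true(all(key(before$pairs) %in% key(after$pairs)))
})
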