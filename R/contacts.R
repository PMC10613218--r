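#' Direction and distance to the nearest structure pixel
#'
#' Finds the nearest `TRUE` pixel of a mask (Euclidean distance between
#' pixel centers) and returns the unit direction toward it. Ties are broken
#' by the smallest `(y, x)` in lexicographic order. A point already inside
#' the mask has distance 0; its direction is taken as the outward local
#' boundary normal (toward the nearest background pixel), so a profile can
#' still be drawn across the structure.
#'
#' @param point `c(x, y)` 0-based coordinates.
#' @param structure_mask Logical `(y, x)` matrix with at least one `TRUE`.
#' @return List: `direction` (unit `c(dx, dy)`), `distance` (px),
#'   `target` (`c(x, y)` of the nearest mask pixel).
#' @export
nearest_structure_direction <- function(point, structure_mask) {
  idx <- which(structure_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    abort("Structure mask is empty.", class = "vesicoloc_geometry_error")
  }
  tx <- unname(idx[, 2]) - 1; ty <- unname(idx[, 1]) - 1
  d2 <- (tx - point[1])^2 + (ty - point[2])^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) best <- best[order(ty[best], tx[best])][1]
  target <- c(tx[best], ty[best])
  dist <- sqrt(d2[best])
  if (dist > 0) {
    return(list(direction = (target - point) / dist, distance = dist,
                target = target))
  }
  # inside the mask: aim at the nearest background pixel (outward normal)
  bg <- which(!structure_mask, arr.ind = TRUE)
  if (nrow(bg) == 0) {
    return(list(direction = c(1, 0), distance = 0, target = target))
  }
  bx <- unname(bg[, 2]) - 1; by <- unname(bg[, 1]) - 1
  d2b <- (bx - point[1])^2 + (by - point[2])^2
  bb <- which(d2b == min(d2b))
  if (length(bb) > 1) bb <- bb[order(by[bb], bx[bb])][1]
  dirv <- c(bx[bb], by[bb]) - point
  list(direction = dirv / sqrt(sum(dirv^2)), distance = 0, target = target)
}

# per-channel background threshold: mean + 2 sd of pixels outside objects
background_threshold <- function(plane, object_mask) {
  bgpix <- plane[!object_mask]
  if (length(bgpix) < 2) bgpix <- as.vector(plane)
  mean(bgpix) + 2 * sd(bgpix)
}

#' Detect mitochondrion-vesicle contact sites along profiles
#'
#' For each vesicle, draws a 50-px line profile from the vesicle center
#' toward the closest mitochondrion and finds supra-background signal runs
#' in the vesicle and mitochondria channels. The vesicle is called a
#' contact site (MMCS) when the two channels' signal supports intersect.
#'
#' Background is not a printed constant of the procedure; by default each
#' channel's threshold is `mean + 2 sd` of intensities outside all detected
#' objects (`background = "auto"`). Pass a number (e.g. the profile cutoff
#' 100) to use a fixed threshold instead. `strict_same_sample = TRUE`
#' additionally requires both channels above threshold at one common sample
#' (the default only requires the runs to overlap).
#'
#' @param vesicles Tibble with `x`, `y` (0-based vesicle anchors).
#' @param stack8 8-bit [image_stack()].
#' @param vesicle_channel,mito_channel Channel names or indices.
#' @param mito_mask Logical `(y, x)` mitochondria mask (targets for the
#'   line direction).
#' @param length_px Profile length (50 by convention for contact scoring).
#' @param background `"auto"` or a numeric threshold applied to both
#'   channels (or `c(vesicle, mito)` thresholds).
#' @param strict_same_sample See Details.
#' @param z z-plane.
#' @return Tibble, one row per vesicle: `vesicle_id`, `x`, `y`,
#'   `is_contact`, `overlap_start`, `overlap_end` (0-based half-open; `NA`
#'   when no contact), `dist_to_mito_px`.
#' @export
detect_mmcs <- function(vesicles, stack8, vesicle_channel, mito_channel,
                        mito_mask, length_px = 50, background = "auto",
                        strict_same_sample = FALSE, z = 1) {
  stopifnot(inherits(stack8, "image_stack"))
  if (!identical(stack8$bit_depth, 8L)) {
    abort("Contact scoring operates on the 8-bit converted stack.",
          class = "vesicoloc_contract_error")
  }
  vplane <- get_plane(stack8, vesicle_channel, z)
  mplane <- get_plane(stack8, mito_channel, z)
  if (identical(background, "auto")) {
    obj <- mito_mask
    for (i in seq_len(nrow(vesicles))) {
      r <- round(vesicles$y[i]) + 1; c <- round(vesicles$x[i]) + 1
      rr <- max(1, r - 6):min(nrow(obj), r + 6)
      cc <- max(1, c - 6):min(ncol(obj), c + 6)
      obj[rr, cc] <- TRUE
    }
    thr_v <- background_threshold(vplane, obj)
    thr_m <- background_threshold(mplane, obj)
  } else {
    thr_v <- background[[1]]
    thr_m <- if (length(background) > 1) background[[2]] else background[[1]]
  }
  rows <- map(seq_len(nrow(vesicles)), function(i) {
    anchor <- c(vesicles$x[i], vesicles$y[i])
    nd <- nearest_structure_direction(anchor, mito_mask)
    prof <- extract_line_profile(stack8, anchor, nd$direction, length_px, z)
    vs <- prof$samples[, channel_index(stack8, vesicle_channel)]
    ms <- prof$samples[, channel_index(stack8, mito_channel)]
    pv <- find_signal_peaks(vs, thr_v)
    pm <- find_signal_peaks(ms, thr_m)
    ov <- c(NA_integer_, NA_integer_)
    hit <- FALSE
    for (a in seq_len(nrow(pv))) {
      for (b in seq_len(nrow(pm))) {
        s <- max(pv$start_idx[a], pm$start_idx[b])
        e <- min(pv$end_idx[a], pm$end_idx[b])
        if (e > s) { hit <- TRUE; ov <- c(s, e); break }
      }
      if (hit) break
    }
    if (strict_same_sample && hit) {
      ks <- (ov[1] + 1):ov[2]
      hit <- any(!is.na(vs[ks]) & !is.na(ms[ks]) & vs[ks] > thr_v & ms[ks] > thr_m)
      if (!hit) ov <- c(NA_integer_, NA_integer_)
    }
    tibble(vesicle_id = i, x = anchor[1], y = anchor[2], is_contact = hit,
           overlap_start = if (hit) ov[1] else NA_integer_,
           overlap_end = if (hit) ov[2] else NA_integer_,
           dist_to_mito_px = nd$distance)
  })
  list_rbind(rows)
}

#' Partition a cell into perinuclear and peripheral regions
#'
#' The perinuclear region is the disk of twice the nuclear diameter,
#' centered on the nucleus centroid, intersected with the cell mask; the
#' remaining cell area is peripheral. For non-circular nuclei the nuclear
#' diameter is the equivalent-area circle diameter, `2 * sqrt(area / pi)`.
#'
#' @param nucleus_mask,cell_mask Logical `(y, x)` matrices; the nucleus must
#'   lie within the cell and both must be nonempty.
#' @return A `region_partition`: nuclear center (`c(x, y)`), equivalent
#'   nuclear diameter (px), perinuclear radius, and the two region masks.
#' @export
partition_cell_regions <- function(nucleus_mask, cell_mask) {
  if (!any(nucleus_mask) || !any(cell_mask)) {
    abort("Masks must be nonempty.", class = "vesicoloc_geometry_error")
  }
  idx <- which(nucleus_mask, arr.ind = TRUE)
  center <- c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))  # (x, y)
  nd <- 2 * sqrt(sum(nucleus_mask) / pi)
  h <- nrow(cell_mask); w <- ncol(cell_mask)
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  disk <- (xs - center[1])^2 + (ys - center[2])^2 <= nd^2  # radius = diameter
  perinuclear <- disk & cell_mask
  structure(list(nuclear_center = center, nuclear_diameter_px = nd,
                 perinuclear_radius_px = nd,
                 perinuclear_mask = perinuclear,
                 peripheral_mask = cell_mask & !perinuclear),
            class = "region_partition")
}

#' Assign points to cell regions
#'
#' @param points Tibble with `x`, `y` (0-based).
#' @param partition A [partition_cell_regions()] result.
#' @return `points` with a `region` column (`"perinuclear"` or
#'   `"peripheral"`, by distance of the anchor to the nuclear center).
#' @export
assign_regions <- function(points, partition) {
  stopifnot(inherits(partition, "region_partition"))
  d <- sqrt((points$x - partition$nuclear_center[1])^2 +
              (points$y - partition$nuclear_center[2])^2)
  mutate(points, region = ifelse(d <= partition$perinuclear_radius_px,
                                 "perinuclear", "peripheral"))
}

#' Count contact sites by cell region
#'
#' Contacts are localized at the vesicle anchor (the vesicle, not the
#' mitochondrion, is the counted object). Whole-cell equals perinuclear plus
#' peripheral by construction.
#'
#' @param contacts Tibble from [detect_mmcs()] (needs `x`, `y`,
#'   `is_contact`).
#' @param partition A [partition_cell_regions()] result.
#' @return One-row tibble: `perinuclear`, `peripheral`, `whole_cell`.
#' @export
count_contacts_by_region <- function(contacts, partition) {
  hits <- assign_regions(filter(contacts, .data$is_contact), partition)
  peri <- sum(hits$region == "perinuclear")
  tibble(perinuclear = peri,
         peripheral = nrow(hits) - peri,
         whole_cell = nrow(hits))
}

#' Direct contacts from EM annotations
#'
#' Applies the electron-microscopy rule: with `r_bar` the mean radius of the
#' image's MVEs, every MVE-mitochondrion pair whose boundary-to-boundary gap
#' (center distance minus the two radii, for circular annotations) is less
#' than `r_bar` is a direct contact. The gap is boundary-to-boundary, not
#' center-to-center, since the rule compares against a radius.
#'
#' @param annotations Tibble with columns `object_class` (`"MVE"` or
#'   `"mitochondrion"`), `id`, `x_um`, `y_um`, `radius_um`, and optionally
#'   `ilv_count` for MVEs.
#' @return A list of class `em_contacts`: `pairs` (tibble: `mve_id`,
#'   `mito_id`, `gap_um`, `is_contact`), `n_contacts`,
#'   `mean_mve_radius_um`.
#' @export
em_direct_contacts <- function(annotations) {
  mves <- filter(annotations, .data$object_class == "MVE")
  mitos <- filter(annotations, .data$object_class == "mitochondrion")
  if (nrow(mves) == 0) {
    abort("At least one MVE annotation is required (mean radius undefined).",
          class = "vesicoloc_contract_error")
  }
  r_bar <- mean(mves$radius_um)
  pairs <- tidyr::expand_grid(i = seq_len(nrow(mves)), j = seq_len(nrow(mitos)))
  pairs <- mutate(pairs,
    mve_id = mves$id[.data$i], mito_id = mitos$id[.data$j],
    gap_um = sqrt((mves$x_um[.data$i] - mitos$x_um[.data$j])^2 +
                    (mves$y_um[.data$i] - mitos$y_um[.data$j])^2) -
      mves$radius_um[.data$i] - mitos$radius_um[.data$j],
    is_contact = .data$gap_um < r_bar)
  pairs <- select(pairs, -"i", -"j")
  structure(list(pairs = pairs, n_contacts = sum(pairs$is_contact),
                 mean_mve_radius_um = r_bar),
            class = "em_contacts")
}

#' @export
print.em_contacts <- function(x, ...) {
  cat(sprintf("<em_contacts> %d direct contact(s) of %d pair(s); mean MVE radius %.3g um\n",
              x$n_contacts, nrow(x$pairs), x$mean_mve_radius_um))
  invisible(x)
}

#' @export
tidy.em_contacts <- function(x, ...) x$pairs

#' @export
glance.em_contacts <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), n_contacts = x$n_contacts,
         mean_mve_radius_um = x$mean_mve_radius_um)
}
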