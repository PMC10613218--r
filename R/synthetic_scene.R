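#' Parameters for a synthetic cell scene
#'
#' Defines everything needed to render a multi-channel synthetic cell with
#' known ground truth: vesicle puncta in a "vesicle" channel, partially
#' colocalized puncta in a "marker" channel at a configurable true fraction,
#' filamentous mitochondria, an elliptical nucleus, Gaussian PSF blur and
#' Poisson + Gaussian read noise.
#'
#' Defaults encode the study conditions this generator emulates: ~1 um
#' vesicles (10 px at 0.1 um/px), a 45% marker-positive fraction, marker
#' puncta offset 2 px from vesicle centers so they occupy discrete regions of
#' the vesicle surface rather than coinciding with it, and a minimum
#' center-to-center spacing of twice the vesicle diameter so ground-truth
#' counting is unambiguous.
#'
#' @param image_size_px `(height, width)` in pixels.
#' @param pixel_size_um Physical pixel size (um).
#' @param n_vesicles Number of vesicles to place.
#' @param vesicle_diameter_um `c(mean, sd)` of vesicle diameters (um).
#' @param marker_positive_fraction Probability a vesicle carries a marker
#'   punctum, in `[0, 1]`.
#' @param marker_offset_px Displacement of the marker punctum from the
#'   vesicle center (px), in a uniformly random direction.
#' @param marker_sigma_px Gaussian sd of marker puncta (px).
#' @param contact_fraction Probability a vesicle touches a mitochondrion.
#' @param mito_clear_margin_px Minimum distance (px) from non-contacting
#'   vesicle centers to any mitochondrion skeleton pixel.
#' @param n_mito Number of mitochondrial filaments.
#' @param psf_sigma_px Gaussian PSF blur sd (px), applied to all channels.
#' @param noise List: `background` (counts added everywhere),
#'   `poisson_scale` (photon conversion; 0 disables shot noise) and
#'   `gaussian_sd` (read noise sd, counts).
#' @param vesicle_intensity,marker_intensity `c(min, max)` uniform range of
#'   pre-blur peak amplitudes (16-bit counts).
#' @param mito_intensity,nucleus_intensity Scalar amplitudes.
#' @param nucleus List: `center` (`c(x, y)` px, 0-based; `NULL` = image
#'   center), `diameter_um`, `axis_ratio` (minor/major).
#' @param spacing_factor Minimum center-to-center spacing as a multiple of
#'   the mean vesicle diameter; the "crowded" preset lowers this to stress
#'   merged-detection flagging.
#' @param ring_mode Render vesicles as Gaussian shells instead of filled
#'   spots (for larger endosomes whose lumen resolves).
#' @param margin_px Keep-out border for vesicle centers.
#' @param seed RNG seed; every stochastic draw in the scene flows from it.
#'
#' @return A `scene_params` object (a validated list).
#' @export
scene_params <- function(image_size_px = c(384, 384),
                         pixel_size_um = 0.1,
                         n_vesicles = 50,
                         vesicle_diameter_um = c(1.0, 0.1),
                         marker_positive_fraction = 0.45,
                         marker_offset_px = 2,
                         marker_sigma_px = 1.5,
                         contact_fraction = 0.3,
                         mito_clear_margin_px = 25,
                         n_mito = 6,
                         psf_sigma_px = 1.0,
                         noise = list(background = 200, poisson_scale = 1,
                                      gaussian_sd = 20),
                         vesicle_intensity = c(2500, 4500),
                         marker_intensity = c(3000, 4500),
                         mito_intensity = 3000,
                         nucleus_intensity = 3000,
                         nucleus = list(center = NULL, diameter_um = 8,
                                        axis_ratio = 0.8),
                         spacing_factor = 2,
                         ring_mode = FALSE,
                         margin_px = 12,
                         seed = 1L) {
  p <- as.list(environment())
  stopifnot(length(p$image_size_px) == 2, all(p$image_size_px >= 32))
  if (p$pixel_size_um <= 0 || p$vesicle_diameter_um[1] <= 0 || p$psf_sigma_px < 0) {
    abort("Physical sizes must be positive.", class = "vesicoloc_parameter_error")
  }
  if (p$n_vesicles < 0) {
    abort("`n_vesicles` must be >= 0.", class = "vesicoloc_parameter_error")
  }
  for (f in c("marker_positive_fraction", "contact_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f), class = "vesicoloc_parameter_error")
    }
  }
  structure(p, class = "scene_params")
}

with_scene_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(h, w, cx, cy, ax, ay) {
  # 0-based pixel-center coordinates
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
}

# add an isotropic Gaussian (peak = amplitude) to canvas at 0-based (x, y)
add_gaussian_spot <- function(canvas, x, y, sigma, amplitude, ring = FALSE) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(4 * sigma)
  cols <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
  rows <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
  if (!length(cols) || !length(rows)) return(canvas)
  gx <- exp(-((cols - x)^2) / (2 * sigma^2))
  gy <- exp(-((rows - y)^2) / (2 * sigma^2))
  patch <- amplitude * outer(gy, gx)
  if (ring) {
    d2 <- outer((rows - y)^2, (cols - x)^2, "+")
    w_ring <- max(sigma / 2, 0.75)
    patch <- amplitude * exp(-(sqrt(d2) - sigma)^2 / (2 * w_ring^2))
  }
  canvas[rows + 1, cols + 1] <- canvas[rows + 1, cols + 1] + patch
  canvas
}

reflect_pad <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(r < h, r < w)
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  m[ri, ci]
}

# Gaussian blur with reflective boundary (FFT convolution on padded image)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(k1, k1); k <- k / sum(k)
  p <- reflect_pad(m, r)
  out <- EBImage::filter2(p, k, boundary = "circular")
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))]
}

rasterize_polyline <- function(vertices, h, w, step = 0.25) {
  # vertices: matrix with columns x, y (0-based); returns integer (row, col)
  pts <- NULL
  for (i in seq_len(nrow(vertices) - 1)) {
    a <- vertices[i, ]; b <- vertices[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, by = step / max(len, step))
    pts <- rbind(pts, cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2])))
  }
  ij <- unique(cbind(round(pts[, 2]), round(pts[, 1])))  # (y, x)
  ij <- ij[ij[, 1] >= 0 & ij[, 1] < h & ij[, 2] >= 0 & ij[, 2] < w, , drop = FALSE]
  ij + 1L  # 1-based matrix indices
}

#' Generate a synthetic scene and its rendered image stack
#'
#' Channels are rendered in the order vesicle, marker, mitochondria, nucleus
#' (named `CD63`, `marker`, `mito`, `DAPI`). Vesicles are isotropic Gaussian
#' spots of sd `diameter / (2 * sqrt(2))` — the scale at which a
#' Laplacian-of-Gaussian detector set to that diameter responds maximally —
#' marker puncta are rendered only for positive vesicles at the vesicle
#' center plus the configured offset, mitochondria are blurred random-walk
#' polylines, and noise is applied last. The returned stack is 16-bit
#' (pre-8-bit-conversion).
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `scene` (a `synthetic_scene`: params, truth
#'   tibble, mitochondria skeleton, masks) and `stack` (an [image_stack()]).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_scene_seed(params$seed, {
    h <- params$image_size_px[1]; w <- params$image_size_px[2]
    ctr <- c((w - 1) / 2, (h - 1) / 2)

    cell_mask <- ellipse_mask(h, w, ctr[1], ctr[2], 0.48 * w, 0.48 * h)
    nuc <- params$nucleus
    ncen <- nuc$center %||% ctr
    nd_px <- nuc$diameter_um / params$pixel_size_um
    # ellipse with the requested equivalent-area diameter
    a <- nd_px / 2 / sqrt(nuc$axis_ratio); b <- a * nuc$axis_ratio
    nucleus_mask <- ellipse_mask(h, w, ncen[1], ncen[2], a, b)

    # mitochondria: jittered random walks steered to stay inside the cell
    # and outside the nucleus; filaments are added beyond n_mito if needed so
    # the usable skeleton can host the expected number of contacting
    # vesicles at the requested spacing
    inside_ok <- function(pt) {
      cx <- round(pt[1]) + 1; cy <- round(pt[2]) + 1
      pt[1] >= 2 && pt[1] <= w - 3 && pt[2] >= 2 && pt[2] <= h - 3 &&
        cell_mask[cy, cx] && !nucleus_mask[cy, cx]
    }
    min_sep <- params$spacing_factor * params$vesicle_diameter_um[1] /
      params$pixel_size_um
    need_len <- 2.5 * params$n_vesicles * params$contact_fraction * min_sep
    mito_segments <- list()
    skel_pts <- NULL
    n_fil <- 0L
    while (n_fil < params$n_mito ||
           (2 * max(0, nrow(skel_pts %||% matrix(0, 0, 2)) - 1) < need_len &&
            n_fil < 3L * params$n_mito)) {
      n_fil <- n_fil + 1L
      start <- NULL
      for (try in 1:100) {
        cand <- c(runif(1, 0.1 * w, 0.9 * w), runif(1, 0.1 * h, 0.9 * h))
        if (inside_ok(cand)) { start <- cand; break }
      }
      if (is.null(start)) next
      ang <- runif(1, 0, 2 * pi)
      n_steps <- sample(30:60, 1)
      verts <- matrix(start, ncol = 2)
      pos <- start
      for (s in seq_len(n_steps)) {
        ang <- ang + rnorm(1, 0, 0.25)
        stepped <- FALSE
        for (turn in 1:8) {
          nxt <- pos + 2 * c(cos(ang), sin(ang))
          if (inside_ok(nxt)) { stepped <- TRUE; break }
          ang <- ang + pi / 4
        }
        if (!stepped) break
        pos <- nxt
        verts <- rbind(verts, pos)
      }
      if (nrow(verts) > 1) {
        mito_segments[[length(mito_segments) + 1]] <- verts
        skel_pts <- rbind(skel_pts, verts)
      }
    }
    mito_mask <- matrix(FALSE, h, w)
    for (v in mito_segments) {
      ij <- rasterize_polyline(v, h, w)
      mito_mask[ij] <- TRUE
    }

    # vesicle placement with rejection sampling
    nv <- params$n_vesicles
    diam_px <- pmax(0.4, rnorm(nv, params$vesicle_diameter_um[1],
                               params$vesicle_diameter_um[2])) / params$pixel_size_um
    positive <- runif(nv) < params$marker_positive_fraction
    contacting <- runif(nv) < params$contact_fraction
    if (is.null(skel_pts)) contacting[] <- FALSE
    min_sep <- params$spacing_factor * params$vesicle_diameter_um[1] /
      params$pixel_size_um
    centers <- matrix(NA_real_, nv, 2)
    mg <- params$margin_px
    for (i in seq_len(nv)) {
      placed <- FALSE
      for (try in seq_len(5000)) {
        if (contacting[i]) {
          anchor <- skel_pts[sample(nrow(skel_pts), 1), ]
          off_ang <- runif(1, 0, 2 * pi)
          off_len <- runif(1, 0, 0.6 * diam_px[i] / 2)
          cand <- anchor + off_len * c(cos(off_ang), sin(off_ang))
        } else {
          cand <- c(runif(1, mg, w - 1 - mg), runif(1, mg, h - 1 - mg))
        }
        cx <- round(cand[1]) + 1; cy <- round(cand[2]) + 1
        if (cand[1] < mg || cand[1] > w - 1 - mg ||
            cand[2] < mg || cand[2] > h - 1 - mg) next
        if (!cell_mask[cy, cx] || nucleus_mask[cy, cx]) next
        if (i > 1) {
          d2 <- (centers[seq_len(i - 1), 1] - cand[1])^2 +
            (centers[seq_len(i - 1), 2] - cand[2])^2
          if (any(d2 < min_sep^2, na.rm = TRUE)) next
        }
        if (!is.null(skel_pts)) {
          dmito <- sqrt(min((skel_pts[, 1] - cand[1])^2 +
                              (skel_pts[, 2] - cand[2])^2))
          if (contacting[i] && dmito > diam_px[i] / 2) next
          if (!contacting[i] && dmito < params$mito_clear_margin_px) next
        }
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("Could not place all vesicles; the cell is too crowded for the requested spacing.",
              class = "vesicoloc_generation_error")
      }
    }

    amp_v <- runif(nv, params$vesicle_intensity[1], params$vesicle_intensity[2])
    amp_m <- runif(nv, params$marker_intensity[1], params$marker_intensity[2])
    marker_ang <- runif(nv, 0, 2 * pi)

    ch_v <- matrix(0, h, w); ch_m <- matrix(0, h, w)
    sig_spot <- diam_px / (2 * sqrt(2))
    for (i in seq_len(nv)) {
      ch_v <- add_gaussian_spot(ch_v, centers[i, 1], centers[i, 2],
                                sig_spot[i], amp_v[i], ring = params$ring_mode)
      if (positive[i]) {
        mx <- centers[i, 1] + params$marker_offset_px * cos(marker_ang[i])
        my <- centers[i, 2] + params$marker_offset_px * sin(marker_ang[i])
        ch_m <- add_gaussian_spot(ch_m, mx, my, params$marker_sigma_px, amp_m[i])
      }
    }
    ch_mito <- matrix(0, h, w); ch_mito[mito_mask] <- params$mito_intensity
    ch_nuc <- matrix(0, h, w); ch_nuc[nucleus_mask] <- params$nucleus_intensity

    planes <- list(ch_v, ch_m, ch_mito, ch_nuc)
    planes <- lapply(planes, gaussian_blur, sigma = params$psf_sigma_px)
    nz <- params$noise
    planes <- lapply(planes, function(p) {
      p <- p + nz$background
      if (nz$poisson_scale > 0) {
        p <- rpois(length(p), pmax(p, 0) * nz$poisson_scale) / nz$poisson_scale
      }
      p <- p + rnorm(length(p), 0, nz$gaussian_sd)
      matrix(pmin(65535, pmax(0, round(p))), h, w)
    })
    arr <- array(0, dim = c(4, 1, h, w))
    for (k in 1:4) arr[k, 1, , ] <- planes[[k]]
    stack <- image_stack(arr, pixel_size_um = params$pixel_size_um,
                         bit_depth = 16L,
                         channel_names = c("CD63", "marker", "mito", "DAPI"))

    nuc_equiv_d <- 2 * sqrt(sum(nucleus_mask) / pi)
    dist_nuc <- sqrt((centers[, 1] - ncen[1])^2 + (centers[, 2] - ncen[2])^2)
    dist_mito <- if (!is.null(skel_pts) && nv > 0) {
      map_dbl(seq_len(nv), function(i) {
        sqrt(min((skel_pts[, 1] - centers[i, 1])^2 +
                   (skel_pts[, 2] - centers[i, 2])^2))
      })
    } else rep(NA_real_, nv)
    truth <- tibble(
      vesicle_id = seq_len(nv),
      x = centers[, 1], y = centers[, 2],
      diameter_px = diam_px,
      diameter_um = diam_px * params$pixel_size_um,
      peak_intensity = amp_v,
      is_marker_positive = positive,
      is_contacting = contacting,
      dist_to_mito_px = dist_mito,
      region = ifelse(dist_nuc < nuc_equiv_d, "perinuclear", "peripheral")
    )
    scene <- structure(
      list(params = params, truth = truth, mito_segments = mito_segments,
           mito_mask = mito_mask, nucleus_mask = nucleus_mask,
           cell_mask = cell_mask, nucleus_center = ncen,
           nucleus_equiv_diameter_px = nuc_equiv_d),
      class = "synthetic_scene"
    )
    list(scene = scene, stack = stack)
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d vesicles (%.0f%% marker+, %.0f%% contacting), %d mito filaments, seed %s\n",
              nrow(x$truth), 100 * mean(x$truth$is_marker_positive),
              100 * mean(x$truth$is_contacting), length(x$mito_segments),
              as.character(x$params$seed)))
  invisible(x)
}

#' Ground-truth table of a synthetic scene
#'
#' @param scene A `synthetic_scene` from [generate_scene()].
#' @return A tibble with one row per vesicle: position, diameter, marker and
#'   contact flags, and the perinuclear/peripheral region label under the
#'   scene's nucleus geometry.
#' @export
scene_truth_table <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  scene$truth
}

#' Render a blank noise-only plane under a scene's noise model
#'
#' Used to calibrate detector quality thresholds from the response noise
#' floor of object-free images.
#'
#' @param params A [scene_params()] object.
#' @param seed Seed for the noise draw.
#' @return A 16-bit `(y, x)` matrix.
#' @export
render_blank_plane <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  with_scene_seed(seed, {
    h <- params$image_size_px[1]; w <- params$image_size_px[2]
    nz <- params$noise
    p <- matrix(nz$background, h, w)
    if (nz$poisson_scale > 0) {
      p <- matrix(rpois(length(p), p * nz$poisson_scale) / nz$poisson_scale, h, w)
    }
    p <- p + rnorm(length(p), 0, nz$gaussian_sd)
    matrix(pmin(65535, pmax(0, round(p))), h, w)
  })
}

#' Write a scene to disk as a self-describing fixture directory
#'
#' Writes the image stack (multi-page TIFF, `zcyx` page order), the
#' ground-truth table (CSV) and the generation parameters (YAML) side by
#' side.
#'
#' @param scene,stack As returned by [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, stack, dir) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(stack, file.path(dir, "stack.tif"))
  readr::write_csv(scene$truth, file.path(dir, "truth.csv"))
  p <- scene$params
  p$image_size_px <- as.integer(p$image_size_px)
  yaml::write_yaml(unclass(p), file.path(dir, "params.yaml"))
  invisible(dir)
}
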