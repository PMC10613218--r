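#' Line-profile scoring configuration
#'
#' Controls the fixed-length intensity profiles drawn across vesicles and
#' the peak-overlap rule that classifies a vesicle as marker-positive:
#' 40-px lines for marker (e.g. exocyst) scoring, 50-px lines for
#' mitochondrion contact profiles; a peak is a maximal run of samples
#' strictly above the cutoff (100 on the 8-bit scale); a vesicle is positive
#' when the overlap area exceeds half of the marker peak's area.
#'
#' @param length_px Number of 1-px-spaced samples along the line (>= 2).
#' @param cutoff Signal threshold in 8-bit units (0-255). A sample exactly
#'   at the cutoff is not signal (strictly greater-than).
#' @param overlap_fraction_threshold Minimum share of the marker peak area
#'   that must overlap the vesicle peak; the call at exactly this share is
#'   negative ("greater than").
#' @param direction_mode How the line direction is chosen:
#'   `"principal-axis"` (local intensity principal axis around the vesicle),
#'   `"toward-marker"` (from the vesicle center through the local
#'   marker-channel maximum, emulating an operator orienting the line
#'   through the visible marker signal), `"toward-reference"` (toward a
#'   supplied point or structure) or `"fixed-angle"`.
#' @param fixed_angle Direction in radians when `direction_mode =
#'   "fixed-angle"`.
#' @param area_mode `"raw-sum"` (peak area = sum of raw intensities over the
#'   run; default) or `"above-cutoff"` (sum of intensity minus cutoff).
#' @param overlap_mode `"min-curve"` (overlap area = pointwise minimum of
#'   the two channels over the support intersection; default) or
#'   `"support-length"` (number of shared supra-cutoff samples).
#' @return A `profile_config` object.
#' @export
profile_config <- function(length_px = 40, cutoff = 100,
                           overlap_fraction_threshold = 0.5,
                           direction_mode = c("principal-axis",
                                              "toward-marker",
                                              "toward-reference",
                                              "fixed-angle"),
                           fixed_angle = 0,
                           area_mode = c("raw-sum", "above-cutoff"),
                           overlap_mode = c("min-curve", "support-length")) {
  if (length_px < 2 || cutoff < 0 || cutoff > 255 ||
      overlap_fraction_threshold <= 0 || overlap_fraction_threshold > 1) {
    abort("Invalid profile configuration.", class = "vesicoloc_parameter_error")
  }
  structure(list(length_px = as.integer(length_px), cutoff = cutoff,
                 overlap_fraction_threshold = overlap_fraction_threshold,
                 direction_mode = match.arg(direction_mode),
                 fixed_angle = fixed_angle,
                 area_mode = match.arg(area_mode),
                 overlap_mode = match.arg(overlap_mode)),
            class = "profile_config")
}

# vectorized bilinear interpolation at 0-based (x, y); NA outside the grid
bilinear_sample <- function(plane, x, y) {
  h <- nrow(plane); w <- ncol(plane)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]
  x0 <- pmin(floor(xo), w - 2); y0 <- pmin(floor(yo), h - 2)
  fx <- xo - x0; fy <- yo - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  out[ok] <- (1 - fy) * ((1 - fx) * plane[i00] + fx * plane[i01]) +
    fy * ((1 - fx) * plane[i10] + fx * plane[i11])
  out
}

#' Extract a fixed-length intensity profile across a point
#'
#' Samples all channels of a stack at 1-px steps along a line centered on
#' the anchor: positions `anchor + (k - (length_px - 1) / 2) * direction`,
#' `k = 0, ..., length_px - 1`, by bilinear interpolation. Samples falling
#' outside the image are marked missing (`NA`) and never contribute to
#' peaks.
#'
#' @param stack An 8-bit [image_stack()] (profiles and the cutoff are
#'   defined on the 8-bit scale).
#' @param anchor `c(x, y)` 0-based pixel coordinates of the vesicle center.
#' @param direction `c(dx, dy)` direction; normalized internally.
#' @param length_px Number of samples.
#' @param z z-plane index.
#' @return A `line_profile`: anchor, unit direction, and a
#'   `length_px x n_channels` sample matrix (columns named by channel).
#' @export
extract_line_profile <- function(stack, anchor, direction, length_px = 40,
                                 z = 1) {
  stopifnot(inherits(stack, "image_stack"))
  h <- dim(stack$pixels)[3]; w <- dim(stack$pixels)[4]
  if (anchor[1] < 0 || anchor[1] > w - 1 || anchor[2] < 0 || anchor[2] > h - 1) {
    abort("Anchor lies outside the image.", class = "vesicoloc_geometry_error")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("Direction must be nonzero.", class = "vesicoloc_geometry_error")
  d <- direction / nrm
  ks <- seq_len(length_px) - 1
  off <- ks - (length_px - 1) / 2
  xs <- anchor[1] + off * d[1]
  ys <- anchor[2] + off * d[2]
  samples <- vapply(seq_len(n_channels(stack)), function(ch) {
    bilinear_sample(get_plane(stack, ch, z), xs, ys)
  }, numeric(length_px))
  samples <- matrix(samples, nrow = length_px,
                    dimnames = list(NULL, stack$channel_names))
  structure(list(anchor = anchor, direction = d,
                 length_px = as.integer(length_px), samples = samples),
            class = "line_profile")
}

#' @export
as_tibble.line_profile <- function(x, ...) {
  tb <- as_tibble(as.data.frame(x$samples))
  tb <- mutate(tb, sample_idx = seq_len(x$length_px) - 1L,
               offset_px = .data$sample_idx - (x$length_px - 1) / 2,
               .before = 1L)
  tidyr::pivot_longer(tb, cols = -c("sample_idx", "offset_px"),
                      names_to = "channel", values_to = "intensity")
}

#' Local intensity principal axis at a point
#'
#' Intensity-weighted second-moment direction in a square window around the
#' anchor; the default line orientation for "a line drawn across each
#' vesicle" when no reference structure dictates one. Degenerate (isotropic
#' or empty) windows fall back to the x axis.
#'
#' @param plane `(y, x)` matrix.
#' @param x,y 0-based anchor coordinates.
#' @param radius Window half-width in px.
#' @return Unit `c(dx, dy)`.
#' @export
principal_axis_direction <- function(plane, x, y, radius = 5) {
  h <- nrow(plane); w <- ncol(plane)
  cs <- max(0, round(x) - radius):min(w - 1, round(x) + radius)
  rs <- max(0, round(y) - radius):min(h - 1, round(y) + radius)
  patch <- plane[rs + 1, cs + 1, drop = FALSE]
  wt <- patch - min(patch)
  if (sum(wt) <= 0) return(c(1, 0))
  xs <- matrix(rep(cs, each = length(rs)), nrow = length(rs)) - x
  ys <- matrix(rep(rs, times = length(cs)), nrow = length(rs)) - y
  sw <- sum(wt)
  mx <- sum(wt * xs) / sw; my <- sum(wt * ys) / sw
  cxx <- sum(wt * (xs - mx)^2) / sw
  cyy <- sum(wt * (ys - my)^2) / sw
  cxy <- sum(wt * (xs - mx) * (ys - my)) / sw
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (abs(ev$values[1] - ev$values[2]) < 1e-12) return(c(1, 0))
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  v
}

#' Find signal peaks in a profile channel
#'
#' A signal peak is a maximal contiguous run of samples strictly above the
#' cutoff. Runs of length 1 count. Missing samples (outside the image) break
#' runs. Peak area is the sum of raw sample intensities over the run (or the
#' cutoff-subtracted sum under `area_mode = "above-cutoff"`).
#'
#' @param samples Numeric vector of intensities (possibly `NA`), or a
#'   `line_profile` together with `channel`.
#' @param cutoff Threshold; samples must exceed it strictly.
#' @param channel Channel name when `samples` is a `line_profile`.
#' @param area_mode See [profile_config()].
#' @return Tibble with 0-based half-open runs: `start_idx`, `end_idx`,
#'   `length`, `area`, `max_intensity`.
#' @export
find_signal_peaks <- function(samples, cutoff = 100, channel = NULL,
                              area_mode = "raw-sum") {
  if (inherits(samples, "line_profile")) {
    stopifnot(!is.null(channel))
    samples <- samples$samples[, channel]
  }
  r <- find_runs(samples, cutoff, area_mode)
  tibble(start_idx = as.integer(r[, 1]), end_idx = as.integer(r[, 2]),
         length = as.integer(r[, 2] - r[, 1]), area = r[, 3],
         max_intensity = r[, 4])
}

# maximal runs strictly above cutoff; matrix with columns
# start (0-based), end (half-open), area, max
find_runs <- function(samples, cutoff, area_mode = "raw-sum") {
  above <- !is.na(samples) & samples > cutoff
  if (!any(above)) return(matrix(numeric(), 0, 4))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  out <- matrix(0, length(idx), 4)
  for (k in seq_along(idx)) {
    v <- samples[starts[idx[k]]:ends[idx[k]]]
    out[k, ] <- c(starts[idx[k]] - 1L, ends[idx[k]],
                  if (area_mode == "above-cutoff") sum(v - cutoff) else sum(v),
                  max(v))
  }
  out
}

# run containing (or nearest to) the profile midpoint; NULL row index if none
select_vesicle_peak <- function(runs, length_px) {
  if (nrow(runs) == 0) return(NULL)
  mid <- (length_px - 1) / 2
  contains <- runs[, 1] <= mid & mid < runs[, 2]
  if (any(contains)) return(which(contains)[1])
  d <- pmax(runs[, 1] - mid, mid - (runs[, 2] - 1), 0)
  which.min(d)
}

# marker run with maximal index-support overlap with the vesicle peak;
# ties broken by larger area then leftmost
select_marker_peak <- function(runs, v_start, v_end) {
  if (nrow(runs) == 0) return(NULL)
  ov <- pmax(0, pmin(runs[, 2], v_end) - pmax(runs[, 1], v_start))
  best <- which(ov == max(ov))
  if (length(best) > 1) best <- best[which.max(runs[best, 3])]
  best[1]
}

# numeric-core classification; returns a named vector (NA where absent)
classify_core <- function(vesicle_samples, marker_samples, cutoff,
                          overlap_fraction_threshold, area_mode = "raw-sum",
                          overlap_mode = "min-curve") {
  L <- length(vesicle_samples)
  vr <- find_runs(vesicle_samples, cutoff, area_mode)
  mr <- find_runs(marker_samples, cutoff, area_mode)
  out <- c(is_positive = 0, overlap_share = 0, overlap_area = 0,
           v_start = NA_real_, v_end = NA_real_, v_area = NA_real_,
           m_start = NA_real_, m_end = NA_real_, m_area = NA_real_)
  iv <- select_vesicle_peak(vr, L)
  if (is.null(iv)) {
    if (nrow(mr) > 0) {
      im <- which.max(mr[, 3])
      out[c("m_start", "m_end", "m_area")] <- mr[im, 1:3]
    }
    return(out)
  }
  out[c("v_start", "v_end", "v_area")] <- vr[iv, 1:3]
  im <- select_marker_peak(mr, vr[iv, 1], vr[iv, 2])
  if (is.null(im)) return(out)
  out[c("m_start", "m_end", "m_area")] <- mr[im, 1:3]
  s <- max(vr[iv, 1], mr[im, 1])
  e <- min(vr[iv, 2], mr[im, 2])
  overlap_area <- if (e > s) {
    ks <- (s + 1):e  # back to 1-based vector indices
    if (overlap_mode == "support-length") {
      e - s
    } else if (area_mode == "above-cutoff") {
      sum(pmin(vesicle_samples[ks], marker_samples[ks]) - cutoff)
    } else {
      sum(pmin(vesicle_samples[ks], marker_samples[ks]))
    }
  } else 0
  marker_area <- if (overlap_mode == "support-length") {
    mr[im, 2] - mr[im, 1]
  } else mr[im, 3]
  out["overlap_area"] <- overlap_area
  out["overlap_share"] <- overlap_area / marker_area
  out["is_positive"] <- as.numeric(
    overlap_area > overlap_fraction_threshold * marker_area)
  out
}

#' Classify a vesicle as marker-positive from two profile channels
#'
#' Applies the peak-overlap rule: the vesicle peak is the supra-cutoff run
#' containing (or nearest to) the profile midpoint; the marker peak is the
#' marker-channel run with maximal support overlap with it; the overlap area
#' is the sum of `min(vesicle, marker)` over the intersection of the two
#' runs' index ranges; the vesicle is positive when the overlap area exceeds
#' `overlap_fraction_threshold` times the marker peak area. Absent vesicle
#' or marker peak gives a negative call with `overlap_share = 0`.
#'
#' @param vesicle_samples,marker_samples Equal-length numeric vectors of
#'   8-bit intensities sampled on the same line geometry, or a
#'   `line_profile` plus two channel names (see [extract_line_profile()]).
#' @param config A [profile_config()].
#' @return A one-row tibble: `is_positive`, `overlap_share`, `overlap_area`,
#'   vesicle/marker peak bounds and areas (`NA` when absent).
#' @export
classify_marker_positive <- function(vesicle_samples, marker_samples,
                                     config = profile_config()) {
  if (inherits(vesicle_samples, "line_profile")) {
    prof <- vesicle_samples
    stopifnot(is.character(marker_samples), length(marker_samples) == 2)
    vesicle_samples <- prof$samples[, marker_samples[1]]
    marker_samples <- prof$samples[, marker_samples[2]]
  }
  if (length(vesicle_samples) != length(marker_samples)) {
    abort("Profiles must share the same geometry (equal lengths).",
          class = "vesicoloc_contract_error")
  }
  cc <- classify_core(vesicle_samples, marker_samples, config$cutoff,
                      config$overlap_fraction_threshold, config$area_mode,
                      config$overlap_mode)
  tibble(
    is_positive = cc[["is_positive"]] > 0,
    overlap_share = cc[["overlap_share"]],
    overlap_area = cc[["overlap_area"]],
    vesicle_peak_start = as.integer(cc[["v_start"]]),
    vesicle_peak_end = as.integer(cc[["v_end"]]),
    vesicle_peak_area = cc[["v_area"]],
    marker_peak_start = as.integer(cc[["m_start"]]),
    marker_peak_end = as.integer(cc[["m_end"]]),
    marker_peak_area = cc[["m_area"]]
  )
}

#' Percentage of marker-positive vesicles
#'
#' @param calls Tibble of colocalization calls with an `is_positive` column.
#' @return `100 * n_positive / n_calls`; `NA` (missing, not 0) for an empty
#'   set of calls.
#' @export
percent_marker_positive <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) return(NA_real_)
  100 * mean(calls$is_positive)
}

#' Quantify reporter intensity on a vesicle from a profile
#'
#' The same line-profile procedure used for marker classification, applied
#' to a reporter channel (e.g. a phosphoinositide biosensor): returns the
#' reporter-channel peak area overlapping the vesicle peak (0 if no
#' reporter peak overlaps) and the reporter peak maximum.
#'
#' @param vesicle_samples,reporter_samples Equal-length 8-bit sample
#'   vectors on the same line, or a `line_profile` plus two channel names.
#' @param config A [profile_config()].
#' @return One-row tibble: `area`, `peak_max`.
#' @export
quantify_profile_intensity <- function(vesicle_samples, reporter_samples,
                                       config = profile_config()) {
  if (inherits(vesicle_samples, "line_profile")) {
    prof <- vesicle_samples
    stopifnot(is.character(reporter_samples), length(reporter_samples) == 2)
    vesicle_samples <- prof$samples[, reporter_samples[1]]
    reporter_samples <- prof$samples[, reporter_samples[2]]
  }
  if (length(vesicle_samples) != length(reporter_samples)) {
    abort("Profiles must share the same geometry (equal lengths).",
          class = "vesicoloc_contract_error")
  }
  L <- length(vesicle_samples)
  vr <- find_runs(vesicle_samples, config$cutoff, config$area_mode)
  rr <- find_runs(reporter_samples, config$cutoff, config$area_mode)
  iv <- select_vesicle_peak(vr, L)
  if (is.null(iv) || nrow(rr) == 0) return(tibble(area = 0, peak_max = NA_real_))
  ir <- select_marker_peak(rr, vr[iv, 1], vr[iv, 2])
  s <- max(vr[iv, 1], rr[ir, 1])
  e <- min(vr[iv, 2], rr[ir, 2])
  if (e <= s) return(tibble(area = 0, peak_max = rr[ir, 4]))
  ks <- (s + 1):e
  area <- if (config$area_mode == "above-cutoff") {
    sum(reporter_samples[ks] - config$cutoff)
  } else sum(reporter_samples[ks])
  tibble(area = area, peak_max = rr[ir, 4])
}

#' Score every detected vesicle on a stack
#'
#' For each detection, draws a line profile across the vesicle (direction
#' per `config$direction_mode`), and classifies it against the marker
#' channel.
#'
#' @param detections Tibble with `x`, `y` columns (0-based), e.g. from
#'   [detect_spots()].
#' @param stack8 8-bit [image_stack()].
#' @param vesicle_channel,marker_channel Channel names or indices.
#' @param config A [profile_config()].
#' @param reference `c(x, y)` used by `direction_mode = "toward-reference"`.
#' @param z z-plane.
#' @return `detections` with a `vesicle_id` column and the call columns of
#'   [classify_marker_positive()] appended, one row per detection.
#' @export
score_vesicles <- function(detections, stack8, vesicle_channel,
                           marker_channel, config = profile_config(),
                           reference = NULL, z = 1) {
  stopifnot(inherits(stack8, "image_stack"))
  if (!identical(stack8$bit_depth, 8L)) {
    abort("Profile scoring operates on the 8-bit converted stack.",
          class = "vesicoloc_contract_error")
  }
  vplane <- get_plane(stack8, vesicle_channel, z)
  mplane <- get_plane(stack8, marker_channel, z)
  calls <- map(seq_len(nrow(detections)), function(i) {
    anchor <- c(detections$x[i], detections$y[i])
    dir <- switch(config$direction_mode,
      "principal-axis" = principal_axis_direction(vplane, anchor[1], anchor[2]),
      "toward-marker" = local_max_direction(mplane, anchor, radius = 4) %||%
        principal_axis_direction(vplane, anchor[1], anchor[2]),
      "toward-reference" = {
        stopifnot(!is.null(reference))
        reference - anchor
      },
      "fixed-angle" = c(cos(config$fixed_angle), sin(config$fixed_angle)))
    prof <- extract_line_profile(stack8, anchor, dir, config$length_px, z)
    classify_marker_positive(
      prof$samples[, channel_index(stack8, vesicle_channel)],
      prof$samples[, channel_index(stack8, marker_channel)],
      config)
  })
  dplyr::bind_cols(
    mutate(detections, vesicle_id = dplyr::row_number(), .before = 1),
    list_rbind(calls))
}

# direction from anchor to the brightest pixel in a small window, or NULL
# when the maximum sits on the anchor itself
local_max_direction <- function(plane, anchor, radius = 4) {
  h <- nrow(plane); w <- ncol(plane)
  cs <- max(0, round(anchor[1]) - radius):min(w - 1, round(anchor[1]) + radius)
  rs <- max(0, round(anchor[2]) - radius):min(h - 1, round(anchor[2]) + radius)
  patch <- plane[rs + 1, cs + 1, drop = FALSE]
  best <- which(patch == max(patch), arr.ind = TRUE)[1, ]
  v <- c(cs[best[2]], rs[best[1]]) - anchor
  if (sqrt(sum(v^2)) < 1e-9) NULL else v
}
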