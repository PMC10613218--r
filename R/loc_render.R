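#' Rendering configuration for 3D localization data
#'
#' Controls the post-processing of single-molecule localization tables
#' (x/y/z in nm): coordinate scaling for pseudo-atom XYZ export, Gaussian
#' density-volume construction, and dust removal.
#'
#' The legacy integer divisor 15 is the default `scale_factor` (the nm per
#' output unit is recorded in the XYZ comment line so downstream tools can
#' recover provenance); `nm_per_unit = 13.46` matches renderers that assume
#' 13.46 nm per output unit and can be set independently of the divisor.
#'
#' @param scale_factor Coordinate divisor applied on export (output units =
#'   nm / `scale_factor`).
#' @param resolution Density kernel resolution parameter, in output units.
#' @param sigma_factor Kernel width multiplier; Gaussian sd =
#'   `sigma_factor * resolution`. Typical range 1.5-2.
#' @param voxel_size_units Output grid spacing in output units; defaults to
#'   `resolution / 3`.
#' @param dust_radius_nm Isolation radius for dust removal: a localization
#'   with no neighbour within this distance is spurious (default 60 nm,
#'   i.e. 1.5 voxels of a 40 nm rendering grid).
#' @param nm_per_unit Physical interpretation of one output unit (nm).
#' @return A `render_config` object.
#' @export
render_config <- function(scale_factor = 15, resolution = 1.4,
                          sigma_factor = 1.5,
                          voxel_size_units = resolution / 3,
                          dust_radius_nm = 60, nm_per_unit = 13.46) {
  if (scale_factor <= 0 || resolution <= 0 || voxel_size_units <= 0 ||
      dust_radius_nm <= 0) {
    abort("All rendering parameters must be positive.",
          class = "vesicoloc_parameter_error")
  }
  if (sigma_factor < 1 || sigma_factor > 3) {
    abort("`sigma_factor` must lie in [1, 3].", class = "vesicoloc_parameter_error")
  }
  structure(list(scale_factor = scale_factor, resolution = resolution,
                 sigma_factor = sigma_factor,
                 voxel_size_units = voxel_size_units,
                 dust_radius_nm = dust_radius_nm, nm_per_unit = nm_per_unit),
            class = "render_config")
}

check_locs <- function(locs) {
  stopifnot(is.data.frame(locs))
  need <- c("x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(locs))) {
    abort("Localization tables need columns x_nm, y_nm, z_nm.",
          class = "vesicoloc_format_error")
  }
  if (nrow(locs) > 0 && !all(is.finite(as.matrix(locs[need])))) {
    abort("Localization coordinates must be finite.",
          class = "vesicoloc_format_error")
  }
  locs
}

#' Export localizations as uranium pseudo-atoms in XYZ format
#'
#' Writes the standard chemical XYZ format: first line the point count,
#' second line a provenance comment (scale factor and nm-per-unit), then
#' one `U x y z` line per localization with coordinates divided by
#' `scale_factor` and printed with 3 decimals.
#'
#' @param locs Tibble with `x_nm`, `y_nm`, `z_nm` (nonempty).
#' @param config A [render_config()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of XYZ lines (invisibly, when writing).
#' @export
export_xyz <- function(locs, config = render_config(), path = NULL) {
  check_locs(locs)
  if (nrow(locs) == 0) {
    abort("XYZ format requires at least one atom.", class = "vesicoloc_format_error")
  }
  s <- config$scale_factor
  lines <- c(
    sprintf("%d", nrow(locs)),
    sprintf("localizations scaled by 1/%g; 1 unit = %g nm", s, config$nm_per_unit),
    sprintf("U %.3f %.3f %.3f", locs$x_nm / s, locs$y_nm / s, locs$z_nm / s)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse an XYZ pseudo-atom file back to a localization table
#'
#' Inverse of [export_xyz()] up to the 3-decimal formatting precision.
#'
#' @param lines Character vector of XYZ lines, or a file path.
#' @param config The [render_config()] used on export (for the scale).
#' @return Tibble: `element`, `x_nm`, `y_nm`, `z_nm`.
#' @export
parse_xyz <- function(lines, config = render_config()) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  n <- as.integer(lines[1])
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  s <- config$scale_factor
  tibble(
    element = map_chr_(parts, 1),
    x_nm = as.numeric(map_chr_(parts, 2)) * s,
    y_nm = as.numeric(map_chr_(parts, 3)) * s,
    z_nm = as.numeric(map_chr_(parts, 4)) * s
  )
}

map_chr_ <- function(x, i) vapply(x, `[[`, character(1), i)

#' Gaussian density volume from localizations
#'
#' Sums an isotropic 3D Gaussian of sd `sigma_factor * resolution` (in
#' scaled output units), normalized to unit integral, over all
#' localizations, sampled on a regular voxel grid covering the point
#' bounding box plus a 4-sigma margin. The grid integral (sum times voxel
#' volume) therefore equals the point count up to the mass outside the
#' margin (< 1%).
#'
#' @param locs Tibble with `x_nm`, `y_nm`, `z_nm`.
#' @param config A [render_config()]; refuses grids with
#'   `voxel_size_units > sigma` (silently aliased).
#' @param bounds Optional list with `lo` and `hi` (length-3, scaled units)
#'   fixing the grid extent, e.g. to place several point sets on a common
#'   grid; defaults to the point bounding box plus a 4-sigma margin.
#' @return A 3D array (x, y, z voxel order) with attributes `origin`
#'   (scaled-unit coordinates of the first voxel center), `voxel_size`
#'   (scaled units) and `sigma`.
#' @export
density_map <- function(locs, config = render_config(), bounds = NULL) {
  check_locs(locs)
  if (nrow(locs) == 0) {
    abort("Cannot render an empty localization set.", class = "vesicoloc_format_error")
  }
  sigma <- config$sigma_factor * config$resolution
  vs <- config$voxel_size_units
  if (vs > sigma) {
    abort("voxel_size_units exceeds the kernel sigma; the grid would alias.",
          class = "vesicoloc_undersampling_error")
  }
  pts <- cbind(locs$x_nm, locs$y_nm, locs$z_nm) / config$scale_factor
  if (is.null(bounds)) {
    lo <- apply(pts, 2, min) - 4 * sigma
    hi <- apply(pts, 2, max) + 4 * sigma
  } else {
    lo <- bounds$lo; hi <- bounds$hi
  }
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k] + vs, by = vs))
  dims <- lengths(axes)
  vol <- array(0, dim = dims)
  norm <- (2 * pi * sigma^2)^(-3 / 2)
  for (p in seq_len(nrow(pts))) {
    gx <- exp(-(axes[[1]] - pts[p, 1])^2 / (2 * sigma^2))
    gy <- exp(-(axes[[2]] - pts[p, 2])^2 / (2 * sigma^2))
    gz <- exp(-(axes[[3]] - pts[p, 3])^2 / (2 * sigma^2))
    vol <- vol + norm * outer(outer(gx, gy), gz)
  }
  attr(vol, "origin") <- lo
  attr(vol, "voxel_size") <- vs
  attr(vol, "sigma") <- sigma
  vol
}

#' Remove isolated localizations (dust)
#'
#' A localization is kept iff at least one other localization lies within
#' `dust_radius_nm`. In the default `"one-pass"` mode the neighbourhood is
#' evaluated on the original set (idempotent by construction); the
#' `"iterative"` mode repeats the pass on the surviving set until a
#' fixpoint, which can erode chain-like arrangements further.
#'
#' @param locs Tibble with `x_nm`, `y_nm`, `z_nm`.
#' @param config A [render_config()].
#' @param mode `"one-pass"` or `"iterative"`.
#' @return The filtered tibble (a subset of `locs`; possibly empty).
#' @export
hide_dust <- function(locs, config = render_config(),
                      mode = c("one-pass", "iterative")) {
  check_locs(locs)
  mode <- match.arg(mode)
  if (nrow(locs) == 0) {
    abort("Cannot filter an empty localization set.", class = "vesicoloc_format_error")
  }
  keep_pass <- function(tab) {
    if (nrow(tab) < 2) return(rep(FALSE, nrow(tab)))
    d <- as.matrix(stats::dist(cbind(tab$x_nm, tab$y_nm, tab$z_nm)))
    diag(d) <- Inf
    apply(d, 1, min) < config$dust_radius_nm
  }
  out <- locs[keep_pass(locs), , drop = FALSE]
  if (mode == "iterative") {
    repeat {
      keep <- keep_pass(out)
      if (all(keep)) break
      out <- out[keep, , drop = FALSE]
      if (nrow(out) == 0) break
    }
  }
  out
}
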