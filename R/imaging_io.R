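#' Multi-channel image stacks
#'
#' An `image_stack` holds pixel data indexed `(channel, z, y, x)` together
#' with the physical pixel size, the bit depth and channel labels. It is the
#' substrate of all 2D quantification in the package. Pixel coordinates used
#' throughout are 0-based and refer to pixel centers: `x` runs along columns,
#' `y` along rows.
#'
#' @param pixels Numeric array. Accepted shapes: `(y, x)` (one channel, one
#'   plane), `(channel, y, x)`, or `(channel, z, y, x)`.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param bit_depth One of `8`, `12`, `16` or `"float"`.
#' @param channel_names Character vector of channel labels, e.g.
#'   `c("CD63", "Exo84", "CoxIV", "DAPI")`. Defaults to `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size_um = 0.1, bit_depth = 16,
                        channel_names = NULL) {
  if (!is.array(pixels) && is.matrix(pixels)) pixels <- as.array(pixels)
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || nd < 2 || nd > 4) {
    abort("`pixels` must be a 2D, 3D or 4D array.", class = "vesicoloc_dimension_error")
  }
  if (nd == 2) dim(pixels) <- c(1L, 1L, dim(pixels))
  if (nd == 3) dim(pixels) <- c(dim(pixels)[1L], 1L, dim(pixels)[2:3])
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.", class = "vesicoloc_parameter_error")
  }
  bit_depth <- if (identical(bit_depth, "float")) "float" else as.integer(bit_depth)
  if (!identical(bit_depth, "float") && !bit_depth %in% c(8L, 12L, 16L)) {
    abort("`bit_depth` must be 8, 12, 16 or \"float\".", class = "vesicoloc_parameter_error")
  }
  nc <- dim(pixels)[1L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    abort("`channel_names` length must equal the number of channels.",
          class = "vesicoloc_dimension_error")
  }
  if (identical(bit_depth, 8L) && (min(pixels) < 0 || max(pixels) > 255)) {
    abort("8-bit stacks must contain only values in [0, 255].",
          class = "vesicoloc_parameter_error")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         bit_depth = bit_depth, channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d z-plane(s), %d x %d px, %s-bit, %.4g um/px\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
              as.character(x$bit_depth), x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_channels <- function(stack) dim(stack$pixels)[1L]
n_planes <- function(stack) dim(stack$pixels)[2L]

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
  } else {
    ch <- match(channel, stack$channel_names)
  }
  if (is.na(ch) || ch < 1L || ch > n_channels(stack)) {
    abort(sprintf("Unknown channel: %s", as.character(channel)),
          class = "vesicoloc_parameter_error")
  }
  ch
}

#' Extract a single 2D plane
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param z 1-based z-plane index.
#' @return A `(y, x)` matrix.
#' @export
get_plane <- function(stack, channel = 1, z = 1) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- channel_index(stack, channel)
  if (z < 1 || z > n_planes(stack)) {
    abort("z-plane out of range.", class = "vesicoloc_dimension_error")
  }
  stack$pixels[ch, z, , , drop = TRUE]
}

#' Read a TIFF file into an image stack
#'
#' Reads plain or multi-page (ImageJ-style) TIFFs. The `layout` string names
#' the meaning of the file's dimensions: `"yx"` for a single plane, `"cyx"`
#' for pages-as-channels, `"zyx"` for pages-as-z, and `"zcyx"`/`"czyx"` for
#' interleaved stacks (first letter = slowest-varying page index; `"zcyx"`
#' means channel cycles fastest, the usual ImageJ hyperstack order).
#'
#' @param path TIFF file path.
#' @param layout Axis-order descriptor (see Details).
#' @param n_channels Number of channels, required for 4D layouts.
#' @param pixel_size_um,bit_depth,channel_names Passed to [image_stack()].
#'   `bit_depth` defaults to the file's sample depth.
#' @return An [image_stack()] with axes `(channel, z, y, x)`; a missing z
#'   axis becomes a singleton.
#' @export
read_stack <- function(path, layout = "cyx", n_channels = NULL,
                       pixel_size_um = 0.1, bit_depth = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "vesicoloc_format_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(sprintf("Not a readable TIFF: %s", path),
                            class = "vesicoloc_format_error", parent = e)
                    })
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # collapse RGB grayscale
  })
  np <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  if (is.null(bit_depth)) bit_depth <- if (max(unlist(pages)) > 255) 16L else 8L

  layout <- tolower(layout)
  if (!layout %in% c("yx", "cyx", "zyx", "zcyx", "czyx")) {
    abort(sprintf("Unknown layout: %s", layout), class = "vesicoloc_dimension_error")
  }
  if (layout == "yx" && np != 1L) {
    abort("layout \"yx\" but file has multiple pages.", class = "vesicoloc_dimension_error")
  }
  if (layout %in% c("zcyx", "czyx")) {
    if (is.null(n_channels)) {
      abort("`n_channels` is required for 4D layouts.", class = "vesicoloc_dimension_error")
    }
    if (np %% n_channels != 0L) {
      abort("Page count is not a multiple of `n_channels`.",
            class = "vesicoloc_dimension_error")
    }
    nz <- np %/% n_channels
    arr <- array(0, dim = c(n_channels, nz, h, w))
    for (i in seq_len(np)) {
      if (layout == "zcyx") {            # channel fastest
        ch <- (i - 1L) %% n_channels + 1L; z <- (i - 1L) %/% n_channels + 1L
      } else {                            # z fastest
        z <- (i - 1L) %% nz + 1L; ch <- (i - 1L) %/% nz + 1L
      }
      arr[ch, z, , ] <- pages[[i]]
    }
  } else if (layout == "zyx") {
    arr <- array(0, dim = c(1L, np, h, w))
    for (i in seq_len(np)) arr[1L, i, , ] <- pages[[i]]
  } else {                                # yx or cyx
    arr <- array(0, dim = c(np, 1L, h, w))
    for (i in seq_len(np)) arr[i, 1L, , ] <- pages[[i]]
  }
  image_stack(arr, pixel_size_um = pixel_size_um, bit_depth = bit_depth,
              channel_names = channel_names)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written in `zcyx` order (channel cycling fastest within each
#' z-plane), the order [read_stack()] expects for that layout. 8- and 16-bit
#' round trips are bit-exact.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  bits <- if (identical(stack$bit_depth, "float")) 32L else
    if (stack$bit_depth == 8L) 8L else 16L
  maxval <- if (bits == 32L) 1 else 2^bits - 1
  pages <- list()
  for (z in seq_len(n_planes(stack))) {
    for (ch in seq_len(n_channels(stack))) {
      p <- stack$pixels[ch, z, , , drop = TRUE]
      pages[[length(pages) + 1L]] <- if (bits == 32L) p else p / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Display range for 8-bit conversion
#'
#' The fixed intensity window mapped onto \[0, 255\]. The same range is meant
#' to be reused across every image of a condition set, so that conversions
#' are comparable ("same settings").
#'
#' @param low,high Window bounds; `high > low`.
#' @return A `display_range` object.
#' @export
display_range <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1 ||
      length(high) != 1 || !(high > low)) {
    abort("`high` must be strictly greater than `low`.",
          class = "vesicoloc_parameter_error")
  }
  structure(list(low = as.numeric(low), high = as.numeric(high)),
            class = "display_range")
}

#' Per-channel display ranges from a reference image
#'
#' Computes each channel's `(min, max)` over the whole stack. Used on the
#' first image of a batch, then frozen for the batch, mirroring an analysis
#' in which display settings are adjusted once and applied identically to
#' every condition.
#'
#' @param stack An [image_stack()].
#' @return Named list of [display_range()] objects, one per channel.
#' @export
auto_display_range <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  out <- lapply(seq_len(n_channels(stack)), function(ch) {
    v <- stack$pixels[ch, , , ]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) hi <- lo + 1  # flat channel: degenerate window widened by 1
    display_range(lo, hi)
  })
  setNames(out, stack$channel_names)
}

round_half_up <- function(x) floor(x + 0.5)

#' Convert a stack to 8-bit with a fixed linear display mapping
#'
#' Values at or below `low` map to 0, at or above `high` to 255, linearly in
#' between with round-half-up: `round(255 * (v - low) / (high - low))`.
#' Rounding convention matters downstream (peak areas are sums of 8-bit
#' values), so it is fixed here and tested.
#'
#' @param stack An [image_stack()].
#' @param ranges A single [display_range()] applied to all channels, or a
#'   list with one range per channel (named by channel or positional).
#' @return An 8-bit [image_stack()] of the same geometry.
#' @export
to_8bit <- function(stack, ranges) {
  stopifnot(inherits(stack, "image_stack"))
  nc <- n_channels(stack)
  if (inherits(ranges, "display_range")) ranges <- rep(list(ranges), nc)
  if (length(ranges) != nc) {
    abort("Need one display range per channel.", class = "vesicoloc_parameter_error")
  }
  if (!is.null(names(ranges)) && all(stack$channel_names %in% names(ranges))) {
    ranges <- ranges[stack$channel_names]
  }
  out <- stack$pixels
  for (ch in seq_len(nc)) {
    r <- ranges[[ch]]
    if (!inherits(r, "display_range")) r <- display_range(r[[1]], r[[2]])
    v <- stack$pixels[ch, , , ]
    scaled <- round_half_up(255 * (v - r$low) / (r$high - r$low))
    out[ch, , , ] <- pmin(255, pmax(0, scaled))
  }
  image_stack(out, pixel_size_um = stack$pixel_size_um, bit_depth = 8L,
              channel_names = stack$channel_names)
}
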