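# Independent reference implementations ("oracles") used to check the
# package's optimized paths. These deliberately use naive mechanics:
# shifted-sum convolution instead of FFT, index-set run logic instead of
# rle ranges, exhaustive pairwise suppression.

# reflective (symmetric, edge-included) index lookup, 1-based
reflect_index <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n + 1 - i, i)
  i
}

oracle_convolve <- function(image, kernel) {
  h <- nrow(image); w <- ncol(image)
  r <- (nrow(kernel) - 1) %/% 2
  out <- matrix(0, h, w)
  for (dy in -r:r) {
    ys <- reflect_index((1:h) + dy, h)
    for (dx in -r:r) {
      xs <- reflect_index((1:w) + dx, w)
      out <- out + kernel[dy + r + 1, dx + r + 1] * image[ys, xs]
    }
  }
  out
}

# exhaustive local-maxima spot detection on a response map
oracle_detect <- function(image, diameter_px, quality_threshold,
                          min_separation_px = diameter_px / 2) {
  resp <- oracle_convolve(image, vesicoloc:::log_kernel(diameter_px))
  h <- nrow(resp); w <- ncol(resp)
  hits <- NULL
  for (i in 1:h) for (j in 1:w) {
    if (resp[i, j] <= quality_threshold) next
    nb <- resp[max(1, i - 1):min(h, i + 1), max(1, j - 1):min(w, j + 1)]
    if (resp[i, j] >= max(nb)) hits <- rbind(hits, c(i, j, resp[i, j]))
  }
  if (is.null(hits)) {
    return(data.frame(x = numeric(), y = numeric(), quality = numeric()))
  }
  ord <- order(-hits[, 3], hits[, 1], hits[, 2])
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (a in seq_len(nrow(hits))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(hits))) {
      if (b <= a || !keep[b]) next
      if ((hits[a, 1] - hits[b, 1])^2 + (hits[a, 2] - hits[b, 2])^2 <
          min_separation_px^2) keep[b] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  data.frame(x = hits[, 2] - 1, y = hits[, 1] - 1, quality = hits[, 3])
}

# runs as index sets
oracle_runs <- function(v, cutoff) {
  out <- list(); cur <- integer()
  for (i in seq_along(v)) {
    if (!is.na(v[i]) && v[i] > cutoff) {
      cur <- c(cur, i)
    } else {
      if (length(cur)) out[[length(out) + 1]] <- cur
      cur <- integer()
    }
  }
  if (length(cur)) out[[length(out) + 1]] <- cur
  out
}

# brute-force sample-summation peak-overlap classification
oracle_classify <- function(ves, mar, cutoff = 100, thr = 0.5) {
  L <- length(ves)
  rv <- oracle_runs(ves, cutoff)
  rm_ <- oracle_runs(mar, cutoff)
  if (length(rv) == 0) return(list(pos = FALSE, share = 0))
  mid <- (L - 1) / 2
  dists <- vapply(rv, function(ix) {
    s <- min(ix) - 1; e <- max(ix)
    if (s <= mid && mid < e) 0 else max(s - mid, mid - (e - 1))
  }, numeric(1))
  vix <- rv[[which.min(dists)]]
  if (length(rm_) == 0) return(list(pos = FALSE, share = 0))
  ovl <- vapply(rm_, function(ix) length(intersect(ix, vix)), numeric(1))
  areas <- vapply(rm_, function(ix) sum(mar[ix]), numeric(1))
  best <- which(ovl == max(ovl))
  if (length(best) > 1) best <- best[which.max(areas[best])]
  mix <- rm_[[best[1]]]
  shared <- intersect(mix, vix)
  overlap <- sum(pmin(ves[shared], mar[shared]))
  marker_area <- sum(mar[mix])
  list(pos = overlap > thr * marker_area, share = overlap / marker_area)
}

# moment-based isotropic Gaussian sd estimate in a window around (x, y)
fit_spot_sigma <- function(plane, x, y, radius) {
  h <- nrow(plane); w <- ncol(plane)
  cs <- max(0, round(x) - radius):min(w - 1, round(x) + radius)
  rs <- max(0, round(y) - radius):min(h - 1, round(y) + radius)
  patch <- plane[rs + 1, cs + 1]
  wt <- pmax(patch - min(patch), 0)
  xs <- matrix(rep(cs, each = length(rs)), nrow = length(rs))
  ys <- matrix(rep(rs, times = length(cs)), nrow = length(rs))
  sw <- sum(wt)
  mx <- sum(wt * xs) / sw; my <- sum(wt * ys) / sw
  sqrt((sum(wt * (xs - mx)^2) + sum(wt * (ys - my)^2)) / (2 * sw))
}

# place isolated Gaussian spots on a blank canvas; returns image + truth
make_spot_image <- function(h, w, centers, sigma, amplitude,
                            noise_sd = 0) {
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    img <- vesicoloc:::add_gaussian_spot(img, centers[i, 1], centers[i, 2],
                                         sigma, amplitude[i])
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
  img
}

# well-separated random centers on a grid
random_centers <- function(n, h, w, margin, min_sep) {
  pts <- matrix(NA_real_, 0, 2)
  guard <- 0
  while (nrow(pts) < n && guard < 10000) {
    guard <- guard + 1
    cand <- c(runif(1, margin, w - 1 - margin), runif(1, margin, h - 1 - margin))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep^2) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}
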