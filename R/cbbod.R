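#' Local-complexity map of one optical section
#'
#' The per-pixel "complexity" statistic behind complexity-based bitmap object
#' detection: the population standard deviation of intensities in the
#' `(2r+1) x (2r+1)` window centered at each pixel, with reflect-padded
#' borders. In-focus DIC structure (shear rims, granular cell texture) has
#' high local variability; defocused regions and clean background do not, so
#' thresholding this map isolates the in-focus object regions of a section.
#'
#' @param slice 2D numeric matrix (one optical section).
#' @param radius window radius in px (>= 1).
#' @return A `complexity_map`: a numeric matrix of the same size with
#'   attributes `radius` and (if present on the input) `t`, `z`.
#' @export
complexity_map <- function(slice, radius = 2) {
  if (!is.matrix(slice) || !is.numeric(slice)) {
    abort("`slice` must be a 2D numeric matrix")
  }
  if (radius < 1) abort("`radius` must be >= 1")
  radius <- as.integer(radius)
  if (nrow(slice) < 2 * radius + 1 || ncol(slice) < 2 * radius + 1) {
    abort("slice smaller than the complexity window")
  }
  p <- pad_reflect(slice, radius)
  n <- (2 * radius + 1)^2
  nr <- nrow(slice); nc <- ncol(slice)
  s1 <- matrix(0, nr, nc)
  s2 <- matrix(0, nr, nc)
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      w <- p[(1 + radius + dy):(nr + radius + dy),
             (1 + radius + dx):(nc + radius + dx), drop = FALSE]
      s1 <- s1 + w
      s2 <- s2 + w * w
    }
  }
  v <- s2 / n - (s1 / n)^2
  v[v < 0] <- 0
  structure(sqrt(v), class = c("complexity_map", "matrix"),
            radius = radius,
            t = attr(slice, "t"), z = attr(slice, "z"))
}

#' Between-class-variance-maximizing threshold
#'
#' Otsu's criterion on a fixed-bin histogram of the supplied values: the
#' threshold (a bin edge) maximizing the between-class variance of the
#' two-class split.
#'
#' @param values numeric vector.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold value.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (!length(values)) return(0)
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(lo)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  h <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                nbins = n_bins)
  w <- cumsum(as.numeric(h))
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  m <- cumsum(as.numeric(h) * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mtot * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * w1[valid])
  # the criterion is flat across empty gaps between modes: take the middle
  # of the maximizing plateau so the threshold sits centered in the gap
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  edges[top[ceiling(length(top) / 2)] + 1]
}

#' Binarize a complexity map into labeled in-focus regions
#'
#' Thresholds the map, then cleans the mask with morphological closing, hole
#' filling and opening, removes components below a minimum area, and labels
#' the remainder.
#'
#' @param map a [complexity_map()] (or plain numeric matrix).
#' @param threshold `"auto"` (Otsu on the map's values) or a fixed
#'   nonnegative value.
#' @param closing_radius,opening_radius disc radii (px) for the closing and
#'   opening steps (0 disables either).
#' @param min_area minimum component area in px^2.
#' @param shrink final erosion radius (px); [detect_stack()] sets this to
#'   the complexity window radius to undo the window's known dilation of the
#'   high-variance support, so bitmap boundaries sit on the true object
#'   boundary.
#' @return A `slice_bitmap`: an integer label matrix (0 = background,
#'   components labeled 1..k) with attributes `threshold`, `min_area`, `t`,
#'   `z`.
#' @export
make_bitmap <- function(map, threshold = "auto",
                        closing_radius = 2, opening_radius = 1,
                        min_area = 50, shrink = 0) {
  stopifnot(is.matrix(map))
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(as.vector(map))
  } else {
    assert_scalar_num(threshold, "threshold", nonneg = TRUE)
  }
  m <- (map > threshold) * 1
  if (any(m > 0)) {
    if (closing_radius > 0) {
      m <- EBImage::closing(m, EBImage::makeBrush(2 * closing_radius + 1,
                                                  "disc"))
    }
    m <- EBImage::fillHull(m)
    if (opening_radius > 0) {
      m <- EBImage::opening(m, EBImage::makeBrush(2 * opening_radius + 1,
                                                  "disc"))
    }
    if (shrink > 0) {
      m <- EBImage::erode(m, EBImage::makeBrush(2 * shrink + 1, "disc"))
    }
  }
  lab <- EBImage::bwlabel(m)
  lab <- as.matrix(lab)
  if (max(lab) > 0 && min_area > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  structure(matrix(as.integer(lab), nrow(map), ncol(map)),
            class = c("slice_bitmap", "matrix"),
            threshold = threshold, min_area = min_area,
            t = attr(map, "t"), z = attr(map, "z"))
}

#' Detect in-focus regions in every slice of a calibrated stack
#'
#' Applies [complexity_map()] and [make_bitmap()] to each optical section of
#' each timepoint. With `threshold = "auto"` the threshold is chosen per
#' timepoint by Otsu's criterion pooled over all of that timepoint's slices,
#' floored at `floor_factor` times the median pooled complexity; the floor
#' keeps object-free stacks (whose complexity histogram is unimodal noise)
#' from being split down the middle.
#'
#' @param stack a [calibrated_stack()].
#' @param radius complexity window radius, px.
#' @param threshold `"auto"` or a fixed value (see [make_bitmap()]).
#' @param floor_factor auto-threshold floor, in multiples of the median
#'   pooled complexity.
#' @param closing_radius,opening_radius,min_area passed to [make_bitmap()].
#' @return A `bitmap_series`: list with `bitmaps` (list over timepoints of
#'   lists over z of `slice_bitmap`s), `dim`, and the stack's calibration.
#' @export
detect_stack <- function(stack, radius = 2, threshold = "auto",
                         floor_factor = 4,
                         closing_radius = 2, opening_radius = 1,
                         min_area = 50) {
  if (!inherits(stack, "calibrated_stack")) {
    abort("`stack` must be a calibrated_stack (calibration is required)")
  }
  d <- dim(stack$data)
  nt <- d[4]; nz <- d[3]
  out <- vector("list", nt)
  for (ti in seq_len(nt)) {
    maps <- vector("list", nz)
    for (k in seq_len(nz)) {
      maps[[k]] <- complexity_map(stack$data[, , k, ti], radius = radius)
    }
    thr <- threshold
    if (identical(threshold, "auto")) {
      pooled <- unlist(lapply(maps, as.vector), use.names = FALSE)
      thr <- max(otsu_threshold(pooled), floor_factor * median(pooled))
    }
    bms <- vector("list", nz)
    for (k in seq_len(nz)) {
      bm <- make_bitmap(maps[[k]], threshold = thr,
                        closing_radius = closing_radius,
                        opening_radius = opening_radius,
                        min_area = min_area, shrink = radius)
      attr(bm, "t") <- ti
      attr(bm, "z") <- k
      bms[[k]] <- bm
    }
    out[[ti]] <- bms
  }
  structure(list(bitmaps = out, dim = d,
                 pixel_size = stack$pixel_size, z_step = stack$z_step,
                 t_step = stack$t_step, times = stack$times),
            class = "bitmap_series")
}
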