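#' Construct a closed outline polygon
#'
#' Represents one manually traced closed perimeter on one optical section.
#'
#' @param xy n x 2 numeric matrix of vertices (x, y in um), not repeated at
#'   the end; >= 3 vertices, no consecutive duplicates.
#' @param t,z timepoint index and slice index.
#' @param object object label the outline belongs to.
#' @return An `outline_polygon` (matrix with attributes).
#' @export
outline_polygon <- function(xy, t = 1L, z = 1L, object = 1L) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, is.numeric(xy))
  if (nrow(xy) >= 2 &&
      isTRUE(all.equal(xy[1, ], xy[nrow(xy), ], tolerance = 1e-12))) {
    xy <- xy[-nrow(xy), , drop = FALSE]   # drop explicit closure
  }
  if (nrow(xy) < 3) abort("an outline needs >= 3 distinct vertices")
  d <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2))
  if (any(d[-length(d)] == 0)) abort("consecutive duplicate vertices")
  structure(xy, class = c("outline_polygon", "matrix"),
            t = as.integer(t), z = as.integer(z),
            object = as.integer(object))
}

poly_perimeter <- function(xy) {
  nxt <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  sum(sqrt(rowSums((nxt - xy)^2)))
}

#' Resample a closed outline at (approximately) equal arc-length spacing
#'
#' Replaces the traced vertices by points spaced equally along the polygon's
#' perimeter, connected by straight lines; orientation is preserved.
#'
#' @param poly an [outline_polygon()].
#' @param spacing target spacing in um; must satisfy
#'   `0 < spacing < perimeter / 3`.
#' @return An [outline_polygon()] with `round(perimeter / spacing)` vertices.
#' @export
resample_outline <- function(poly, spacing = 2) {
  stopifnot(inherits(poly, "outline_polygon"))
  assert_scalar_num(spacing, "spacing", positive = TRUE)
  xy <- unclass(poly)
  attributes(xy) <- list(dim = dim(xy))
  per <- poly_perimeter(xy)
  if (spacing >= per / 3) {
    abort("`spacing` too large: fewer than 3 output points")
  }
  n_out <- max(3L, as.integer(round(per / spacing)))
  # cumulative arc length over the closed loop
  pts <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  s_target <- (seq_len(n_out) - 1) * per / n_out
  out <- matrix(0, n_out, 2)
  j <- 1L
  for (i in seq_len(n_out)) {
    s <- s_target[i]
    while (cum[j + 1] < s && j < length(seg)) j <- j + 1L
    f <- if (seg[j] > 0) (s - cum[j]) / seg[j] else 0
    out[i, ] <- pts[j, ] + f * (pts[j + 1, ] - pts[j, ])
  }
  outline_polygon(out, t = attr(poly, "t"), z = attr(poly, "z"),
                  object = attr(poly, "object"))
}

# beta-spline (bias/tension) segment basis at parameter u in [0, 1):
# weights for control points (P[i-1], P[i], P[i+1], P[i+2]).
# With beta1 = 1, beta2 = 0 this is the uniform cubic B-spline basis; the
# four weights always form a partition of unity (affine invariance).
beta_basis <- function(u, beta1, beta2) {
  delta <- beta2 + 2 * beta1^3 + 4 * beta1^2 + 4 * beta1 + 2
  b0 <- 2 * beta1^3 * (1 - u)^3 / delta
  b1 <- (2 * beta1^3 * u * (u^2 - 3 * u + 3) +
           2 * beta1^2 * (u^3 - 3 * u^2 + 2) +
           2 * beta1 * (u^3 - 3 * u + 2) +
           beta2 * (2 * u^3 - 3 * u^2 + 1)) / delta
  b3 <- 2 * u^3 / delta
  b2 <- 1 - b0 - b1 - b3
  cbind(b0, b1, b2, b3)
}

#' Smooth a closed outline with a beta spline
#'
#' Fits the closed periodic beta spline (bias `beta1`, tension `beta2`) to the
#' outline's vertices as control points and samples it densely. With
#' `beta1 = 1, beta2 = 0` the curve is the uniform periodic cubic B-spline;
#' raising `beta2` pulls the curve toward the control polygon.
#'
#' @param poly an [outline_polygon()] with >= 4 vertices.
#' @param beta1 bias parameter (> 0; default 1).
#' @param beta2 tension parameter (>= 0; default 0).
#' @param samples_per_segment samples per control-polygon edge.
#' @return A `spline_curve`: an (n*samples+1) x 2 matrix of points, closed
#'   (first row repeated at the end), with attributes `beta1`, `beta2`,
#'   `control`, `t`, `z`, `object`.
#' @export
beta_spline <- function(poly, beta1 = 1, beta2 = 0,
                        samples_per_segment = 10) {
  stopifnot(inherits(poly, "outline_polygon"))
  if (!is.finite(beta1) || !is.finite(beta2)) {
    abort("spline parameters must be finite")
  }
  if (beta1 <= 0 || beta2 < 0) abort("need beta1 > 0 and beta2 >= 0")
  xy <- unclass(poly)
  attributes(xy) <- list(dim = dim(xy))
  n <- nrow(xy)
  if (n < 4) abort("beta_spline needs >= 4 control points")
  u <- (seq_len(samples_per_segment) - 1) / samples_per_segment
  w <- beta_basis(u, beta1, beta2)
  out <- matrix(0, n * samples_per_segment, 2)
  for (i in seq_len(n)) {
    idx <- c((i - 2) %% n + 1, i, i %% n + 1, (i + 1) %% n + 1)
    seg <- w %*% xy[idx, , drop = FALSE]
    out[((i - 1) * samples_per_segment + 1):(i * samples_per_segment), ] <-
      seg
  }
  out <- rbind(out, out[1, , drop = FALSE])
  structure(out, class = c("spline_curve", "matrix"),
            beta1 = beta1, beta2 = beta2, control = xy,
            t = attr(poly, "t"), z = attr(poly, "z"),
            object = attr(poly, "object"))
}

#' Stack one object's smoothed contours at one timepoint
#'
#' Orders the curves by slice and flags gaps (missing intermediate slices),
#' readying them for 3D surface reconstruction.
#'
#' @param curves list of [beta_spline()] curves (or outline polygons) sharing
#'   the same object label and timepoint, at distinct z indices.
#' @param z_step axial spacing in um between consecutive slice indices.
#' @return A `contour_stack`: list with `curves` (ordered by z), `z_um`,
#'   `z_index`, `gaps` (z indices of missing slices), `z_step`, `object`,
#'   `t`. Empty input gives an empty stack.
#' @export
stack_outlines <- function(curves, z_step = 10) {
  if (!length(curves)) {
    return(structure(list(curves = list(), z_um = numeric(),
                          z_index = integer(), gaps = integer(),
                          z_step = z_step, object = NA_integer_,
                          t = NA_integer_),
                     class = "contour_stack"))
  }
  zs <- vapply(curves, function(cv) as.integer(attr(cv, "z")), 1L)
  obj <- unique(vapply(curves, function(cv) as.integer(attr(cv, "object")),
                       1L))
  tt <- unique(vapply(curves, function(cv) as.integer(attr(cv, "t")), 1L))
  if (length(obj) > 1 || length(tt) > 1) {
    abort("curves must share one object label and one timepoint")
  }
  if (anyDuplicated(zs)) abort("duplicate z for the same object")
  o <- order(zs)
  zs <- zs[o]
  curves <- curves[o]
  full <- seq(min(zs), max(zs))
  gaps <- setdiff(full, zs)
  structure(list(curves = curves, z_um = (zs - 0.5) * z_step,
                 z_index = zs, gaps = gaps, z_step = z_step,
                 object = obj, t = tt),
            class = "contour_stack")
}

#' Read / write outline CSV files
#'
#' The outline interchange format is a plain CSV with columns
#' `t, z, object, vertex_index, x_um, y_um`; one row per traced vertex,
#' vertices ordered along the perimeter.
#'
#' @param path CSV file path.
#' @return `read_outlines()`: a named list of [outline_polygon()]s.
#' @export
read_outlines <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "z", "object", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    abort(sprintf("outline CSV must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  keys <- unique(df[c("t", "z", "object")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$t == keys$t[i] & df$z == keys$z[i] &
                df$object == keys$object[i], ]
    sub <- sub[order(sub$vertex_index), ]
    out[[sprintf("t%d_z%d_obj%d", keys$t[i], keys$z[i], keys$object[i])]] <-
      outline_polygon(cbind(sub$x_um, sub$y_um),
                      t = keys$t[i], z = keys$z[i], object = keys$object[i])
  }
  out
}

#' @param polys list of [outline_polygon()]s or `spline_curve`s.
#' @rdname read_outlines
#' @export
write_outlines <- function(polys, path) {
  rows <- lapply(polys, function(p) {
    xy <- unclass(p)
    attributes(xy) <- list(dim = dim(xy))
    tibble::tibble(t = attr(p, "t"), z = attr(p, "z"),
                   object = attr(p, "object"),
                   vertex_index = seq_len(nrow(xy)),
                   x_um = xy[, 1], y_um = xy[, 2])
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Open polyline for a manually drawn filopodium
#'
#' @param xy n x 2 matrix (>= 2 points), um.
#' @param anchor label of the object the filopodium is anchored to.
#' @param t,z timepoint and slice indices.
#' @return A `filopod_polyline`.
#' @export
filopod_polyline <- function(xy, anchor = 1L, t = 1L, z = 1L) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2)
  if (nrow(xy) < 2) abort("a filopod polyline needs >= 2 points")
  structure(xy, class = c("filopod_polyline", "matrix"),
            anchor = as.integer(anchor), t = as.integer(t),
            z = as.integer(z))
}

# even-odd scanline rasterization of a closed polygon onto a pixel grid;
# pixel (i, j) center is at ((j - 0.5) px + ox, (i - 0.5) px + oy)
rasterize_polygon <- function(xy, ny, nx, pixel_size, origin = c(0, 0)) {
  m <- matrix(FALSE, ny, nx)
  n <- nrow(xy)
  xs <- xy[, 1]; ys <- xy[, 2]
  xs2 <- xs[c(2:n, 1)]; ys2 <- ys[c(2:n, 1)]
  for (i in seq_len(ny)) {
    yc <- (i - 0.5) * pixel_size + origin[2]
    cross <- (ys <= yc & ys2 > yc) | (ys2 <= yc & ys > yc)
    if (!any(cross)) next
    xi <- xs[cross] + (yc - ys[cross]) / (ys2[cross] - ys[cross]) *
      (xs2[cross] - xs[cross])
    xi <- sort(xi)
    for (p in seq(1, length(xi) - 1, by = 2)) {
      jc <- which((seq_len(nx) - 0.5) * pixel_size + origin[1] > xi[p] &
                    (seq_len(nx) - 0.5) * pixel_size + origin[1] < xi[p + 1])
      m[i, jc] <- TRUE
    }
  }
  m
}

# does the closed polygon self-intersect? O(n^2) segment test (outlines are
# small); shared endpoints between adjacent segments don't count
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) -
      (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) -
      (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
      (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) -
      (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (seg_int(xy[i, ], xy[i %% n + 1, ], xy[j, ], xy[j %% n + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}
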