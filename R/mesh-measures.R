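#' Mesh measures: enclosed volume, surface area, centroid
#'
#' `mesh_volume()` is the absolute signed sum of origin tetrahedra over the
#' triangles (exact for watertight, consistently oriented meshes);
#' `mesh_area()` sums triangle areas; `mesh_centroid()` is the
#' volume-weighted centroid of the enclosed solid.
#'
#' @param mesh a [faceted_object()].
#' @return A scalar (um^3 or um^2) or length-3 numeric (um).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "faceted_object"))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(det6)) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname mesh_volume
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  ct <- (a + b + c) / 4            # origin-tet centroid, origin term is 0
  tot <- sum(det6)
  if (abs(tot) < 1e-12) abort("degenerate (zero-volume) mesh")
  colSums(ct * det6) / tot
}

#' Analytic test meshes
#'
#' `icosphere()` subdivides an icosahedron and projects to the sphere
#' (watertight, genus 0); `cube_mesh()` is an axis-aligned cube as 12
#' outward-oriented triangles. Both are used as analytic references for the
#' mesh measures.
#'
#' @param radius sphere radius, um.
#' @param subdivisions icosahedron subdivision level (4 gives 5120 faces).
#' @param center center, um.
#' @return A [faceted_object()].
#' @export
icosphere <- function(radius = 50, subdivisions = 4, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (q in seq_len(nrow(f))) {
      a <- f[q, 1]; b <- f[q, 2]; cc <- f[q, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  faceted_object(sweep(v * radius, 2, center, `+`), f,
                 generator = "analytic")
}

#' @param side cube edge length, um.
#' @rdname icosphere
#' @export
cube_mesh <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, `+`)
  # vertices ordered (x fastest): 1:(---) 2:(+--) 3:(-+-) 4:(++-)
  #                               5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -h, outward -z
    c(5, 6, 8), c(5, 8, 7),   # z = +h, outward +z
    c(1, 2, 6), c(1, 6, 5),   # y = -h, outward -y
    c(3, 7, 8), c(3, 8, 4),   # y = +h, outward +y
    c(1, 5, 7), c(1, 7, 3),   # x = -h, outward -x
    c(2, 4, 8), c(2, 8, 6))   # x = +h, outward +x
  faceted_object(v, f, generator = "analytic")
}

#' Export a faceted object
#'
#' `write_ply()` writes Stanford PLY (binary little-endian by default, or
#' ASCII); `write_obj()` writes Wavefront OBJ. One file per object per
#' timepoint; the conventional name is `t{tttt}_obj{label}.ply`.
#'
#' @param mesh a [faceted_object()].
#' @param path output file.
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", sprintf("format %s 1.0", fmt),
           sprintf("comment dic4d t%d obj%d (%s)", mesh$timepoint,
                   mesh$label, mesh$generator),
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4,
             endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
    writeLines(apply(mesh$faces - 1L, 1,
                     function(r) paste(c(3L, r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dic4d t%d obj%d (%s)", mesh$timepoint, mesh$label,
                     mesh$generator), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
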