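test_that("slice grouping separates disjoint objects and keeps slabs", {
  blank <- matrix(0L, 30, 30)
  d1 <- blank; d1[5:12, 5:12] <- 1L
  d2 <- blank; d2[20:27, 20:27] <- 1L
  # two disks in non-adjacent slices: two objects
  objs <- group_slices(list(d1, blank, d2), pixel_size = 2, z_step = 10)
  expect_length(objs, 2)
  # a single-slice component survives as a one-z-step slab
  objs1 <- group_slices(list(d1), pixel_size = 2, z_step = 10)
  mesh <- skeleton_climb(objs1[[1]])
  expect_true(is_watertight(mesh))
  expect_equal(mesh_volume(mesh), 64 * 2 * 2 * 10)
  expect_equal(diff(range(mesh$vertices[, 3])), 10)
  # empty and malformed inputs
  expect_length(group_slices(list(blank, blank), 2, 10), 0)
  expect_error(group_slices(list(d1, matrix(0L, 10, 10)), 2, 10),
               "shapes")
})

test_that("single-voxel extraction gives a closed unit cube", {
  vox <- voxel_object(1L, dim = c(1, 1, 1), voxel = c(10, 10, 10))
  for (mesh in list(unit_cell_surface(vox), skeleton_climb(vox))) {
    expect_true(is_watertight(mesh))
    expect_equal(euler_characteristic(mesh), 2)
    expect_lt(abs(mesh_volume(mesh) - 1000) / 1000, 0.15)
  }
})

test_that("voxelized sphere meshes recover the analytic volume", {
  vox <- voxel_sphere(50, c(2, 2, 10))
  analytic <- 4 / 3 * pi * 50^3
  oracle <- unit_cell_surface(vox)
  asc <- skeleton_climb(vox, block_size = 4)
  expect_lt(abs(mesh_volume(asc) - analytic) / analytic, 0.05)
  # adaptive route agrees with the unit-cell route and uses fewer facets
  expect_lt(abs(mesh_volume(asc) - mesh_volume(oracle)) /
              mesh_volume(oracle), 0.02)
  expect_lt(nrow(asc$faces), nrow(oracle$faces))
  for (mesh in list(oracle, asc)) {
    expect_true(is_watertight(mesh))
    expect_equal(euler_characteristic(mesh), 2)
  }
})

test_that("mesh volume matches voxel count times voxel volume", {
  vox <- voxel_sphere(30, c(2, 2, 10))
  vv <- length(vox$indices) * prod(vox$voxel)
  expect_lt(abs(mesh_volume(skeleton_climb(vox)) - vv) / vv, 0.05)
})

test_that("vertex smoothing is identity at 0 iterations and conserves volume", {
  vox <- voxel_sphere(30, c(2, 2, 10))
  mesh <- skeleton_climb(vox)
  expect_identical(smooth_mesh(mesh, 0), mesh)
  sm <- smooth_mesh(mesh, 10)
  expect_true(is_watertight(sm))
  expect_equal(euler_characteristic(sm), 2)
  expect_lt(abs(mesh_volume(sm) - mesh_volume(mesh)) / mesh_volume(mesh),
            0.03)
  # staircase aliasing shrinks: radial deviation from the best-fit sphere
  rad_dev <- function(m) {
    ctr <- mesh_centroid(m)
    r <- sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))
    max(abs(r - mean(r)))
  }
  expect_lt(rad_dev(sm), rad_dev(mesh))
  expect_error(smooth_mesh(faceted_object(mesh$vertices,
                                          mesh$faces[-1, ]), 1),
               "watertight")
})

test_that("mesh geometry is exactly rigid under origin translation", {
  vox <- voxel_sphere(20, c(2, 2, 10))
  vox2 <- vox
  vox2$origin <- c(100, -50, 30)
  m1 <- skeleton_climb(vox)
  m2 <- skeleton_climb(vox2)
  expect_identical(m1$faces, m2$faces)
  expect_equal(sweep(m2$vertices, 2, c(100, -50, 30)), m1$vertices)
  expect_equal(mesh_volume(m1), mesh_volume(m2), tolerance = 1e-6)
  expect_equal(mesh_area(m1), mesh_area(m2), tolerance = 1e-6)
})

test_that("anisotropy scales slab volumes linearly in z-step", {
  blank <- matrix(0L, 20, 20)
  d <- blank; d[5:15, 5:15] <- 1L
  v1 <- mesh_volume(skeleton_climb(
    group_slices(list(d, d), 2, 10)[[1]]))
  v2 <- mesh_volume(skeleton_climb(
    group_slices(list(d, d), 2, 30)[[1]]))
  expect_equal(v2 / v1, 3, tolerance = 1e-9)
})

test_that("contour stacks mesh into closed solids with expected volume", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- function(r, z) {
    p <- outline_polygon(cbind(r * cos(th) + 60, r * sin(th) + 60),
                         z = z)
    beta_spline(resample_outline(p, 2))
  }
  # cylinder: 3 equal circles at 10 um spacing
  stk <- stack_outlines(lapply(1:3, function(k) circ(50, k)), z_step = 10)
  mesh <- contours_to_mesh(stk, pixel_size = 2, smooth_iterations = 0)
  expect_true(is_watertight(mesh))
  cyl <- pi * 50^2 * 30
  expect_lt(abs(mesh_volume(mesh) - cyl) / cyl, 0.1)
  # single contour: watertight slab
  slab <- contours_to_mesh(stack_outlines(list(circ(30, 1)), z_step = 10),
                           pixel_size = 2, smooth_iterations = 0)
  expect_true(is_watertight(slab))
  expect_equal(diff(range(slab$vertices[, 3])), 10)
  # shrinking radii: between frustum-of-cone and cylinder bounds
  stk3 <- stack_outlines(list(circ(50, 1), circ(30, 2), circ(10, 3)),
                         z_step = 10)
  m3 <- contours_to_mesh(stk3, pixel_size = 2, smooth_iterations = 0)
  v <- mesh_volume(m3)
  expect_gt(v, pi * 30 / 3 * (50^2 + 50 * 10 + 10^2) * 0.9)
  expect_lt(v, pi * 50^2 * 30)
  # missing intermediate slices are interpolated
  stk_gap <- stack_outlines(list(circ(40, 1), circ(40, 3)), z_step = 10)
  expect_equal(stk_gap$gaps, 2)
  mg <- contours_to_mesh(stk_gap, pixel_size = 2, smooth_iterations = 0)
  expect_true(is_watertight(mg))
  expect_equal(diff(range(mg$vertices[, 3])), 30)
  # self-intersecting contours are rejected
  bow <- outline_polygon(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)),
                         z = 1)
  expect_error(
    contours_to_mesh(stack_outlines(list(bow), z_step = 10)),
    "self-intersecting")
})

test_that("meshes of detected phantom objects are watertight genus-0 solids", {
  res <- two_merge_run()$result
  for (ti in c(1, length(res$objects))) {
    for (ob in res$objects[[ti]]) {
      mesh <- skeleton_climb(ob)
      expect_true(is_watertight(mesh))
      expect_equal(euler_characteristic(mesh), 2)
    }
  }
})

test_that("PLY and OBJ exports carry all vertices and faces", {
  vox <- voxel_object(1L, dim = c(1, 1, 1), voxel = c(5, 5, 5))
  mesh <- skeleton_climb(vox)
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, ply)
  hdr <- readLines(ply, n = 10, warn = FALSE)
  expect_true(any(grepl("binary_little_endian", hdr)))
  expect_true(any(grepl(sprintf("element vertex %d", nrow(mesh$vertices)),
                        hdr)))
  obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
})
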