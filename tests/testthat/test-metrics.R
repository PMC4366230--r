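test_that("centroids of voxel and mesh objects agree with geometry", {
  vox <- voxel_object(1L, dim = c(1, 1, 1), voxel = c(20, 40, 60))
  expect_equal(centroid3d(vox), c(10, 20, 30))
  # two equal voxels differing only in z: centroid at the midpoint
  occ <- array(FALSE, c(1, 1, 2)); occ[1, 1, 1] <- occ[1, 1, 2] <- TRUE
  vox2 <- voxel_object(which(occ), dim(occ), c(2, 2, 10))
  expect_equal(centroid3d(vox2)[3], 10)
  # voxel and mesh centroids of a sphere agree within half a voxel
  sph <- voxel_sphere(30, c(2, 2, 10))
  expect_lt(max(abs(centroid3d(sph) -
                      centroid3d(skeleton_climb(sph)))), 5)
  expect_error(centroid3d(1:3), "voxel_object")
})

test_that("speed series follow centroid displacement per unit time", {
  still <- tibble::tibble(time_min = seq(0, 120, 30), x_um = 5, y_um = 5,
                          z_um = 5)
  expect_equal(mean_speed(still)$mean, 0)
  # 10 um in 30 min is 20 um/hr
  two <- tibble::tibble(time_min = c(0, 30), x_um = c(0, 10), y_um = 0,
                        z_um = 0)
  expect_equal(mean_speed(two)$speeds$speed_um_hr, 20)
  expect_error(mean_speed(two[1, ]), "2 timepoints")
  # merged-away rows are excluded from the series
  tr <- tibble::tibble(time_min = c(0, 30, 60), x_um = c(0, 10, 999),
                       y_um = 0, z_um = 0,
                       status = c("present", "present", "merged-away"))
  expect_length(mean_speed(tr)$speeds$speed_um_hr, 1)
  # speed is invariant to a constant spatial offset
  set.seed(41)
  wob <- tibble::tibble(time_min = seq(0, 300, 30),
                        x_um = cumsum(rnorm(11)),
                        y_um = cumsum(rnorm(11)),
                        z_um = cumsum(rnorm(11)))
  off <- dplyr::mutate(wob, x_um = x_um + 100, y_um = y_um - 40,
                       z_um = z_um + 7)
  expect_equal(mean_speed(wob)$speeds, mean_speed(off)$speeds)
})

test_that("mesh volume matches analytic solids", {
  expect_equal(volume3d(cube_mesh(1)), 1)
  sph <- icosphere(50, 4)
  expect_lt(abs(volume3d(sph) - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3),
            0.005)
  open_mesh <- faceted_object(cube_mesh(1)$vertices,
                              cube_mesh(1)$faces[-1, ])
  expect_error(volume3d(open_mesh), "watertight")
})

test_that("surface complexity is reciprocal sphericity", {
  expect_equal(surface_complexity(icosphere(50, 4)), 1, tolerance = 0.01)
  expect_equal(surface_complexity(cube_mesh(2)),
               6 / (pi^(1 / 3) * 6^(2 / 3)), tolerance = 1e-6)
  # a 3:1 prolate ellipsoid is rougher than the equal-volume sphere
  ell <- icosphere(1, 4)
  ell$vertices[, 3] <- ell$vertices[, 3] * 3
  expect_gt(surface_complexity(ell), surface_complexity(icosphere(1, 4)))
})

test_that("complexity respects the isoperimetric bound on phantom meshes", {
  run <- coalescence_run()$result
  expect_true(all(run$meshes$complexity >= 1 - 0.02))
})

test_that("uniform scaling cubes the volume and preserves complexity", {
  vox <- voxel_sphere(20, c(2, 2, 10))
  mesh <- skeleton_climb(vox)
  scaled <- mesh
  scaled$vertices <- mesh$vertices * 3
  expect_equal(volume3d(scaled) / volume3d(mesh), 27, tolerance = 1e-9)
  expect_equal(surface_complexity(scaled), surface_complexity(mesh),
               tolerance = 1e-6)
})

test_that("percent original aggregate number follows the corrected count", {
  grid <- function(n, times, status = "present") {
    tidyr::expand_grid(time_min = times, lineage_id = as.character(1:n)) |>
      dplyr::mutate(x_um = 50, y_um = 50, z_um = 50, status = status)
  }
  times <- seq(0, 120, 30)
  # no events: 100% throughout
  tr <- grid(10, times)
  for (t in times) expect_equal(percent_original(tr, t), 100)
  # 10 founders, one 2-way merge: 90% afterwards
  tr2 <- grid(10, times)
  tr2 <- tr2[!(tr2$lineage_id %in% c("1", "2") & tr2$time_min >= 60), ]
  merged <- tibble::tibble(time_min = times[times >= 60],
                           lineage_id = "1/2", x_um = 50, y_um = 50,
                           z_um = 50, status = "present")
  tr2 <- dplyr::bind_rows(tr2, merged)
  expect_equal(percent_original(tr2, 0), 100)
  expect_equal(percent_original(tr2, 90), 90)
  # 10 founders, 1 entry: 110% afterwards
  tr3 <- dplyr::bind_rows(
    grid(10, times),
    tibble::tibble(time_min = times[times >= 60], lineage_id = "11",
                   x_um = 95, y_um = 50, z_um = 50, status = "present"))
  expect_equal(percent_original(tr3, 120), 110)
  expect_error(percent_original(tr3[0, ], 0))
})

test_that("the metric series equals a brute-force per-track recomputation", {
  run <- two_merge_run()$result
  m <- run$metrics
  tr <- run$tracking$tracks
  for (t in m$time_min[c(2, 5, 9)]) {
    live <- tr[tr$time_min == t & tr$status == "present", ]
    expect_equal(m$n_aggregates[m$time_min == t], nrow(live))
    vols <- run$meshes$volume_um3[run$meshes$time_min == t]
    expect_equal(m$mean_volume_um3[m$time_min == t], mean(vols))
  }
})

test_that("metric signatures separate coalescing from static scenes", {
  st <- static_run()$result$metrics
  co <- coalescence_run()$result$metrics
  n <- nrow(st)
  # static: flat count, flat complexity, growing volume
  expect_true(all(st$n_aggregates == st$n_aggregates[1]))
  expect_lt(abs(mean(tail(st$mean_complexity, 5)) -
                  mean(head(st$mean_complexity, 5))), 0.15)
  expect_gt(st$mean_volume_um3[n], st$mean_volume_um3[1])
  # coalescing: count falls, volume and complexity rise
  expect_lt(co$n_aggregates[n], co$n_aggregates[1])
  expect_true(all(diff(co$n_aggregates) <= 0))
  expect_gt(co$mean_volume_um3[n], 2 * co$mean_volume_um3[1])
  expect_gt(mean(tail(co$mean_complexity, 5)),
            mean(head(co$mean_complexity, 5)))
  # count only decreases except at enter events (none here)
  expect_equal(co$pct_original[1], 100)
})

test_that("growing phantoms yield a monotone mean-volume series", {
  res <- static_run()$result
  v <- res$metrics$mean_volume_um3
  fit <- stats::lm(v ~ seq_along(v))
  expect_gt(stats::coef(fit)[2], 0)
})

test_that("metric series plot builds without error", {
  p <- autoplot(static_run()$result$metrics)
  expect_s3_class(p, "ggplot")
  q <- plot_track_path(dervish_track(seed = 2))
  expect_s3_class(q, "ggplot")
})
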