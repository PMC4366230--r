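make_vox <- function(center_px, r_px, dims = c(60, 60, 12),
                     voxel = c(2, 2, 10), label = 1L) {
  occ <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    dz <- (k - center_px[3]) * voxel[3] / voxel[1]
    d2 <- outer((seq_len(dims[1]) - center_px[2])^2,
                (seq_len(dims[2]) - center_px[1])^2, "+") + dz^2
    occ[, , k] <- d2 <= r_px^2
  }
  voxel_object(which(occ), dims, voxel, label = label)
}

test_that("slash-coded lineage ids merge with numeric founder order", {
  expect_equal(merge_ids(c("6", "7")), "6/7")
  expect_equal(merge_ids(c("6/7", "5")), "5/6/7")
  expect_equal(merge_ids(c("2", "10")), "2/10")
  expect_error(merge_ids("6"), ">= 2")
  expect_error(merge_ids(c("5/6", "6")), "overlapping")
})

test_that("a displaced object links one-to-one", {
  a <- list(make_vox(c(25, 25, 6), 8))
  b <- list(make_vox(c(27, 25, 6), 8))   # ~4 um shift
  lk <- link_frames(a, b)
  expect_equal(lk$type, "link")
  expect_equal(lk$a, 1); expect_equal(lk$b, 1)
  expect_error(link_frames(a, b, gate = -5), "gate")
})

test_that("greedy linking matches the exhaustive assignment oracle", {
  set.seed(31)
  for (rep in 1:4) {
    ctrs <- cbind(runif(3, 12, 48), runif(3, 12, 48), runif(3, 4, 8))
    while (min(dist(ctrs[, 1:2])) < 18) {
      ctrs <- cbind(runif(3, 12, 48), runif(3, 12, 48), runif(3, 4, 8))
    }
    shift <- matrix(runif(9, -2, 2), 3, 3)
    a <- lapply(1:3, function(i) make_vox(ctrs[i, ], 5))
    b <- lapply(1:3, function(i) make_vox(ctrs[i, ] + shift[i, ], 5))
    lk <- link_frames(a, b)
    links <- lk[lk$type == "link", ]
    expect_equal(nrow(links), 3)
    ca <- t(vapply(a, centroid3d, numeric(3)))
    cb <- t(vapply(b, centroid3d, numeric(3)))
    oracle <- bf_assignment(ca, cb)
    expect_equal(links$b[order(links$a)], oracle)
  }
})

test_that("two predecessors over one successor flag a candidate merge", {
  a <- list(make_vox(c(20, 25, 6), 7), make_vox(c(38, 25, 6), 7))
  b <- list(make_vox(c(29, 25, 6), 10))   # covers both
  lk <- link_frames(a, b)
  expect_true("candidate_merge" %in% lk$type)
  merges <- detect_coalescence(lk, a, b, tau = 0.3)
  expect_equal(nrow(merges), 1)
  expect_equal(merges$participants[[1]], c(1, 2))
  expect_error(detect_coalescence(lk, a, b, tau = 1.5), "tau")
})

test_that("a transient touch below the overlap threshold is not a merge", {
  a <- list(make_vox(c(20, 25, 6), 7), make_vox(c(40, 25, 6), 7))
  # successor barely clips the second predecessor
  b <- list(make_vox(c(22, 25, 6), 8))
  lk <- link_frames(a, b)
  merges <- detect_coalescence(lk, a, b, tau = 0.3)
  expect_equal(nrow(merges), 0)
})

test_that("coalescence volume guard rejects occlusion-like successors", {
  a <- list(make_vox(c(20, 25, 6), 8), make_vox(c(33, 25, 6), 8))
  b <- list(make_vox(c(26, 25, 6), 8))  # too small to be the fused body
  lk <- link_frames(a, b)
  expect_equal(nrow(detect_coalescence(lk, a, b)), 0)
})

test_that("edge classification separates entries, exits and anomalies", {
  mk_tracks <- function(rows) dplyr::bind_rows(rows)
  tr <- mk_tracks(list(
    tibble::tibble(time_min = c(0, 30, 60), lineage_id = "1",
                   x_um = 50, y_um = 50, z_um = 50, status = "present"),
    # appears at t>0 near the +x face: enter
    tibble::tibble(time_min = c(30, 60), lineage_id = "2",
                   x_um = c(95, 85), y_um = 50, z_um = 50,
                   status = "present"),
    # appears at t>0 at field center: anomaly
    tibble::tibble(time_min = 60, lineage_id = "3",
                   x_um = 50, y_um = 55, z_um = 50, status = "present"),
    # disappears mid-run near a face: exit
    tibble::tibble(time_min = c(0, 30), lineage_id = "4",
                   x_um = c(15, 8), y_um = 50, z_um = 50,
                   status = "present")))
  ev <- classify_edge_events(tr, field_bounds = c(100, 100, 100),
                             margin = 20)
  expect_equal(ev$type[ev$participants == "2"], "enter")
  expect_equal(ev$type[ev$participants == "3"], "anomaly")
  expect_equal(ev$type[ev$participants == "4"], "exit")
  expect_false("1" %in% ev$participants)
})

test_that("the tracker recovers a scripted two-body coalescence", {
  run <- two_merge_run()
  ev <- run$result$tracking$events
  mg <- ev[ev$type == "merge", ]
  expect_equal(nrow(mg), 1)
  expect_equal(mg$product, "1/2")
  scripted <- run$truth$events$time_min[run$truth$events$type == "merge"]
  expect_lte(abs(mg$time_min - scripted), 30)   # one frame
  expect_false(any(ev$type == "anomaly"))
  # absorbed tracks end as merged-away, never as exits
  tr <- run$result$tracking$tracks
  expect_true(any(tr$status == "merged-away"))
})

test_that("the tracker recovers scripted field-edge traffic", {
  run <- edge_run()
  ev <- run$result$tracking$events
  expect_equal(sum(ev$type == "exit"), 3)
  expect_equal(sum(ev$type == "enter"), 2)
  expect_equal(sum(ev$type == "merge"), 0)
  expect_equal(sum(ev$type == "anomaly"), 0)
})

test_that("founder labels are conserved across the track table", {
  for (run in list(coalescence_run(), edge_run())) {
    tk <- run$result$tracking
    # founders of live tracks at each timepoint are disjoint
    for (t in unique(tk$tracks$time_min)) {
      ids <- tk$tracks$lineage_id[tk$tracks$time_min == t &
                                    tk$tracks$status == "present"]
      founders <- unlist(strsplit(ids, "/", fixed = TRUE))
      expect_false(anyDuplicated(founders) > 0)
    }
    # every founder ever seen is accounted for by the final live tracks
    # plus exited and merged-away lineages
    all_f <- sort(unique(unlist(strsplit(tk$tracks$lineage_id, "/",
                                         fixed = TRUE))))
    expect_setequal(all_f, tk$founders)
    # no split events exist anywhere
    expect_false(any(tk$events$type == "split"))
  }
})
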