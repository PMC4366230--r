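#' Merge slash-coded lineage identifiers
#'
#' A coalesced aggregate carries the history of its founders as a
#' slash-joined identifier: when aggregates 6 and 7 coalesce the product is
#' `"6/7"`; when that product later absorbs aggregate 5 it becomes
#' `"5/6/7"`. Founder labels sort numerically (so `"2/10"`, not `"10/2"`);
#' non-numeric labels sort lexicographically after the numeric ones.
#'
#' @param ids character vector (>= 2) of lineage ids with disjoint founder
#'   sets.
#' @return The merged lineage id string.
#' @examples
#' merge_ids(c("6", "7"))      # "6/7"
#' merge_ids(c("6/7", "5"))    # "5/6/7"
#' @export
merge_ids <- function(ids) {
  if (length(ids) < 2) abort("merge_ids needs >= 2 ids")
  founders <- unlist(strsplit(ids, "/", fixed = TRUE))
  if (anyDuplicated(founders)) abort("overlapping founder sets")
  num <- suppressWarnings(as.numeric(founders))
  o <- order(is.na(num), num, founders)
  paste(founders[o], collapse = "/")
}

founder_set <- function(id) strsplit(id, "/", fixed = TRUE)[[1]]

# pairwise voxel-overlap fractions between two frames' objects; fraction is
# relative to the earlier (predecessor) object
overlap_table <- function(objs_a, objs_b) {
  rows <- list()
  for (i in seq_along(objs_a)) {
    ia <- objs_a[[i]]$indices
    for (j in seq_along(objs_b)) {
      ov <- length(intersect(ia, objs_b[[j]]$indices))
      if (ov > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          a = i, b = j, overlap = ov, frac = ov / length(ia))
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(a = integer(), b = integer(), overlap = integer(),
                   frac = numeric())
}

object_centroid <- function(vox) {
  co <- arrayInd(vox$indices, vox$dim)
  vox$origin + c(mean((co[, 2] - 0.5) * vox$voxel[1]),
                 mean((co[, 1] - 0.5) * vox$voxel[2]),
                 mean((co[, 3] - 0.5) * vox$voxel[3]))
}

#' Link one frame's objects to the next
#'
#' Greedy best-first assignment by descending voxel-overlap fraction, with a
#' centroid-distance fallback (within `gate` um) for non-overlapping pairs.
#' Unmatched current objects are flagged `candidate_exit`, unmatched next
#' objects `candidate_entry`, and additional predecessors overlapping an
#' already-claimed successor `candidate_merge`.
#'
#' @param objs_a,objs_b lists of [voxel_object()]s at `t` and `t + dt`
#'   (same grid and calibration).
#' @param gate centroid-distance gate in um for non-overlapping links
#'   (>= 0; default 50).
#' @param min_overlap minimum overlap fraction considered at all.
#' @return A tibble with columns `type` (`link`, `candidate_merge`,
#'   `candidate_exit`, `candidate_entry`), `a`, `b`, `frac`, `dist`.
#' @export
link_frames <- function(objs_a, objs_b, gate = 50, min_overlap = 0.05) {
  assert_scalar_num(gate, "gate", nonneg = TRUE)
  ot <- overlap_table(objs_a, objs_b)
  ot <- ot[ot$frac >= min_overlap, , drop = FALSE]
  na <- length(objs_a); nb <- length(objs_b)
  free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
  links <- list()
  if (nrow(ot)) {
    ot <- ot[order(-ot$frac), , drop = FALSE]
    for (r in seq_len(nrow(ot))) {
      i <- ot$a[r]; j <- ot$b[r]
      if (free_a[i] && free_b[j]) {
        links[[length(links) + 1]] <- tibble::tibble(
          type = "link", a = i, b = j, frac = ot$frac[r], dist = NA_real_)
        free_a[i] <- FALSE; free_b[j] <- FALSE
      }
    }
  }
  # centroid-distance fallback for still-unmatched pairs
  if (any(free_a) && any(free_b)) {
    ca <- t(vapply(objs_a, object_centroid, numeric(3)))
    cb <- t(vapply(objs_b, object_centroid, numeric(3)))
    cand <- expand.grid(a = which(free_a), b = which(free_b))
    if (nrow(cand)) {
      cand$dist <- sqrt(rowSums((ca[cand$a, , drop = FALSE] -
                                   cb[cand$b, , drop = FALSE])^2))
      cand <- cand[cand$dist <= gate, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand$a[r]; j <- cand$b[r]
        if (free_a[i] && free_b[j]) {
          links[[length(links) + 1]] <- tibble::tibble(
            type = "link", a = i, b = j, frac = 0, dist = cand$dist[r])
          free_a[i] <- FALSE; free_b[j] <- FALSE
        }
      }
    }
  }
  # many-to-one: unmatched predecessors overlapping a claimed successor
  if (nrow(ot)) {
    for (r in seq_len(nrow(ot))) {
      i <- ot$a[r]; j <- ot$b[r]
      if (free_a[i] && !free_b[j]) {
        links[[length(links) + 1]] <- tibble::tibble(
          type = "candidate_merge", a = i, b = j, frac = ot$frac[r],
          dist = NA_real_)
        free_a[i] <- FALSE
      }
    }
  }
  for (i in which(free_a)) {
    links[[length(links) + 1]] <- tibble::tibble(
      type = "candidate_exit", a = i, b = NA_integer_, frac = NA_real_,
      dist = NA_real_)
  }
  for (j in which(free_b)) {
    links[[length(links) + 1]] <- tibble::tibble(
      type = "candidate_entry", a = NA_integer_, b = j, frac = NA_real_,
      dist = NA_real_)
  }
  if (length(links)) dplyr::bind_rows(links) else
    tibble::tibble(type = character(), a = integer(), b = integer(),
                   frac = numeric(), dist = numeric())
}

#' Confirm coalescence events among merge candidates
#'
#' A merge into successor `b` is confirmed when at least two predecessors
#' each overlap `b` with fraction >= `tau` and the successor volume is at
#' least 0.6 of the summed predecessor volumes (guards against one object
#' briefly occluding another).
#'
#' @param links a [link_frames()] table.
#' @param objs_a,objs_b the frame object lists given to [link_frames()].
#' @param tau overlap-fraction threshold in (0, 1] (default 0.3).
#' @param volume_factor successor-volume factor (default 0.6).
#' @return A tibble of confirmed merges: `b`, `participants`
#'   (list-column of predecessor indices).
#' @export
detect_coalescence <- function(links, objs_a, objs_b, tau = 0.3,
                               volume_factor = 0.6) {
  if (!is.numeric(tau) || tau <= 0 || tau > 1) {
    abort("`tau` must be in (0, 1]")
  }
  ot <- overlap_table(objs_a, objs_b)
  cand_b <- unique(links$b[links$type == "candidate_merge"])
  out <- list()
  for (j in cand_b) {
    part <- ot$a[ot$b == j & ot$frac >= tau]
    if (length(part) < 2) next
    vols_a <- vapply(objs_a[part], function(o) length(o$indices), 1)
    vol_b <- length(objs_b[[j]]$indices)
    if (vol_b < volume_factor * sum(vols_a)) next
    out[[length(out) + 1]] <- tibble::tibble(
      b = j, participants = list(sort(part)))
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(b = integer(), participants = list())
}

#' Classify track endpoints as field-edge entries, exits, or anomalies
#'
#' A track first appearing after the initial timepoint with centroid within
#' `margin` um of a field face is an `enter` event; a track disappearing
#' (without merging) while within the margin is an `exit`; a disappearance
#' or appearance away from the edge is flagged `anomaly` instead.
#'
#' @param tracks a track table (`time_min`, `lineage_id`, `x_um`, `y_um`,
#'   `z_um`, `status`), as produced by [track_objects()].
#' @param field_bounds `c(x, y, z)` field extent in um (lower corner at 0).
#' @param margin edge margin in um (>= 0; default 20).
#' @return A tibble of events: `time_min`, `type` (`enter`, `exit`,
#'   `anomaly`), `participants`, `product`.
#' @export
classify_edge_events <- function(tracks, field_bounds, margin = 20) {
  assert_scalar_num(margin, "margin", nonneg = TRUE)
  stopifnot(length(field_bounds) == 3)
  t0 <- min(tracks$time_min)
  t_end <- max(tracks$time_min)
  near_edge <- function(p) {
    any(p <= margin) || any(field_bounds - p <= margin)
  }
  ev <- list()
  for (id in unique(tracks$lineage_id)) {
    tr <- tracks[tracks$lineage_id == id & tracks$status == "present", ,
                 drop = FALSE]
    if (!nrow(tr)) next
    tr <- tr[order(tr$time_min), , drop = FALSE]
    first <- tr[1, ]; last <- tr[nrow(tr), ]
    born_by_merge <- grepl("/", id, fixed = TRUE)
    if (first$time_min > t0 && !born_by_merge) {
      type <- if (near_edge(c(first$x_um, first$y_um, first$z_um)))
        "enter" else "anomaly"
      ev[[length(ev) + 1]] <- tibble::tibble(
        time_min = first$time_min, type = type, participants = id,
        product = id)
    }
    merged_away <- any(tracks$status[tracks$lineage_id == id] ==
                         "merged-away")
    if (last$time_min < t_end && !merged_away) {
      type <- if (near_edge(c(last$x_um, last$y_um, last$z_um)))
        "exit" else "anomaly"
      ev[[length(ev) + 1]] <- tibble::tibble(
        time_min = last$time_min, type = type, participants = id,
        product = id)
    }
  }
  if (length(ev)) dplyr::arrange(dplyr::bind_rows(ev), time_min) else
    tibble::tibble(time_min = numeric(), type = character(),
                   participants = character(), product = character())
}

#' Track reconstructed objects through time
#'
#' Links objects frame to frame ([link_frames()]), confirms coalescence
#' ([detect_coalescence()]), maintains slash-coded lineage identifiers
#' ([merge_ids()]), and classifies field-edge entries and exits
#' ([classify_edge_events()]). Splits are never emitted; an off-edge
#' disappearance or appearance is an anomaly.
#'
#' @param frames list over timepoints of [voxel_object()] lists (one shared
#'   grid).
#' @param times timepoint times in minutes.
#' @param field_bounds field extent `c(x, y, z)` um; defaults to the grid
#'   extent of the first object.
#' @param gate,tau,volume_factor,margin tracking parameters (see the linked
#'   functions).
#' @param reentry_window frames within which an entry adjacent to a previous
#'   exit of the same face re-uses the exited lineage id (transient exit).
#' @return A `lineage_tracks` list: `tracks` tibble (`time_min`,
#'   `lineage_id`, `object`, `x_um`, `y_um`, `z_um`, `volume_um3`,
#'   `status`), `events` tibble, `founders` character vector.
#' @export
track_objects <- function(frames, times, field_bounds = NULL, gate = 50,
                          tau = 0.3, volume_factor = 0.6, margin = 20,
                          reentry_window = 10) {
  nt <- length(frames)
  stopifnot(length(times) == nt)
  if (is.null(field_bounds)) {
    ob <- NULL
    for (fr in frames) if (length(fr)) { ob <- fr[[1]]; break }
    if (is.null(ob)) abort("no objects in any frame")
    field_bounds <- c(ob$dim[2] * ob$voxel[1], ob$dim[1] * ob$voxel[2],
                      ob$dim[3] * ob$voxel[3])
  }
  vvol <- NULL
  next_founder <- 1L
  tracks <- list()        # per live track: id, obj (index in current frame)
  rows <- list()
  merge_rows <- list()
  exited <- list()        # recent exits for transient re-entry matching

  new_track <- function(id, obj) list(id = id, obj = obj)

  # initial frame
  fr <- frames[[1]]
  for (j in seq_along(fr)) {
    tracks[[length(tracks) + 1]] <- new_track(as.character(next_founder), j)
    next_founder <- next_founder + 1L
  }
  record <- function(ti, trk, status) {
    ob <- frames[[ti]][[trk$obj]]
    cen <- object_centroid(ob)
    tibble::tibble(
      time_min = times[ti], lineage_id = trk$id, object = ob$label,
      x_um = cen[1], y_um = cen[2], z_um = cen[3],
      volume_um3 = length(ob$indices) * prod(ob$voxel), status = status)
  }
  for (trk in tracks) rows[[length(rows) + 1]] <- record(1L, trk, "present")

  for (ti in seq_len(nt - 1)) {
    A <- frames[[ti]]; B <- frames[[ti + 1]]
    # current tracks mapped onto A's objects
    amap <- vapply(tracks, function(tr) tr$obj, 1L)
    links <- link_frames(A, B, gate = gate)
    merges <- detect_coalescence(links, A, B, tau = tau,
                                 volume_factor = volume_factor)
    consumed_a <- integer(0)
    claimed_b <- integer(0)
    new_tracks <- list()
    if (nrow(merges)) {
      for (r in seq_len(nrow(merges))) {
        part_a <- merges$participants[[r]]
        part_tr <- which(amap %in% part_a)
        if (length(part_tr) < 2) next
        ids <- vapply(tracks[part_tr], function(tr) tr$id, "")
        prod_id <- merge_ids(ids)
        merge_rows[[length(merge_rows) + 1]] <- tibble::tibble(
          time_min = times[ti + 1], type = "merge",
          participants = paste(sort(ids), collapse = "+"),
          product = prod_id)
        new_tracks[[length(new_tracks) + 1]] <-
          new_track(prod_id, merges$b[r])
        # absorbed tracks get a terminal merged-away row
        for (k in part_tr) {
          trk <- tracks[[k]]
          ob <- A[[trk$obj]]
          cen <- object_centroid(ob)
          rows[[length(rows) + 1]] <- tibble::tibble(
            time_min = times[ti + 1], lineage_id = trk$id,
            object = NA_integer_, x_um = cen[1], y_um = cen[2],
            z_um = cen[3], volume_um3 = NA_real_, status = "merged-away")
        }
        consumed_a <- c(consumed_a, part_a)
        claimed_b <- c(claimed_b, merges$b[r])
      }
    }
    plain <- links[links$type == "link" & !(links$a %in% consumed_a) &
                     !(links$b %in% claimed_b), , drop = FALSE]
    for (r in seq_len(nrow(plain))) {
      k <- which(amap == plain$a[r])
      if (length(k) != 1) next
      trk <- tracks[[k]]
      trk$obj <- plain$b[r]
      new_tracks[[length(new_tracks) + 1]] <- trk
    }
    # unmatched current tracks end here (exit or anomaly, classified later)
    ended_a <- setdiff(amap, c(consumed_a, plain$a))
    for (a in ended_a) {
      k <- which(amap == a)
      if (length(k) != 1) next
      trk <- tracks[[k]]
      ob <- A[[trk$obj]]
      exited[[length(exited) + 1]] <- list(
        id = trk$id, ti = ti, centroid = object_centroid(ob))
    }
    # unmatched next objects start new tracks (entry or anomaly)
    matched_b <- c(claimed_b, plain$b)
    for (j in setdiff(seq_along(B), matched_b)) {
      cen <- object_centroid(B[[j]])
      reuse <- NULL
      for (ei in seq_along(exited)) {
        ex <- exited[[ei]]
        if (ti + 1 - ex$ti <= reentry_window &&
            sqrt(sum((cen - ex$centroid)^2)) <= 2 * gate) {
          reuse <- ei
          break
        }
      }
      if (!is.null(reuse)) {
        id <- exited[[reuse]]$id
        exited[[reuse]] <- NULL
      } else {
        id <- as.character(next_founder)
        next_founder <- next_founder + 1L
      }
      new_tracks[[length(new_tracks) + 1]] <- new_track(id, j)
    }
    tracks <- new_tracks
    for (trk in tracks) {
      rows[[length(rows) + 1]] <- record(ti + 1L, trk, "present")
    }
  }
  track_tbl <- dplyr::arrange(dplyr::bind_rows(rows), time_min, lineage_id)
  edge_ev <- classify_edge_events(track_tbl, field_bounds, margin = margin)
  events <- dplyr::arrange(
    dplyr::bind_rows(c(merge_rows, list(edge_ev))), time_min)
  founders <- sort(unique(unlist(lapply(track_tbl$lineage_id,
                                        founder_set))))
  structure(list(tracks = track_tbl, events = events, founders = founders,
                 field_bounds = field_bounds),
            class = "lineage_tracks")
}

#' @export
print.lineage_tracks <- function(x, ...) {
  cat(sprintf(
    "<lineage_tracks> %d founders, %d track rows, %d events\n",
    length(x$founders), nrow(x$tracks), nrow(x$events)))
  invisible(x)
}
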