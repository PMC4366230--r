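#' Script a synthetic aggregate scene
#'
#' A scene script describes a rectangular field of transparent gel, its
#' acquisition geometry, and a cast of scripted objects (aggregates and single
#' cells). Defaults reproduce the acquisition geometry used throughout the
#' package's validation work: a 446 x 335 um field sectioned through 1.5 mm of
#' gel at 10 um z-steps, re-imaged every 30 minutes for 17 days. Scenes used in
#' tests are much smaller; pass explicit values.
#'
#' @param objects list of [object_script()] entries.
#' @param field_size numeric length-3, field extent in um as `c(x, y, z)`.
#' @param pixel_size lateral calibration, um per pixel.
#' @param z_step axial spacing between optical sections, um.
#' @param t_step interval between timepoints, minutes.
#' @param duration total scripted duration, minutes. The scene has
#'   `floor(duration / t_step)` timepoints at `0, t_step, 2 t_step, ...`.
#' @param approach_min minutes over which scripted merge partners drift from
#'   their scripted positions into tangent contact before the merge time
#'   (coalescence is a gradual, directed approach, not a jump).
#' @param contact_factor merged partners sit at `contact_factor * (r1 + r2)`
#'   center separation (volume-equivalent radii): values near 1 give
#'   dumbbell-shaped coalesced bodies, smaller values deeper fusion.
#' @param seed integer; fixes every random draw made by [build_scene()] and
#'   [render_dic()] so that identical scripts give bit-identical output.
#' @return A `scene_script` object (a validated list).
#' @seealso [object_script()], [build_scene()], [render_dic()]
#' @export
scene_script <- function(objects = list(),
                         field_size = c(446, 335, 1500),
                         pixel_size = 2,
                         z_step = 10,
                         t_step = 30,
                         duration = 17 * 24 * 60,
                         approach_min = 90,
                         contact_factor = 0.8,
                         seed = 1L) {
  stopifnot(length(field_size) == 3)
  if (any(!is.finite(field_size)) || any(field_size <= 0)) {
    abort("all field extents must be > 0")
  }
  assert_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  assert_scalar_num(z_step, "z_step", positive = TRUE)
  assert_scalar_num(t_step, "t_step", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  if (duration < t_step) abort("`duration` must be >= `t_step`")
  ids <- vapply(objects, function(o) o$id, 1L)
  if (anyDuplicated(ids)) abort("object ids must be unique")
  for (o in objects) {
    if (!is.null(o$merge_with) && !(o$merge_with$partner %in% ids)) {
      abort(sprintf("object %d merges with nonexistent partner %d",
                    o$id, o$merge_with$partner))
    }
  }
  assert_scalar_num(approach_min, "approach_min", nonneg = TRUE)
  if (contact_factor <= 0 || contact_factor > 1) {
    abort("`contact_factor` must be in (0, 1]")
  }
  structure(
    list(objects = objects, field_size = as.numeric(field_size),
         pixel_size = pixel_size, z_step = z_step, t_step = t_step,
         duration = duration, approach_min = approach_min,
         contact_factor = contact_factor, seed = as.integer(seed)),
    class = "scene_script")
}

#' Script one object of a synthetic scene
#'
#' @param id positive integer label, unique within the scene.
#' @param centroid initial centroid, um, `c(x, y, z)`.
#' @param radius initial radius, um (> 0).
#' @param t_birth,t_death lifetime in scene minutes.
#' @param growth radial growth rate, um/hr.
#' @param motion one of `"stationary"`, `"random_walk"` (isotropic Gaussian
#'   steps of `step_sigma` um per frame), `"drift"` (constant `velocity`) or
#'   `"dervish"` (correlated random walk with per-step speeds drawn uniformly
#'   from `speed_range` um/hr and direction perturbed by `turning_sigma`).
#' @param step_sigma random-walk step standard deviation, um per frame.
#' @param velocity drift velocity `c(vx, vy, vz)`, um/hr.
#' @param speed_range dervish speed range, um/hr.
#' @param turning_sigma dervish direction perturbation scale (radian-like).
#' @param merge_with optional `list(partner =, time =)`: coalesce with the
#'   partner object at the given scene time (minutes). The merge time must lie
#'   within both partners' lifetimes.
#' @param lumpiness amplitude (fraction of radius) of a low-order angular
#'   perturbation of the surface, giving irregular rather than spherical
#'   contours.
#' @return An `object_script` list.
#' @export
object_script <- function(id, centroid, radius,
                          t_birth = 0, t_death = Inf, growth = 0,
                          motion = c("stationary", "random_walk", "drift",
                                     "dervish"),
                          step_sigma = 2,
                          velocity = c(0, 0, 0),
                          speed_range = c(10, 40),
                          turning_sigma = 0.6,
                          merge_with = NULL,
                          lumpiness = 0) {
  motion <- match.arg(motion)
  assert_scalar_num(radius, "radius", positive = TRUE)
  stopifnot(length(centroid) == 3, is.finite(centroid))
  if (length(speed_range) != 2 || any(speed_range < 0) ||
      speed_range[2] < speed_range[1]) {
    abort("`speed_range` must be c(lo, hi) with 0 <= lo <= hi")
  }
  if (!is.null(merge_with)) {
    stopifnot(is.list(merge_with), !is.null(merge_with$partner),
              !is.null(merge_with$time))
    if (merge_with$time < t_birth || merge_with$time > t_death) {
      abort("merge time must lie within the object's lifetime")
    }
  }
  structure(
    list(id = as.integer(id), centroid = as.numeric(centroid),
         radius = radius, t_birth = t_birth, t_death = t_death,
         growth = growth, motion = motion, step_sigma = step_sigma,
         velocity = as.numeric(velocity),
         speed_range = as.numeric(speed_range),
         turning_sigma = turning_sigma, merge_with = merge_with,
         lumpiness = lumpiness),
    class = "object_script")
}

# unit direction vectors perturbed into a correlated walk
correlated_directions <- function(n, turning_sigma) {
  d <- matrix(0, n, 3)
  cur <- rnorm(3)
  cur <- cur / sqrt(sum(cur^2))
  for (i in seq_len(n)) {
    cur <- cur + turning_sigma * rnorm(3)
    nrm <- sqrt(sum(cur^2))
    if (nrm < 1e-12) { cur <- rnorm(3); nrm <- sqrt(sum(cur^2)) }
    cur <- cur / nrm
    d[i, ] <- cur
  }
  d
}

#' Generate a dervish trajectory
#'
#' A correlated random walk emulating the fast, swirling, non-adherent cell
#' type observed in tumorigenic gel preparations: per step a speed is drawn
#' uniformly from `speed_range` (um/hr) and the heading direction is a unit
#' vector perturbed from the previous step, so the path swirls rather than
#' diffuses.
#'
#' @param speed_range `c(lo, hi)` in um/hr, `0 <= lo <= hi` and `hi > 0`.
#' @param turning_sigma heading perturbation scale per step.
#' @param duration_hr total duration, hours.
#' @param sampling_min sampling interval, minutes (> 0). The track has
#'   `floor(duration_hr * 60 / sampling_min)` steps.
#' @param seed RNG seed (default 1).
#' @param start starting point, um.
#' @return A tibble with columns `time_min`, `x_um`, `y_um`, `z_um`; one row
#'   per sample (steps + 1 rows).
#' @examples
#' trk <- dervish_track(c(10, 40), duration_hr = 18, sampling_min = 30)
#' nrow(trk)  # 37 samples = 36 steps
#' @export
dervish_track <- function(speed_range = c(10, 40), turning_sigma = 0.6,
                          duration_hr = 18, sampling_min = 30, seed = 1L,
                          start = c(0, 0, 0)) {
  if (length(speed_range) != 2 || any(!is.finite(speed_range))) {
    abort("`speed_range` must be c(lo, hi)")
  }
  if (speed_range[1] < 0 || speed_range[2] < speed_range[1] ||
      speed_range[2] <= 0) {
    abort("`speed_range` must satisfy 0 <= lo <= hi, hi > 0")
  }
  assert_scalar_num(sampling_min, "sampling_min", positive = TRUE)
  assert_scalar_num(duration_hr, "duration_hr", positive = TRUE)
  n <- floor(duration_hr * 60 / sampling_min)
  dt_hr <- sampling_min / 60
  with_seed(seed, {
    dirs <- correlated_directions(n, turning_sigma)
    speeds <- runif(n, speed_range[1], speed_range[2])
    steps <- dirs * (speeds * dt_hr)
    pos <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`))
    tibble::tibble(
      time_min = seq(0, by = sampling_min, length.out = n + 1),
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  })
}

# low-order angular surface perturbation: effective radius multiplier at a
# set of offsets from the centroid
lumpy_radius <- function(dx, dy, dz, lumpiness) {
  if (lumpiness == 0) return(1)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- 1e-9
  ct <- dz / r
  phi <- atan2(dy, dx)
  # mix of degree-2 harmonics; deterministic, smooth, mean ~ 1
  1 + lumpiness * ((3 * ct^2 - 1) / 2 * 0.6 +
                     (1 - ct^2) * cos(2 * phi) * 0.4)
}

# rasterize a (possibly lumpy) ball into the label array `lab`
paint_ball <- function(lab, center, radius, label, pixel_size, z_step,
                       lumpiness = 0) {
  d <- dim(lab)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  zc <- (seq_len(nz) - 0.5) * z_step
  jr <- which(abs(xc - center[1]) <= radius * (1 + abs(lumpiness)) + pixel_size)
  ir <- which(abs(yc - center[2]) <= radius * (1 + abs(lumpiness)) + pixel_size)
  kr <- which(abs(zc - center[3]) <= radius * (1 + abs(lumpiness)) + z_step)
  if (!length(jr) || !length(ir) || !length(kr)) return(lab)
  dx <- rep(xc[jr] - center[1], each = length(ir))
  dy <- rep(yc[ir] - center[2], times = length(jr))
  sub <- array(0, c(length(ir), length(jr), length(kr)))
  for (k in seq_along(kr)) {
    dz <- zc[kr[k]] - center[3]
    rr <- radius * lumpy_radius(dx, dy, dz, lumpiness)
    inside <- (dx^2 + dy^2 + dz^2) <= rr^2
    sub[, , k] <- inside
  }
  block <- lab[ir, jr, kr, drop = FALSE]
  block[sub > 0] <- label
  lab[ir, jr, kr] <- block
  lab
}

#' Build the ground truth of a scripted scene
#'
#' Plays a [scene_script()] forward on its acquisition grid, producing exact
#' per-timepoint voxel label masks, per-object centroid/volume series, and an
#' event log of merges, field entries and exits. Merged partners are replaced
#' from the merge time onward by a connected, volume-conserving coalesced body:
#' the partner spheres are relocated to tangent contact about their
#' volume-weighted centroid, so the rendered union stays a single connected
#' object.
#'
#' @param script a [scene_script()].
#' @return A `ground_truth` object: list with `times` (minutes), `dim`
#'   (`c(ny, nx, nz)`), `masks` (list of integer label arrays, one per
#'   timepoint; labels are the minimal founder id of the owning lineage),
#'   `objects` (tibble: `time_min, label, lineage, x_um, y_um, z_um,
#'   volume_um3, present`), `events` (tibble: `time_min, type, participants,
#'   product`), and the `script`.
#' @export
build_scene <- function(script) {
  stopifnot(inherits(script, "scene_script"))
  fx <- script$field_size[1]; fy <- script$field_size[2]
  fz <- script$field_size[3]
  px <- script$pixel_size; zs <- script$z_step
  nx <- max(1L, floor(fx / px)); ny <- max(1L, floor(fy / px))
  nz <- max(1L, floor(fz / zs))
  nt <- floor(script$duration / script$t_step)
  times <- seq(0, by = script$t_step, length.out = nt)
  obs <- script$objects
  nobj <- length(obs)

  # trajectories: nobj x nt x 3, drawn from the scene seed in id order
  traj <- array(NA_real_, c(max(nobj, 1), nt, 3))
  radii <- matrix(NA_real_, max(nobj, 1), nt)
  if (nobj > 0) {
    with_seed(script$seed, {
      for (oi in seq_len(nobj)) {
        o <- obs[[oi]]
        disp <- switch(o$motion,
          stationary = matrix(0, nt, 3),
          drift = outer((times - times[1]) / 60, o$velocity),
          random_walk = {
            st <- matrix(rnorm(3 * nt, sd = o$step_sigma), nt, 3)
            st[1, ] <- 0
            apply(st, 2, cumsum)
          },
          dervish = {
            dirs <- correlated_directions(nt, o$turning_sigma)
            sp <- runif(nt, o$speed_range[1], o$speed_range[2])
            st <- dirs * (sp * script$t_step / 60)
            st[1, ] <- 0
            apply(st, 2, cumsum)
          })
        if (nt == 1) disp <- matrix(disp, 1, 3)
        traj[oi, , ] <- sweep(disp, 2, o$centroid, `+`)
        radii[oi, ] <- o$radius + o$growth * pmax(0, times - o$t_birth) / 60
      }
    })
  }

  # merge scripts in time order; union-find over object indices
  merges <- list()
  if (nobj > 0) {
    ids <- vapply(obs, `[[`, 1L, "id")
    for (oi in seq_len(nobj)) {
      mw <- obs[[oi]]$merge_with
      if (!is.null(mw)) {
        pj <- match(mw$partner, ids)
        merges[[length(merges) + 1]] <-
          list(a = oi, b = pj, time = mw$time)
      }
    }
    if (length(merges)) {
      merges <- merges[order(vapply(merges, `[[`, 1, "time"))]
    }
  }

  parent <- seq_len(max(nobj, 1))
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_offset <- matrix(0, max(nobj, 1), 3)  # member offset from anchor
  anchor <- seq_len(max(nobj, 1))               # trajectory carrier per root

  ids <- if (nobj) vapply(obs, `[[`, 1L, "id") else integer()
  lineage_of <- as.character(ids)               # per root index

  masks <- vector("list", nt)
  obj_rows <- vector("list", nt)
  ev <- list()
  merge_ptr <- 1L
  was_present <- rep(FALSE, max(nobj, 1))
  vvol <- px * px * zs

  for (ti in seq_len(nt)) {
    t_now <- times[ti]
    # activate merges scheduled at or before this timepoint
    while (merge_ptr <= length(merges) &&
           merges[[merge_ptr]]$time <= t_now) {
      m <- merges[[merge_ptr]]
      ra <- find_root(m$a); rb <- find_root(m$b)
      if (ra != rb) {
        mem_a <- which(vapply(seq_len(nobj), find_root, 1L) == ra)
        mem_b <- which(vapply(seq_len(nobj), find_root, 1L) == rb)
        va <- sum((4 / 3) * pi * radii[mem_a, ti]^3)
        vb <- sum((4 / 3) * pi * radii[mem_b, ti]^3)
        pa <- traj[anchor[ra], ti, ] + colMeans(cluster_offset[mem_a, ,
                                                               drop = FALSE])
        pb <- traj[anchor[rb], ti, ] + colMeans(cluster_offset[mem_b, ,
                                                               drop = FALSE])
        cen <- (va * pa + vb * pb) / (va + vb)
        axis <- pb - pa
        nrm <- sqrt(sum(axis^2))
        if (nrm < 1e-9) axis <- c(1, 0, 0) else axis <- axis / nrm
        # tangent contact: slight overlap keeps the union 26-connected
        ra_eq <- (3 * va / (4 * pi))^(1 / 3)
        rb_eq <- (3 * vb / (4 * pi))^(1 / 3)
        gap <- script$contact_factor * (ra_eq + rb_eq)
        root_new <- min(ra, rb)
        other <- max(ra, rb)
        off_a <- -axis * gap * vb / (va + vb)
        off_b <- axis * gap * va / (va + vb)
        for (mi in mem_a) cluster_offset[mi, ] <-
          cluster_offset[mi, ] - colMeans(cluster_offset[mem_a, ,
                                                         drop = FALSE]) + off_a
        for (mi in mem_b) cluster_offset[mi, ] <-
          cluster_offset[mi, ] - colMeans(cluster_offset[mem_b, ,
                                                         drop = FALSE]) + off_b
        # the new cluster is carried by the larger partner's trajectory,
        # re-based so the cluster centroid starts at `cen`
        carrier <- if (va >= vb) anchor[ra] else anchor[rb]
        shift_now <- cen - traj[carrier, ti, ]
        traj[carrier, , ] <- sweep(traj[carrier, , , drop = FALSE][1, , ],
                                   2, shift_now, `+`)
        parent[other] <- root_new
        anchor[root_new] <- carrier
        id_a <- lineage_of[ra]; id_b <- lineage_of[rb]
        prod <- merge_ids(c(id_a, id_b))
        lineage_of[root_new] <- prod
        ev[[length(ev) + 1]] <- tibble::tibble(
          time_min = t_now, type = "merge",
          participants = paste(sort(c(id_a, id_b)), collapse = "+"),
          product = prod)
      }
      merge_ptr <- merge_ptr + 1L
    }

    # approach phase: pending merge partners drift toward tangent contact
    extra_off <- matrix(0, max(nobj, 1), 3)
    if (merge_ptr <= length(merges) && script$approach_min > 0) {
      for (mp in merge_ptr:length(merges)) {
        m <- merges[[mp]]
        w <- 1 - (m$time - t_now) / script$approach_min
        if (w <= 0 || w > 1) next
        ra <- find_root(m$a); rb <- find_root(m$b)
        if (ra == rb) next
        mem_a <- which(vapply(seq_len(nobj), find_root, 1L) == ra)
        mem_b <- which(vapply(seq_len(nobj), find_root, 1L) == rb)
        va <- sum((4 / 3) * pi * radii[mem_a, ti]^3)
        vb <- sum((4 / 3) * pi * radii[mem_b, ti]^3)
        pa <- traj[anchor[ra], ti, ] +
          colMeans(cluster_offset[mem_a, , drop = FALSE])
        pb <- traj[anchor[rb], ti, ] +
          colMeans(cluster_offset[mem_b, , drop = FALSE])
        cen <- (va * pa + vb * pb) / (va + vb)
        axis <- pb - pa
        nrm <- sqrt(sum(axis^2))
        axis <- if (nrm < 1e-9) c(1, 0, 0) else axis / nrm
        ra_eq <- (3 * va / (4 * pi))^(1 / 3)
        rb_eq <- (3 * vb / (4 * pi))^(1 / 3)
        gap <- script$contact_factor * (ra_eq + rb_eq)
        ta <- cen - axis * gap * vb / (va + vb)
        tb <- cen + axis * gap * va / (va + vb)
        for (mi in mem_a) extra_off[mi, ] <- extra_off[mi, ] + w * (ta - pa)
        for (mi in mem_b) extra_off[mi, ] <- extra_off[mi, ] + w * (tb - pb)
      }
    }

    lab <- array(0L, c(ny, nx, nz))
    roots <- if (nobj) unique(vapply(seq_len(nobj), find_root, 1L)) else
      integer()
    centers <- list()
    for (r in roots) {
      mem <- which(vapply(seq_len(nobj), find_root, 1L) == r)
      alive <- mem[vapply(mem, function(mi) {
        obs[[mi]]$t_birth <= t_now && obs[[mi]]$t_death >= t_now
      }, TRUE)]
      if (!length(alive)) next
      lin <- lineage_of[r]
      lab_id <- min(as.integer(strsplit(lin, "/", fixed = TRUE)[[1]]))
      for (mi in alive) {
        cen <- traj[anchor[r], ti, ] + cluster_offset[mi, ] +
          extra_off[mi, ]
        centers[[as.character(mi)]] <- cen
        lab <- paint_ball(lab, cen, radii[mi, ti], lab_id, px, zs,
                          obs[[mi]]$lumpiness)
      }
    }
    masks[[ti]] <- lab

    # per-lineage logged series from the mask itself (mask-consistent)
    labs_present <- sort(setdiff(unique(as.vector(lab)), 0L))
    rows <- list()
    for (r in roots) {
      lin <- lineage_of[r]
      lab_id <- min(as.integer(strsplit(lin, "/", fixed = TRUE)[[1]]))
      mem <- which(vapply(seq_len(nobj), find_root, 1L) == r)
      alive <- mem[vapply(mem, function(mi) {
        obs[[mi]]$t_birth <= t_now && obs[[mi]]$t_death >= t_now
      }, TRUE)]
      if (!length(alive)) next
      idx <- which(lab == lab_id)
      if (length(idx)) {
        co <- arrayInd(idx, dim(lab))
        cx <- mean((co[, 2] - 0.5) * px)
        cy <- mean((co[, 1] - 0.5) * px)
        cz <- mean((co[, 3] - 0.5) * zs)
        vol <- length(idx) * vvol
        present <- TRUE
      } else {
        cen <- traj[anchor[r], ti, ] +
          colMeans(cluster_offset[alive, , drop = FALSE]) +
          colMeans(extra_off[alive, , drop = FALSE])
        cx <- cen[1]; cy <- cen[2]; cz <- cen[3]
        vol <- 0
        present <- FALSE
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        time_min = t_now, label = lab_id, lineage = lin,
        x_um = cx, y_um = cy, z_um = cz, volume_um3 = vol,
        present = present)
      # enter/exit bookkeeping on the scripted (root) lineage
      if (present && !was_present[r] && ti > 1) {
        ev[[length(ev) + 1]] <- tibble::tibble(
          time_min = t_now, type = "enter", participants = lin,
          product = lin)
      }
      if (!present && was_present[r]) {
        ev[[length(ev) + 1]] <- tibble::tibble(
          time_min = t_now, type = "exit", participants = lin,
          product = lin)
      }
      was_present[r] <- present
    }
    obj_rows[[ti]] <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(time_min = numeric(), label = integer(),
                     lineage = character(), x_um = numeric(),
                     y_um = numeric(), z_um = numeric(),
                     volume_um3 = numeric(), present = logical())
  }

  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(time_min = numeric(), type = character(),
                   participants = character(), product = character())
  structure(
    list(times = times, dim = c(ny, nx, nz), masks = masks,
         objects = dplyr::bind_rows(obj_rows), events = events,
         script = script),
    class = "ground_truth")
}
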