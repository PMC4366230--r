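#' 3D centroid of a voxel or faceted object
#'
#' Voxel route: unweighted mean of occupied voxel centers. Mesh route:
#' volume-weighted tetrahedron centroid. On well-resolved objects the two
#' agree within a voxel.
#'
#' @param obj a [voxel_object()] or [faceted_object()].
#' @return Length-3 numeric `c(x, y, z)` in um.
#' @export
centroid3d <- function(obj) {
  if (inherits(obj, "voxel_object")) {
    object_centroid(obj)
  } else if (inherits(obj, "faceted_object")) {
    mesh_centroid(obj)
  } else {
    abort("`obj` must be a voxel_object or faceted_object")
  }
}

#' Instantaneous and mean 3D speed of a track
#'
#' Instantaneous speed between consecutive present frames is
#' `|centroid(t + dt) - centroid(t)| / dt` with `dt` in hours; intervals
#' during which the track was merged away (or absent) are excluded. The mean
#' is over the requested window.
#'
#' @param track tibble with `time_min`, `x_um`, `y_um`, `z_um` and
#'   optionally `status` (rows with status other than `"present"` are
#'   dropped).
#' @param window optional `c(t_min, t_max)` in minutes restricting the mean.
#' @return List with `speeds` (tibble: `time_min` of the interval end,
#'   `speed_um_hr`) and `mean` (um/hr).
#' @export
mean_speed <- function(track, window = NULL) {
  if ("status" %in% names(track)) {
    track <- track[track$status == "present", , drop = FALSE]
  }
  track <- track[order(track$time_min), , drop = FALSE]
  if (nrow(track) < 2) abort("mean_speed needs >= 2 timepoints")
  dt_hr <- diff(track$time_min) / 60
  disp <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2 +
                 diff(track$z_um)^2)
  sp <- tibble::tibble(time_min = track$time_min[-1],
                       speed_um_hr = as.numeric(disp / dt_hr))
  in_win <- if (is.null(window)) rep(TRUE, nrow(sp)) else
    sp$time_min >= window[1] & sp$time_min <= window[2]
  list(speeds = sp, mean = mean(sp$speed_um_hr[in_win]))
}

#' Volume of a faceted object
#'
#' Absolute signed sum of origin tetrahedra over the triangles; requires a
#' watertight, consistently oriented mesh.
#'
#' @param mesh a [faceted_object()].
#' @return Volume in um^3.
#' @export
volume3d <- function(mesh) {
  stopifnot(inherits(mesh, "faceted_object"))
  if (!is_watertight(mesh)) abort("volume3d needs a watertight mesh")
  mesh_volume(mesh)
}

#' Surface complexity of a faceted object
#'
#' Dimensionless reciprocal sphericity: the surface area divided by the area
#' of the sphere of equal volume,
#' `A / (pi^(1/3) * (6 V)^(2/3))`. Exactly 1 for a perfect sphere and larger
#' for any other shape, rising with contour irregularity (lobes, coalescence
#' necks, protrusions).
#'
#' @param mesh a watertight [faceted_object()] with positive volume.
#' @return Complexity value (>= 1 up to mesh tolerance).
#' @export
surface_complexity <- function(mesh) {
  stopifnot(inherits(mesh, "faceted_object"))
  v <- mesh_volume(mesh)
  if (v <= 0) abort("degenerate (zero-volume) mesh")
  mesh_area(mesh) / (pi^(1 / 3) * (6 * v)^(2 / 3))
}

#' Percent original aggregate number
#'
#' `100 * N(t) / N(t0)`, where `N(t)` counts live tracks at `t` (entered
#' tracks count from their entry frame) and `N(t0)` counts the initial
#' tracks, excluding founders that exited before contributing at least two
#' frames. This is the aggregate-count parameter corrected for field-edge
#' entries and exits.
#'
#' @param tracks a track table (see [track_objects()]).
#' @param t time in minutes, on the acquisition grid.
#' @return Percent (100 at `t0` when no immediate exits occur).
#' @export
percent_original <- function(tracks, t) {
  if (!nrow(tracks)) abort("no initial aggregates (N(t0) = 0)")
  t0 <- min(tracks$time_min)
  at0 <- unique(tracks$lineage_id[tracks$time_min == t0 &
                                    tracks$status == "present"])
  t_last <- max(tracks$time_min)
  short_exit <- vapply(at0, function(id) {
    pres <- tracks$time_min[tracks$lineage_id == id &
                              tracks$status == "present"]
    length(pres) < 2 && max(pres) < t_last
  }, TRUE)
  n0 <- sum(!short_exit)
  if (n0 == 0) abort("no initial aggregates (N(t0) = 0)")
  nt <- length(unique(tracks$lineage_id[tracks$time_min == t &
                                          tracks$status == "present"]))
  100 * nt / n0
}

#' Per-timepoint 3D parameter suite
#'
#' Summarizes tracks, meshes and events into the per-timepoint parameter
#' table: aggregate count, percent original aggregate number, mean volume
#' (um^3), mean surface complexity, and mean 3D speed (um/hr), each averaged
#' over the live tracks at that timepoint.
#'
#' @param tracks a track table or `lineage_tracks` object.
#' @param meshes optional tibble `(time_min, object, complexity,
#'   volume_um3)` of per-object mesh measures, as produced by
#'   [run_pipeline()]; when absent, complexity is `NA` and volumes come from
#'   the track table.
#' @param events optional event table (unused in the means; carried through
#'   for provenance).
#' @return A `metric_series` tibble: `time_min`, `n_aggregates`,
#'   `pct_original`, `mean_volume_um3`, `mean_complexity`,
#'   `mean_speed_um_hr`.
#' @export
summarize_metrics <- function(tracks, meshes = NULL, events = NULL) {
  if (inherits(tracks, "lineage_tracks")) {
    if (is.null(events)) events <- tracks$events
    tracks <- tracks$tracks
  }
  if (!nrow(tracks)) abort("empty track table")
  times <- sort(unique(tracks$time_min))
  live <- tracks[tracks$status == "present", , drop = FALSE]
  # instantaneous speeds per lineage
  sp <- live |>
    dplyr::group_by(.data$lineage_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::mutate(speed_um_hr = c(
      NA_real_,
      sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2 + diff(.data$z_um)^2) /
        (diff(.data$time_min) / 60))) |>
    dplyr::ungroup()
  if (!is.null(meshes) && nrow(meshes)) {
    sp <- dplyr::left_join(sp, meshes, by = c("time_min", "object"),
                           suffix = c("", "_mesh"))
    if ("volume_um3_mesh" %in% names(sp)) {
      sp$volume_um3 <- dplyr::coalesce(sp$volume_um3_mesh, sp$volume_um3)
    }
  } else {
    sp$complexity <- NA_real_
  }
  out <- sp |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      n_aggregates = dplyr::n_distinct(.data$lineage_id),
      mean_volume_um3 = mean(.data$volume_um3, na.rm = TRUE),
      mean_complexity = mean(.data$complexity, na.rm = TRUE),
      mean_speed_um_hr = mean(.data$speed_um_hr, na.rm = TRUE),
      .groups = "drop")
  out$pct_original <- vapply(out$time_min,
                             function(t) percent_original(tracks, t), 1)
  out <- out[, c("time_min", "n_aggregates", "pct_original",
                 "mean_volume_um3", "mean_complexity",
                 "mean_speed_um_hr")]
  out <- out[match(times, out$time_min), , drop = FALSE]
  class(out) <- c("metric_series", class(out))
  out
}

#' Plot a metric series
#'
#' Four-panel summary of the parameter suite over time: percent original
#' aggregate number, mean volume, mean surface complexity and mean speed.
#'
#' @param object a `metric_series` from [summarize_metrics()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.metric_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_min", "pct_original",
                                  "mean_volume_um3", "mean_complexity",
                                  "mean_speed_um_hr")],
    -"time_min", names_to = "parameter", values_to = "value")
  lab <- c(pct_original = "percent original aggregate number (%)",
           mean_volume_um3 = "mean aggregate volume (µm³)",
           mean_complexity = "mean surface complexity",
           mean_speed_um_hr = "mean 3D speed (µm/hr)")
  long$parameter <- factor(lab[long$parameter], levels = unname(lab))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min / 60, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time (hr)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 3D track path as projections
#'
#' @param track tibble with `time_min`, `x_um`, `y_um`, `z_um`.
#' @return A ggplot object (x-y path colored by time, with z shown by point
#'   size).
#' @export
plot_track_path <- function(track) {
  ggplot2::ggplot(track,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               color = .data$time_min / 60)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(size = .data$z_um), alpha = 0.6) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  color = "time (hr)", size = "z (µm)") +
    ggplot2::theme_minimal()
}
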