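#' Acquisition plan arithmetic
#'
#' Counting uses the interval convention at both axes: a 1500 um column
#' sectioned at 10 um steps gives 150 optical sections, and 17 days re-imaged
#' every 30 minutes gives 816 timepoints, for 122,400 sections per
#' preparation.
#'
#' @param z_depth total sectioned depth, um.
#' @param z_step z increment, um (`<= z_depth`).
#' @param t_interval minutes between reconstructions (`<= duration`).
#' @param duration total recording time, minutes.
#' @return An `acquisition_plan` list.
#' @examples
#' plan <- acquisition_plan(1500, 10, 30, 17 * 24 * 60)
#' n_slices(plan)       # 150
#' n_timepoints(plan)   # 816
#' total_sections(plan) # 122400
#' @export
acquisition_plan <- function(z_depth, z_step, t_interval, duration) {
  assert_scalar_num(z_depth, "z_depth", positive = TRUE)
  assert_scalar_num(z_step, "z_step", positive = TRUE)
  assert_scalar_num(t_interval, "t_interval", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  if (z_step > z_depth) abort("`z_step` must be <= `z_depth`")
  if (t_interval > duration) abort("`t_interval` must be <= `duration`")
  structure(list(z_depth = z_depth, z_step = z_step,
                 t_interval = t_interval, duration = duration),
            class = "acquisition_plan")
}

#' @param plan an [acquisition_plan()].
#' @rdname acquisition_plan
#' @export
n_slices <- function(plan) {
  stopifnot(inherits(plan, "acquisition_plan"))
  as.integer(floor(plan$z_depth / plan$z_step))
}

#' @rdname acquisition_plan
#' @export
n_timepoints <- function(plan) {
  stopifnot(inherits(plan, "acquisition_plan"))
  as.integer(floor(plan$duration / plan$t_interval))
}

#' @rdname acquisition_plan
#' @export
total_sections <- function(plan) {
  n_slices(plan) * n_timepoints(plan)
}

#' Read / write a run configuration
#'
#' The run configuration is a plain YAML hierarchy (calibration, detection,
#' meshing, tracking parameters, seed, output directory). Serialization
#' round-trips identically.
#'
#' @param path YAML file path.
#' @param config named list.
#' @return `read_config()`: the configuration list. `write_config()`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

default_run_config <- function() {
  list(
    detect = list(radius = 2, threshold = "auto", floor_factor = 4,
                  closing_radius = 2, opening_radius = 1, min_area = 50),
    mesh = list(block_size = 4, smooth_iterations = 10, min_voxels = 8),
    track = list(gate = 50, tau = 0.3, volume_factor = 0.6, margin = 20,
                 reentry_window = 10),
    seed = 1L)
}

#' Write / read a calibrated stack as multi-page TIFF
#'
#' Pages are ordered timepoint-major then z (T-Z-Y-X); calibration travels
#' in a YAML sidecar (`<stem>.calibration.yaml`) with `pixel_size`,
#' `z_step`, `t_step`, `n_z`, `n_t`.
#'
#' @param stack a [calibrated_stack()].
#' @param path TIFF file path.
#' @return `write_stack_tiff()`: `path` invisibly; `read_stack_tiff()`: a
#'   [calibrated_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  p <- 1L
  for (ti in seq_len(d[4])) {
    for (k in seq_len(d[3])) {
      pages[[p]] <- pmin(pmax(stack$data[, , k, ti], 0), 1)
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  side <- sub("\\.tiff?$", "", path)
  yaml::write_yaml(list(pixel_size = stack$pixel_size,
                        z_step = stack$z_step, t_step = stack$t_step,
                        n_z = d[3], n_t = d[4]),
                   paste0(side, ".calibration.yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  side <- paste0(sub("\\.tiff?$", "", path), ".calibration.yaml")
  if (!file.exists(side)) {
    abort(sprintf("missing calibration sidecar: %s", side))
  }
  cal <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != cal$n_z * cal$n_t) {
    abort(sprintf(
      "corrupt or partial stack: %d pages found, %d x %d expected",
      length(pages), cal$n_z, cal$n_t))
  }
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], cal$n_z, cal$n_t))
  p <- 1L
  for (ti in seq_len(cal$n_t)) {
    for (k in seq_len(cal$n_z)) {
      arr[, , k, ti] <- pages[[p]]
      p <- p + 1L
    }
  }
  calibrated_stack(arr, cal$pixel_size, cal$z_step, cal$t_step)
}

#' Run the full detection / reconstruction / tracking / metrics chain
#'
#' Executes [detect_stack()] on every timepoint, groups the slice bitmaps
#' into voxel objects ([group_slices()]), builds smoothed faceted models
#' ([skeleton_climb()] + [smooth_mesh()]), tracks objects through time with
#' coalescence and field-edge bookkeeping ([track_objects()]), and
#' summarizes the 3D parameter suite ([summarize_metrics()]). When `outdir`
#' is given, writes `metrics.csv`, `tracks.csv`, `events.csv`,
#' `events.json`, per-object PLY meshes (`t{tttt}_obj{label}.ply`) and a
#' `manifest.json` listing every output file with its MD5 content hash, the
#' configuration hash, package version and seed. Deterministic given
#' identical config and inputs.
#'
#' @param stack a [calibrated_stack()] or a TIFF path readable by
#'   [read_stack_tiff()].
#' @param config configuration list (see `default_run_config()` for the
#'   shape); missing entries take defaults.
#' @param outdir optional output directory (created if needed).
#' @return A `pipeline_result` list: `objects` (per-timepoint voxel-object
#'   lists), `meshes` (tibble: `time_min, object, volume_um3, complexity`),
#'   `tracking` (a `lineage_tracks`), `metrics` (a `metric_series`),
#'   `config`, `files`.
#' @export
run_pipeline <- function(stack, config = list(), outdir = NULL) {
  if (is.character(stack)) stack <- read_stack_tiff(stack)
  stopifnot(inherits(stack, "calibrated_stack"))
  cfg <- utils::modifyList(default_run_config(), config)
  d <- dim(stack$data)
  bits <- detect_stack(stack, radius = cfg$detect$radius,
                       threshold = cfg$detect$threshold,
                       floor_factor = cfg$detect$floor_factor,
                       closing_radius = cfg$detect$closing_radius,
                       opening_radius = cfg$detect$opening_radius,
                       min_area = cfg$detect$min_area)
  nt <- d[4]
  frames <- vector("list", nt)
  mesh_rows <- list()
  mesh_objs <- list()
  for (ti in seq_len(nt)) {
    frames[[ti]] <- group_slices(bits$bitmaps[[ti]],
                                 pixel_size = stack$pixel_size,
                                 z_step = stack$z_step, timepoint = ti,
                                 min_voxels = cfg$mesh$min_voxels)
    for (ob in frames[[ti]]) {
      mesh <- skeleton_climb(ob, block_size = cfg$mesh$block_size)
      if (cfg$mesh$smooth_iterations > 0) {
        mesh <- smooth_mesh(mesh, cfg$mesh$smooth_iterations)
      }
      mesh_rows[[length(mesh_rows) + 1]] <- tibble::tibble(
        time_min = stack$times[ti], object = ob$label,
        volume_um3 = mesh_volume(mesh),
        complexity = surface_complexity(mesh))
      mesh_objs[[length(mesh_objs) + 1]] <- mesh
    }
  }
  meshes <- if (length(mesh_rows)) dplyr::bind_rows(mesh_rows) else
    tibble::tibble(time_min = numeric(), object = integer(),
                   volume_um3 = numeric(), complexity = numeric())
  field_bounds <- c(d[2] * stack$pixel_size, d[1] * stack$pixel_size,
                    d[3] * stack$z_step)
  tracking <- track_objects(frames, stack$times,
                            field_bounds = field_bounds,
                            gate = cfg$track$gate, tau = cfg$track$tau,
                            volume_factor = cfg$track$volume_factor,
                            margin = cfg$track$margin,
                            reentry_window = cfg$track$reentry_window)
  metrics <- summarize_metrics(tracking$tracks, meshes = meshes,
                               events = tracking$events)
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      p <- file.path(outdir, name)
      utils::write.csv(as.data.frame(df), p, row.names = FALSE)
      p
    }
    files <- c(files,
               wcsv(metrics, "metrics.csv"),
               wcsv(tracking$tracks, "tracks.csv"),
               wcsv(tracking$events, "events.csv"))
    pj <- file.path(outdir, "events.json")
    jsonlite::write_json(tracking$events, pj, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, pj)
    for (mesh in mesh_objs) {
      p <- file.path(outdir, sprintf("t%04d_obj%d.ply", mesh$timepoint,
                                     mesh$label))
      write_ply(mesh, p)
      files <- c(files, p)
    }
    cfg_yaml <- yaml::as.yaml(cfg)
    manifest <- list(
      package = "dic4d",
      version = as.character(utils::packageVersion("dic4d")),
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(
        textConnection_md5(cfg_yaml))),
      files = lapply(files, function(p) {
        list(path = basename(p), md5 = unname(tools::md5sum(p)))
      }))
    pm <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, pm)
  }
  structure(list(objects = frames, meshes = meshes, tracking = tracking,
                 metrics = metrics, config = cfg, files = files),
            class = "pipeline_result")
}

# md5 of a string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(text) {
  tf <- tempfile()
  writeLines(text, tf)
  tf
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d timepoints, %d meshes, %d events\n",
    length(x$objects), nrow(x$meshes), nrow(x$tracking$events)))
  invisible(x)
}
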