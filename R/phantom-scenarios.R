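#' Canned validation scenarios
#'
#' Pre-scripted scenes exercising the behaviors the pipeline must recover,
#' at a desk-scale geometry (256 x 256 x 400 um at 4 um/px and 10 um
#' z-steps, 30-minute frames, 20 timepoints = 64 x 64 x 40 voxels).
#'
#' `scenario_coalescence()`: nine aggregates in two z-layers of which eight
#' coalesce over the run through six scripted merges (the ninth never
#' participates), emulating a strongly coalescing tumorigenic preparation.
#'
#' `scenario_static()`: non-coalescing control - round aggregates that grow
#' slowly in place and never merge, so count and surface complexity stay
#' flat while volume rises.
#'
#' `scenario_edge_events()`: thirteen initial aggregates of which three
#' drift out through field faces and two more enter from outside, with no
#' merges - the field-edge bookkeeping case.
#'
#' @param seed scene seed.
#' @return A [scene_script()].
#' @export
scenario_coalescence <- function(seed = 17L) {
  objs <- list(
    object_script(1, c(60, 60, 120), 18,
                  merge_with = list(partner = 5, time = 120)),
    object_script(2, c(196, 60, 120), 18,
                  merge_with = list(partner = 5, time = 210)),
    object_script(3, c(60, 196, 120), 18,
                  merge_with = list(partner = 5, time = 300)),
    object_script(4, c(196, 196, 120), 18,
                  merge_with = list(partner = 5, time = 390)),
    object_script(5, c(128, 128, 120), 20),
    object_script(6, c(128, 60, 280), 18,
                  merge_with = list(partner = 7, time = 150)),
    object_script(7, c(60, 128, 280), 18),
    object_script(8, c(128, 196, 280), 18,
                  merge_with = list(partner = 7, time = 240)),
    object_script(9, c(196, 128, 280), 18))
  scene_script(objects = objs, field_size = c(256, 256, 400),
               pixel_size = 4, z_step = 10, t_step = 30, duration = 600,
               approach_min = 120, contact_factor = 0.95, seed = seed)
}

#' @rdname scenario_coalescence
#' @export
scenario_static <- function(seed = 23L) {
  pos <- rbind(c(64, 64, 120), c(192, 64, 120), c(64, 192, 280),
               c(192, 192, 280), c(128, 128, 200))
  objs <- lapply(seq_len(nrow(pos)), function(i) {
    object_script(i, pos[i, ], 18, growth = 0.6)
  })
  scene_script(objects = objs, field_size = c(256, 256, 400),
               pixel_size = 4, z_step = 10, t_step = 30, duration = 600,
               seed = seed)
}

#' @rdname scenario_coalescence
#' @export
scenario_edge_events <- function(seed = 31L) {
  # 13 in-field aggregates on a loose grid; 3 drift out through the -x, +x
  # and +y faces; 2 start outside and drift in. 320 x 320 x 400 um field.
  grid <- expand.grid(x = c(60, 160, 260), y = c(60, 160, 260),
                      z = c(120, 280))
  grid <- grid[seq_len(13), ]
  objs <- vector("list", 15)
  for (i in seq_len(13)) {
    objs[[i]] <- object_script(i, as.numeric(grid[i, ]), 18)
  }
  # exits: overwrite three of the outer positions with outbound drifters
  objs[[1]] <- object_script(1, c(60, 60, 120), 18, motion = "drift",
                             velocity = c(-12, 0, 0))
  objs[[3]] <- object_script(3, c(260, 60, 120), 18, motion = "drift",
                             velocity = c(12, 0, 0))
  objs[[9]] <- object_script(9, c(260, 260, 120), 18, motion = "drift",
                             velocity = c(0, 12, 0))
  # entries: start fully outside, drift inward along unoccupied lanes
  objs[[14]] <- object_script(14, c(-40, 110, 200), 18, motion = "drift",
                              velocity = c(20, 0, 0))
  objs[[15]] <- object_script(15, c(360, 210, 200), 18, motion = "drift",
                              velocity = c(-20, 0, 0))
  scene_script(objects = objs, field_size = c(320, 320, 400),
               pixel_size = 4, z_step = 10, t_step = 30, duration = 600,
               seed = seed)
}
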