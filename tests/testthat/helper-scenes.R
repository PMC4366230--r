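# shared scene fixtures; expensive pipeline runs are computed once per test
# session and reused across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# one stationary sphere, desk scale
scene_one_sphere <- function(radius = 30, seed = 3L) {
  scene_script(
    objects = list(object_script(1, centroid = c(100, 100, 100),
                                 radius = radius)),
    field_size = c(200, 200, 200), pixel_size = 2, z_step = 10,
    t_step = 30, duration = 30, seed = seed)
}

# two well-separated spheres that coalesce at 150 min
scene_two_merge <- function(seed = 11L) {
  scene_script(
    objects = list(
      object_script(1, centroid = c(70, 128, 200), radius = 22),
      object_script(2, centroid = c(170, 128, 200), radius = 20,
                    merge_with = list(partner = 1, time = 150))),
    field_size = c(256, 256, 400), pixel_size = 4, z_step = 10,
    t_step = 30, duration = 270, seed = seed)
}

run_scene <- function(script) {
  run_pipeline(render_dic(build_scene(script)))
}

coalescence_run <- function() {
  cached("coalescence", function() {
    sc <- scenario_coalescence()
    truth <- build_scene(sc)
    list(truth = truth, result = run_pipeline(render_dic(truth)))
  })
}

static_run <- function() {
  cached("static", function() {
    sc <- scenario_static()
    truth <- build_scene(sc)
    list(truth = truth, result = run_pipeline(render_dic(truth)))
  })
}

edge_run <- function() {
  cached("edge", function() {
    sc <- scenario_edge_events()
    truth <- build_scene(sc)
    list(truth = truth, result = run_pipeline(render_dic(truth)))
  })
}

two_merge_run <- function() {
  cached("two_merge", function() {
    sc <- scene_two_merge()
    truth <- build_scene(sc)
    list(truth = truth, result = run_pipeline(render_dic(truth)))
  })
}

# distinct founders appearing in confirmed merge events
absorbed_founders <- function(events) {
  mg <- events[events$type == "merge", ]
  unique(unlist(strsplit(unlist(strsplit(mg$participants, "+",
                                         fixed = TRUE)),
                         "/", fixed = TRUE)))
}
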