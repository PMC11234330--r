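# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default-grid microtrap and its solved fields at the two study flow rates
trap_dm <- function() cached("trap_dm", build_microtrap())

trap_field <- function(rate) {
  cached(paste0("trap_field_", rate),
         solve_depth_averaged(trap_dm(), rate))
}

# a coarse microtrap for cheap geometry/occupancy work
trap_dm_coarse <- function() {
  cached("trap_dm_coarse",
         build_microtrap(microtrap_spec(), channel_spec(grid_spacing = 4)))
}

# small plain channel and a uniform synthetic field on it
plain_dm <- function() {
  cached("plain_dm",
         build_channel(channel_spec(grid_spacing = 2), area = c(200, 100)))
}

# a short uniform-flow tracer video with ground truth (for tracking tests)
short_video <- function() {
  cached("short_video", {
    ch <- channel_spec(grid_spacing = 2)
    dm <- build_channel(ch, area = c(400, 140))
    U <- mean_velocity(0.5, ch) # ~111 um/s
    fld <- uniform_flow_field(dm, u = U)
    optics <- optics_spec(frame_count = 80, frame_rate = 25)
    traj <- advect(fld, particle_spec(diameter = 2), n_particles = 120,
                   duration = 80 / 25, dt = 0.01, rng_seed = 42,
                   start = tibble::tibble(x = runif_seeded(120, 0, 400, 7),
                                          y = runif_seeded(120, 5, 135, 8)),
                   record_every = 4L)
    render_video(traj, optics, origin = c(100, 5), dim_px = c(256, 180),
                 rng_seed = 43)
  })
}

runif_seeded <- function(n, lo, hi, seed) {
  r <- NULL
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  r <- runif(n, lo, hi)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  r
}

# render one or more static spots without noise into a single frame
render_spots_frame <- function(pos_px, optics = optics_spec(frame_count = 1),
                              dim_px = c(64, 64), amp = 120) {
  img <- matrix(optics$background, dim_px[2], dim_px[1])
  for (m in seq_len(nrow(pos_px))) {
    sg <- optics$psf_sigma
    cx <- pos_px$x[m]; cy <- pos_px$y[m]
    rr <- seq_len(dim_px[2]); cc <- seq_len(dim_px[1])
    img <- img + amp * outer(exp(-(rr - cy)^2 / (2 * sg^2)),
                             exp(-(cc - cx)^2 / (2 * sg^2)))
  }
  img
}
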