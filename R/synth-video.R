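#' Render a fluorescence video from particle trajectories
#'
#' Simulates an epifluorescence recording of tracer microspheres: each
#' particle becomes an isotropic Gaussian spot whose integrated intensity
#' scales with diameter cubed (fluorophore volume), optionally widened with
#' defocus |z - z_focus|; Poisson shot noise and Gaussian read noise are
#' added on top of a constant background and the result is clipped to the
#' camera bit depth.
#'
#' @param traj A `trajectory_set` from [advect()] (positions in um). Must
#'   cover the requested time span `frame_count / frame_rate`.
#' @param optics An [optics_spec()].
#' @param origin Physical coordinates (um) mapped to the corner of pixel
#'   (1, 1); defaults to the trajectory domain origin implied by the data.
#' @param dim_px Length-2 integer, frame size `c(width, height)` in px.
#' @param peak_intensity Peak counts of an in-focus spot of a 2 um particle;
#'   scales with `(diameter/2)^3`.
#' @param z_focus Focal plane height in um, or `NULL` to disable defocus.
#' @param defocus_rate PSF widening per um of defocus (fraction of
#'   `psf_sigma`).
#' @param shot_noise Add Poisson shot noise?
#' @param rng_seed Seed for the noise; `NULL` uses the current RNG state.
#' @return A `frame_stack`: list with `frames` (list of numeric matrices,
#'   rows = y), `optics`, `timestamps` (s), and `truth`, a tibble of the
#'   rendered ground-truth spot positions per frame (`frame`, `particle`,
#'   `x_px`, `y_px`, `x`, `y`, `z`) enabling tracking parameter-recovery
#'   tests.
#' @export
render_video <- function(traj, optics = optics_spec(), origin = NULL,
                         dim_px = c(256, 192), peak_intensity = 120,
                         z_focus = NULL, defocus_rate = 0.1,
                         shot_noise = TRUE, rng_seed = NULL) {
  ps <- optics$pixel_size
  t_frames <- (seq_len(optics$frame_count) - 1) / optics$frame_rate
  if (nrow(traj) && max(traj$t) < t_frames[length(t_frames)] - 1e-9) {
    stop("trajectories do not cover the requested time span", call. = FALSE)
  }
  origin <- origin %||% c(min(traj$x %||% 0, 0), min(traj$y %||% 0, 0))
  nxp <- dim_px[1]; nyp <- dim_px[2]
  spec <- attr(traj, "particle_spec") %||% particle_spec()
  amp <- peak_intensity * (spec$diameter / 2)^3 / (2 / 2)^3

  # interpolate each particle's path to the frame times
  truth <- if (nrow(traj) == 0) {
    tibble::tibble(frame = integer(), particle = integer(), x_px = double(),
                   y_px = double(), x = double(), y = double(), z = double())
  } else {
    traj |>
      dplyr::filter(!.data$exited) |>
      dplyr::group_by(.data$particle) |>
      dplyr::reframe(
        frame = which(t_frames >= min(.data$t) - 1e-9 &
                        t_frames <= max(.data$t) + 1e-9),
        x = interp_path(.data$t, .data$x, t_frames[frame]),
        y = interp_path(.data$t, .data$y, t_frames[frame]),
        z = interp_path(.data$t, .data$z, t_frames[frame])
      ) |>
      dplyr::mutate(x_px = (.data$x - origin[1]) / ps + 0.5,
                    y_px = (.data$y - origin[2]) / ps + 0.5) |>
      dplyr::filter(.data$x_px >= 1, .data$x_px <= nxp,
                    .data$y_px >= 1, .data$y_px <= nyp)
  }

  render <- function() {
    frames <- vector("list", optics$frame_count)
    for (f in seq_len(optics$frame_count)) {
      img <- matrix(optics$background, nyp, nxp)
      tf <- truth[truth$frame == f, ]
      for (m in seq_len(nrow(tf))) {
        sg <- optics$psf_sigma
        amp_m <- amp
        if (!is.null(z_focus)) {
          sg <- sg * (1 + defocus_rate * abs(tf$z[m] - z_focus))
          # defocus spreads a fixed integrated intensity: peak dims as 1/sg^2
          amp_m <- amp * (optics$psf_sigma / sg)^2
        }
        wr <- ceiling(4 * sg)
        cx <- tf$x_px[m]; cy <- tf$y_px[m]
        c0 <- max(1, floor(cx) - wr); c1 <- min(nxp, floor(cx) + wr)
        r0 <- max(1, floor(cy) - wr); r1 <- min(nyp, floor(cy) + wr)
        if (c0 > c1 || r0 > r1) next
        cc <- c0:c1; rr <- r0:r1
        g <- outer(exp(-(rr - cy)^2 / (2 * sg^2)),
                   exp(-(cc - cx)^2 / (2 * sg^2)))
        img[rr, cc] <- img[rr, cc] + amp_m * g
      }
      if (shot_noise) img[] <- rpois(length(img), pmax(img, 0))
      if (optics$noise_sigma > 0) {
        img[] <- img + rnorm(length(img), 0, optics$noise_sigma)
      }
      if (shot_noise || optics$noise_sigma > 0) {
        img[] <- pmin(pmax(round(img), 0), 2^optics$bit_depth - 1)
      }
      frames[[f]] <- img
    }
    frames
  }
  frames <- if (is.null(rng_seed)) render() else with_seed(rng_seed, render())

  structure(
    list(frames = frames, optics = optics, timestamps = t_frames,
         origin = origin, truth = dplyr::select(
           truth, "frame", "particle", "x_px", "y_px", "x", "y", "z")),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g Hz, %g um/px\n",
              length(x$frames), d[2], d[1], x$optics$frame_rate,
              x$optics$pixel_size))
  invisible(x)
}

#' Synthesize a tracer video of uniform channel flow
#'
#' Convenience generator for velocimetry validation: seeds tracer particles
#' throughout a long plain-channel domain carrying uniform flow at the mean
#' velocity of the given pump rate, advects them (Brownian motion included)
#' and renders the fluorescence recording over a fixed field of view, with
#' ground truth attached.
#'
#' @param flow_rate Pump rate in uL min^-1 (sets the mean velocity through
#'   [mean_velocity()]).
#' @param optics An [optics_spec()]; its frame count/rate set the duration.
#' @param dim_px Field of view in px `c(width, height)`.
#' @param particle A [particle_spec()].
#' @param n_particles Number of particles seeded over the whole domain (the
#'   domain is long enough that particles keep entering the field of view).
#' @param rng_seed Integer seed for trajectories and camera noise.
#' @return A `frame_stack` with ground truth.
#' @export
synthesize_uniform_flow_video <- function(flow_rate = 0.5,
                                          optics = optics_spec(),
                                          dim_px = c(256, 192),
                                          particle = particle_spec(diameter = 2),
                                          n_particles = NULL,
                                          rng_seed = 1) {
  U <- mean_velocity(flow_rate)
  duration <- optics$frame_count / optics$frame_rate
  fov <- dim_px * optics$pixel_size
  Lx <- U * duration + fov[1] + 20 # particles drift through the FOV
  Ly <- fov[2] + 10
  ch <- channel_spec(grid_spacing = 2)
  dm <- build_channel(ch, area = c(Lx, Ly))
  fld <- uniform_flow_field(dm, u = U)
  n_particles <- n_particles %||%
    ceiling(0.75 * dim_px[1] * Lx / fov[1] / 10) # ~ tens in view per frame
  steps_per_frame <- 4L
  dt <- 1 / optics$frame_rate / steps_per_frame
  start <- with_seed(rng_seed + 1L, tibble::tibble(
    x = runif(n_particles, 0, Lx),
    y = runif(n_particles, 5, Ly - 5)
  ))
  traj <- advect(fld, particle, n_particles = n_particles,
                 duration = duration, dt = dt, rng_seed = rng_seed,
                 start = start, record_every = steps_per_frame)
  render_video(traj, optics, origin = c(10, 5), dim_px = dim_px,
               rng_seed = rng_seed + 2L)
}

# linear interpolation of a sampled path (constant for single samples)
interp_path <- function(t, v, tout) {
  if (length(tout) == 0) return(numeric(0))
  if (length(t) < 2) return(rep(v[1], length(tout)))
  approx(t, v, tout, rule = 2)$y
}

#' Extract one frame of a stack
#'
#' @param stack A `frame_stack`.
#' @param i Frame index.
#' @return A numeric matrix (rows = y).
#' @export
get_frame <- function(stack, i) stack$frames[[i]]

#' Write a frame stack as a multi-page TIFF
#'
#' @param stack A `frame_stack`.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_frame_stack <- function(stack, path) {
  maxv <- 2^stack$optics$bit_depth - 1
  tiff::writeTIFF(lapply(stack$frames, function(f) pmin(pmax(f / maxv, 0), 1)),
                  path, bits.per.sample = stack$optics$bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path A `.tif` path.
#' @param optics An [optics_spec()] describing the acquisition.
#' @return A `frame_stack` (without ground truth).
#' @export
read_frame_stack <- function(path, optics = optics_spec()) {
  maxv <- 2^optics$bit_depth - 1
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) f * maxv)
  structure(
    list(frames = frames, optics = optics,
         timestamps = (seq_along(frames) - 1) / optics$frame_rate,
         origin = c(0, 0), truth = NULL),
    class = "frame_stack"
  )
}
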