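#' Advect tracer particles through a flow field
#'
#' Euler-Maruyama integration of passive tracer particles (microsphere or
#' bacterium surrogates) through a plan-view flow field:
#' `x <- x + u dt + sqrt(2 D dt) xi` in the plane, with the diffusion
#' coefficient from Stokes-Einstein unless overridden, plus gravitational
#' settling in z (2.5-D composition: the in-plane field is depth-averaged,
#' the vertical coordinate only feels settling and wall/lid reflection; an
#' approximation that neglects vertical advection). Walls are reflective:
#' particles may pass over features whose clearance exceeds their diameter,
#' while moves into cells with clearance below the particle diameter are
#' rejected (specular side-wall collision). The downstream boundary absorbs;
#' other domain edges reflect.
#'
#' @param field A plan-view `flow_field` from [solve_depth_averaged()].
#' @param spec A [particle_spec()].
#' @param n_particles Number of particles.
#' @param duration Simulated time in s.
#' @param dt Time step in s; must satisfy `dt <= grid_spacing / max speed`.
#' @param rng_seed Integer seed (trajectories are reproducible given it).
#' @param start Optional tibble of starting positions (`x`, `y`, optionally
#'   `z`); defaults to uniform seeding over the upstream 10% of the domain,
#'   full width, at mid-height.
#' @param record_every Record positions every this many steps (the start and
#'   final states are always recorded).
#' @return A `trajectory_set`: a tibble with `particle`, `t`, `x`, `y`, `z`
#'   (um) and `exited`, carrying the particle spec, seed and dt as
#'   attributes.
#' @export
advect <- function(field, spec = particle_spec(), n_particles = 100,
                   duration = 1, dt = 1e-3, rng_seed = 1, start = NULL,
                   record_every = 1L) {
  stopifnot(identical(field$plane, "xy"))
  depth <- field$depth
  ds <- field$spacing
  vmax <- max(sqrt(field$u^2 + field$v^2))
  if (vmax > 0 && dt > ds / vmax) {
    stop(sprintf(
      "dt = %g s violates the advection guard dt <= spacing/max speed = %g s",
      dt, ds / vmax), call. = FALSE)
  }
  origin <- depth$origin
  xmax <- origin[1] + ncol(field$u) * ds
  ymax <- origin[2] + nrow(field$u) * ds
  H <- depth$channel_height
  r <- spec$diameter / 2
  D <- spec$diffusivity_override %||%
    stokes_einstein_diffusivity(spec$diameter, field$fluid)
  w_settle <- settling_velocity(spec$diameter, spec$density, field$fluid)

  n_steps <- ceiling(duration / dt)
  record_at <- unique(c(seq(0L, n_steps, by = record_every), n_steps))

  clearance_at <- function(x, y) {
    j <- pmin(pmax(ceiling((x - origin[1]) / ds), 1), ncol(depth$h))
    i <- pmin(pmax(ceiling((y - origin[2]) / ds), 1), nrow(depth$h))
    depth$h[cbind(i, j)]
  }

  with_seed(rng_seed, {
    if (is.null(start)) {
      x <- runif(n_particles, origin[1], origin[1] + 0.1 * (xmax - origin[1]))
      y <- runif(n_particles, origin[2], ymax)
      z <- rep(H / 2, n_particles)
    } else {
      x <- rep_len(start$x, n_particles)
      y <- rep_len(start$y, n_particles)
      z <- if ("z" %in% names(start)) rep_len(start[["z"]], n_particles) else
        rep(H / 2, n_particles)
    }
    exited <- rep(FALSE, n_particles)
    sig <- sqrt(2 * D * dt)
    rec <- vector("list", length(record_at))
    ri <- 1L
    rec[[ri]] <- tibble::tibble(particle = seq_len(n_particles), t = 0,
                                x = x, y = y, z = z, exited = exited)
    for (s in seq_len(n_steps)) {
      act <- which(!exited)
      if (length(act)) {
        ua <- interp_bilinear(field$u, x[act], y[act], origin, ds)
        va <- interp_bilinear(field$v, x[act], y[act], origin, ds)
        nx_ <- x[act] + ua * dt + if (D > 0) rnorm(length(act), 0, sig) else 0
        ny_ <- y[act] + va * dt + if (D > 0) rnorm(length(act), 0, sig) else 0
        nz_ <- z[act] - w_settle * dt +
          if (D > 0) rnorm(length(act), 0, sig) else 0
        # side-domain reflection; downstream absorbs
        ny_ <- ifelse(ny_ < origin[2], 2 * origin[2] - ny_, ny_)
        ny_ <- ifelse(ny_ > ymax, 2 * ymax - ny_, ny_)
        nx_ <- ifelse(nx_ < origin[1], 2 * origin[1] - nx_, nx_)
        gone <- nx_ >= xmax
        # reject in-plane moves into cells too shallow for the particle
        ok <- gone | clearance_at(pmin(nx_, xmax - 1e-9), ny_) >= spec$diameter
        nx_ <- ifelse(ok, nx_, x[act]); ny_ <- ifelse(ok, ny_, y[act])
        # vertical reflection between local floor (channel top minus local
        # clearance) and lid
        floor_z <- H - clearance_at(pmin(nx_, xmax - 1e-9), ny_)
        nz_ <- ifelse(nz_ < floor_z + r, 2 * (floor_z + r) - nz_, nz_)
        nz_ <- ifelse(nz_ > H - r, 2 * (H - r) - nz_, nz_)
        nz_ <- pmin(pmax(nz_, floor_z + r), H - r)
        x[act] <- nx_; y[act] <- ny_; z[act] <- nz_
        exited[act] <- gone
      }
      if (s %in% record_at) {
        ri <- ri + 1L
        rec[[ri]] <- tibble::tibble(particle = seq_len(n_particles),
                                    t = s * dt, x = x, y = y, z = z,
                                    exited = exited)
      }
    }
    traj <- dplyr::arrange(dplyr::bind_rows(rec[seq_len(ri)]),
                           .data$particle, .data$t)
    attr(traj, "particle_spec") <- spec
    attr(traj, "rng_seed") <- rng_seed
    attr(traj, "dt") <- dt
    attr(traj, "diffusivity") <- D
    class(traj) <- c("trajectory_set", class(traj))
    traj
  })
}

#' Cavity occupancy statistics of a trajectory set
#'
#' Maps recorded positions onto the cavity label map of a microtrap depth
#' map and summarizes visits, residence times and the trapped fraction at
#' the simulation horizon.
#'
#' @param traj A `trajectory_set` from [advect()].
#' @param depth A `depth_map` with cavity metadata ([build_microtrap()]).
#' @return An `occupancy_stats` list: `per_cavity` (tibble: cavity, particles
#'   visited, total residence time s), `trapped_fraction` (fraction of all
#'   particles inside any cavity at the final recorded time),
#'   `mean_residence` (mean per-particle time spent inside cavities, s).
#' @export
trap_occupancy <- function(traj, depth) {
  lab <- depth$feature$cavities
  if (is.null(lab) || max(lab) == 0) {
    return(structure(list(
      per_cavity = tibble::tibble(cavity = integer(), particles = integer(),
                                  residence_time = double()),
      trapped_fraction = 0, mean_residence = 0
    ), class = "occupancy_stats"))
  }
  ds <- depth$spacing; origin <- depth$origin
  j <- pmin(pmax(ceiling((traj$x - origin[1]) / ds), 1), ncol(lab))
  i <- pmin(pmax(ceiling((traj$y - origin[2]) / ds), 1), nrow(lab))
  cav <- lab[cbind(i, j)]
  cav[traj$exited] <- 0L
  # sample interval per record (assume uniform recording)
  ts <- sort(unique(traj$t))
  dt_rec <- if (length(ts) > 1) stats::median(diff(ts)) else 0
  df <- tibble::tibble(particle = traj$particle, t = traj$t, cavity = cav)
  per_cavity <- df |>
    dplyr::filter(.data$cavity > 0) |>
    dplyr::group_by(.data$cavity) |>
    dplyr::summarise(particles = dplyr::n_distinct(.data$particle),
                     residence_time = dplyr::n() * dt_rec, .groups = "drop")
  final <- df |> dplyr::filter(.data$t == max(.data$t))
  structure(list(
    per_cavity = per_cavity,
    trapped_fraction = mean(final$cavity > 0),
    mean_residence = df |>
      dplyr::group_by(.data$particle) |>
      dplyr::summarise(rt = sum(.data$cavity > 0) * dt_rec) |>
      dplyr::pull(.data$rt) |> mean()
  ), class = "occupancy_stats")
}

#' @export
print.occupancy_stats <- function(x, ...) {
  cat(sprintf("<occupancy_stats> trapped fraction %.3f, mean residence %.3g s\n",
              x$trapped_fraction, x$mean_residence))
  print(x$per_cavity)
  invisible(x)
}

#' @rdname trap_occupancy
#' @param x An `occupancy_stats` object.
#' @param ... Unused.
#' @export
tidy.occupancy_stats <- function(x, ...) x$per_cavity

#' @rdname trap_occupancy
#' @export
glance.occupancy_stats <- function(x, ...) {
  tibble::tibble(trapped_fraction = x$trapped_fraction,
                 mean_residence = x$mean_residence,
                 cavities_visited = nrow(x$per_cavity))
}

#' Mean squared planar displacement of a trajectory set
#'
#' @param traj A `trajectory_set`.
#' @return A tibble with `t` and `msd` (um^2), displacement from each
#'   particle's initial position, averaged over particles.
#' @export
planar_msd <- function(traj) {
  traj |>
    dplyr::group_by(.data$particle) |>
    dplyr::mutate(dx = .data$x - .data$x[1], dy = .data$y - .data$y[1]) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(msd = mean(.data$dx^2 + .data$dy^2), .groups = "drop")
}
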