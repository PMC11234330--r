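#' Vorticity of a flow field
#'
#' Out-of-plane vorticity `omega = dv/dx - du/dy` by centered differences
#' (one-sided at the domain edges), in s^-1. For vertical-slice fields the
#' same expression is evaluated in the slice's (x, z) axes; its magnitude is
#' the in-slice vorticity.
#'
#' @param field A `flow_field`.
#' @return A `scalar_field` of kind `"vorticity"`.
#' @export
vorticity <- function(field) {
  w <- ddx(field$v, field$spacing) - ddy(field$u, field$spacing)
  new_scalar_field(w, "vorticity", field)
}

#' Q-criterion of a flow field
#'
#' The vortex-identification scalar `Q = (||Omega||^2 - ||S||^2) / 2`, half
#' the difference between the squared norms of the rotation-rate and
#' strain-rate tensors of the in-plane velocity gradient, in s^-2. Positive
#' where rotation dominates strain (vortex cores); for rigid rotation at rate
#' w it equals w^2, for simple shear 0, for pure strain at rate g, -g^2.
#'
#' @param field A `flow_field`.
#' @return A `scalar_field` of kind `"q_criterion"`.
#' @export
q_criterion <- function(field) {
  ds <- field$spacing
  ux <- ddx(field$u, ds); uy <- ddy(field$u, ds)
  vx <- ddx(field$v, ds); vy <- ddy(field$v, ds)
  q <- (vx - uy)^2 / 4 - ux^2 / 2 - vy^2 / 2 - (uy + vx)^2 / 4
  new_scalar_field(q, "q_criterion", field)
}

#' Speed field
#'
#' @param field A `flow_field`.
#' @return A `scalar_field` of kind `"speed"` (um s^-1).
#' @export
flow_speed <- function(field) {
  new_scalar_field(sqrt(field$u^2 + field$v^2), "speed", field)
}

new_scalar_field <- function(values, kind, parent) {
  structure(
    list(values = values, kind = kind, plane = parent$plane,
         spacing = parent$spacing,
         origin = if (!is.null(parent$depth)) parent$depth$origin else c(0, 0)),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field %s (%s)> %d x %d, range %.4g .. %.4g\n",
              x$kind, x$plane, ncol(x$values), nrow(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Tidy a scalar field
#'
#' @param x A `scalar_field`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `value`.
#' @export
tidy.scalar_field <- function(x, ...) {
  ds <- x$spacing
  tibble::tibble(
    x = rep(x$origin[1] + (seq_len(ncol(x$values)) - 0.5) * ds,
            each = nrow(x$values)),
    y = rep(x$origin[2] + (seq_len(nrow(x$values)) - 0.5) * ds,
            times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Integrate streamlines through a flow field
#'
#' Fourth-order Runge-Kutta integration of seed points through the
#' (bilinearly interpolated) velocity field until the trajectory leaves the
#' domain, stagnates, or exhausts its step budget.
#'
#' @param field A `flow_field`.
#' @param seeds A data frame / tibble with columns `x`, `y` (um), inside the
#'   domain.
#' @param step Integration step in um (arc-length controlled).
#' @param max_steps Step budget per streamline.
#' @param stop_clearance If set (um), stop a streamline before it enters a
#'   cell whose clearance is below this value (e.g. an effectively
#'   full-height obstacle). `NULL` lets streamlines pass over shallow
#'   features, as the depth-averaged flow does.
#' @return A tibble of polylines: `line`, `s` (step index), `x`, `y`.
#' @export
streamlines <- function(field, seeds, step = NULL, max_steps = 5000,
                        stop_clearance = NULL) {
  ds <- field$spacing
  step <- step %||% (ds / 2)
  origin <- if (!is.null(field$depth)) field$depth$origin else c(0, 0)
  xmax <- origin[1] + ncol(field$u) * ds
  ymax <- origin[2] + nrow(field$u) * ds
  inside <- function(x, y) {
    x >= origin[1] & x <= xmax & y >= origin[2] & y <= ymax
  }
  if (!all(inside(seeds$x, seeds$y))) {
    stop("all seeds must lie inside the domain", call. = FALSE)
  }
  vel <- function(x, y) {
    c(interp_bilinear(field$u, x, y, origin, ds),
      interp_bilinear(field$v, x, y, origin, ds))
  }
  out <- vector("list", nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    px <- numeric(max_steps + 1); py <- numeric(max_steps + 1)
    px[1] <- seeds$x[s]; py[1] <- seeds$y[s]
    np <- 1L
    for (it in seq_len(max_steps)) {
      x <- px[np]; y <- py[np]
      v1 <- vel(x, y); sp <- sqrt(sum(v1^2))
      if (!is.finite(sp) || sp < 1e-12) break # stagnation
      dt <- step / sp
      v2 <- vel(x + v1[1] * dt / 2, y + v1[2] * dt / 2)
      v3 <- vel(x + v2[1] * dt / 2, y + v2[2] * dt / 2)
      v4 <- vel(x + v3[1] * dt, y + v3[2] * dt)
      xn <- x + dt / 6 * (v1[1] + 2 * v2[1] + 2 * v3[1] + v4[1])
      yn <- y + dt / 6 * (v1[2] + 2 * v2[2] + 2 * v3[2] + v4[2])
      if (!inside(xn, yn)) break
      if (!is.null(stop_clearance) && !is.null(field$depth)) {
        dpt <- field$depth
        jj <- pmin(pmax(ceiling((xn - origin[1]) / ds), 1), ncol(dpt$h))
        ii <- pmin(pmax(ceiling((yn - origin[2]) / ds), 1), nrow(dpt$h))
        if (dpt$h[ii, jj] < stop_clearance) break
      }
      np <- np + 1L
      px[np] <- xn; py[np] <- yn
    }
    out[[s]] <- tibble::tibble(line = s, s = seq_len(np),
                               x = px[seq_len(np)], y = py[seq_len(np)])
  }
  dplyr::bind_rows(out)
}

#' Microtrap microvortex metrics
#'
#' Solves the flow over a microtrap and characterizes the strength of the
#' microvortices it generates: the maximum vorticity magnitude and maximum
#' Q-criterion evaluated at the cores of the cavity eddies.
#'
#' The depth-averaged plan-view field is solved first; vertical-slice
#' Stokes solves are then run along several cross-flow offsets through the
#' cavities, each carrying the local through-flux taken from the plan-view
#' solution (2.5-D coupling), and a Brinkman plan-view solve
#' ([solve_brinkman()]) is searched for closed in-plane recirculation.
#' Microvortices appear as closed recirculation regions (streamfunction
#' beyond the through-flow range); the reported metrics are the vorticity
#' magnitude and Q-criterion at each vortex core (the streamfunction
#' extremum), maximized over all vortices, slices and models. Cores — not
#' shear-layer maxima — are used because the Q-criterion is designed to
#' isolate rotation-dominated vortex cores, whereas raw field maxima sit in
#' wall shear layers whose discrete value grows without bound under grid
#' refinement. In the Stokes regime vorticity scales linearly and Q
#' quadratically with flow rate, so vortices are weak at 0.5 uL min^-1 and
#' appreciable at 3.0 uL min^-1. Note the 2.5-D chain resolves corner
#' eddies but not fully three-dimensional spiral vortices, and so tends to
#' underestimate vortex strength (see the methods vignette).
#'
#' @param flow_rate Flow rate in uL min^-1.
#' @param spec A [microtrap_spec()].
#' @param channel A [channel_spec()]; its `grid_spacing` sets the plan-view
#'   resolution.
#' @param fluid A [fluid_properties()].
#' @param offsets Cross-flow offsets (um) of the slice lines relative to the
#'   trap centerline.
#' @param dz Slice grid step in um.
#' @param field,depth Optionally a precomputed plan-view `flow_field` and
#'   its `depth_map` (skips the plan-view solve).
#' @return A one-row tibble: `flow_rate`, `max_vorticity` (s^-1, vortex
#'   core), `max_q` (s^-2, vortex core), `n_vortices`, `plan_max_speed`
#'   (um/s over the trap interior), `grid_spacing`.
#' @export
microtrap_vortex_metrics <- function(flow_rate, spec = microtrap_spec(),
                                     channel = channel_spec(),
                                     fluid = water(),
                                     offsets = c(-45, -30, -15, 15, 30, 45),
                                     dz = 0.5, field = NULL, depth = NULL) {
  if (is.null(depth)) depth <- build_microtrap(spec, channel)
  if (is.null(field)) {
    field <- solve_depth_averaged(depth, flow_rate, fluid,
                                  channel_width = channel$width)
  }
  bb <- depth$feature$bbox
  ys <- dm_y(depth); xs <- dm_x(depth)
  cy <- (bb["ymin"] + bb["ymax"]) / 2
  trap_cols <- xs >= bb["xmin"] & xs <= bb["xmax"]

  best_om <- 0; best_q <- -Inf; n_vort <- 0L
  # in-plane recirculation (Brinkman model)
  bf <- solve_brinkman(depth, flow_rate, fluid, channel_width = channel$width)
  vcb <- vortex_cores_xy(bf, mask = trap_interior_mask(depth))
  if (nrow(vcb)) {
    n_vort <- n_vort + nrow(vcb)
    best_om <- max(best_om, max(abs(vcb$vorticity)))
    best_q <- max(best_q, max(vcb$q))
  }
  for (off in offsets) {
    row <- which.min(abs(ys - (cy + off)))
    prof <- depth$h[row, ]
    qx <- (field$Fx[row, -1] + field$Fx[row, -ncol(field$Fx)]) / 2 /
      depth$spacing # per-width flux along the line, um^2/s
    slice_flux <- mean(abs(qx[trap_cols]))
    sl <- solve_vertical_slice(prof, fluid = fluid, channel = channel,
                               flux = slice_flux, dz = dz,
                               profile_spacing = depth$spacing)
    vc <- vortex_cores(sl)
    if (nrow(vc)) {
      n_vort <- n_vort + nrow(vc)
      best_om <- max(best_om, max(abs(vc$vorticity)))
      best_q <- max(best_q, max(vc$q))
    }
  }
  mask <- trap_interior_mask(depth)
  sp <- sqrt(field$u^2 + field$v^2)
  tibble::tibble(
    flow_rate = flow_rate,
    max_vorticity = best_om,
    max_q = if (is.finite(best_q)) best_q else 0,
    n_vortices = n_vort,
    plan_max_speed = max(sp[mask]),
    grid_spacing = depth$spacing
  )
}

#' Locate microvortex cores in a vertical-slice solution
#'
#' Finds closed-recirculation regions (streamfunction below the floor value
#' or above the lid value by a tolerance) and reports, per region, the core
#' (streamfunction extremum) position and the vorticity and Q-criterion
#' there.
#'
#' @param field An `"xz"` `flow_field` from [solve_vertical_slice()].
#' @param tol Relative streamfunction tolerance (fraction of the through
#'   flux).
#' @return A tibble: `vortex`, `x`, `z` (um), `psi`, `vorticity` (s^-1,
#'   signed), `q` (s^-2), `n_cells`.
#' @export
vortex_cores <- function(field, tol = 1e-6) {
  stopifnot(identical(field$plane, "xz"))
  if (field$flux == 0) {
    return(tibble::tibble(vortex = integer(), x = double(), z = double(),
                          psi = double(), vorticity = double(), q = double(),
                          n_cells = integer()))
  }
  om <- vorticity(field)$values
  qf <- q_criterion(field)$values
  thr <- abs(field$flux) * tol
  lo <- min(0, field$flux); hi <- max(0, field$flux)
  rec <- (field$psi < lo - thr) | (field$psi > hi + thr)
  rec[field$solid] <- FALSE
  lab <- t(EBImage::imageData(EBImage::bwlabel(t(rec) * 1)))
  out <- list()
  for (l in seq_len(max(lab, 0))) {
    cells <- which(lab == l, arr.ind = TRUE)
    dev <- abs(field$psi[cells] - pmin(pmax(field$psi[cells], lo), hi))
    core <- cells[which.max(dev), , drop = TRUE]
    out[[l]] <- tibble::tibble(
      vortex = l,
      x = (core[2] - 1) * field$spacing,
      z = (core[1] - 1) * field$spacing,
      psi = field$psi[core[1], core[2]],
      vorticity = om[core[1], core[2]],
      q = qf[core[1], core[2]],
      n_cells = nrow(cells)
    )
  }
  dplyr::bind_rows(out)
}

# cells inside the trap footprint, eroded by one wall thickness from the
# side (y) edges
trap_interior_mask <- function(depth) {
  bb <- depth$feature$bbox
  t <- depth$feature$spec$wall_thickness
  xs <- dm_x(depth); ys <- dm_y(depth)
  outer(ys >= bb["ymin"] + t & ys <= bb["ymax"] - t,
        xs >= bb["xmin"] & xs <= bb["xmax"], `&`)
}

#' Glance at a solved flow field
#'
#' @param x A `flow_field`.
#' @param ... Unused.
#' @return A one-row tibble with the plane, flow rate, maximum speed and
#'   (for plan-view fields) the relative depth-flux divergence.
#' @export
glance.flow_field <- function(x, ...) {
  tibble::tibble(
    plane = x$plane,
    flow_rate = x$flow_rate %||% NA_real_,
    max_speed = max(sqrt(x$u^2 + x$v^2)),
    flux_divergence = if (identical(x$plane, "xy") && !is.null(x$Fx)) {
      depth_flux_divergence(x)
    } else NA_real_
  )
}
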