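#' Depth-averaged (Hele-Shaw) creeping-flow solve
#'
#' Solves the lubrication model for the plan-view flow over a depth map:
#' `div(h^3 grad p) = 0` with a uniform prescribed inlet flux on the upstream
#' (left) boundary, zero pressure on the downstream (right) boundary, and
#' no-flux side walls. The depth-averaged velocity is
#' `u = -h^2/(12 mu) grad p`. Valid in the creeping-flow regime (Re << 1)
#' of shallow channels (height << width), which holds for all flow rates
#' used here (Re <= 0.02).
#'
#' The discretization is a conservative finite-volume scheme with harmonic
#' face transmissibilities and a direct sparse Cholesky factorization, so the
#' depth-flux field is divergence-free and cross-section flux matches the
#' inlet flux to machine precision.
#'
#' `flow_rate` is the pump setting for the full channel; the inlet flux of
#' the simulated sub-domain is scaled by the fraction of the channel width it
#' covers, so the far-field velocity equals `Q/(width*height)` regardless of
#' the domain size.
#'
#' @param depth A [new_depth_map()] object.
#' @param flow_rate Pump flow rate in uL min^-1 (positive).
#' @param fluid A [fluid_properties()].
#' @param channel_width Full physical channel width in um used to scale the
#'   inlet flux (default 5000).
#' @return An object of class `flow_field` with components `u`, `v`
#'   (um s^-1 matrices, rows = y, cols = x), `p` (Pa), face fluxes `Fx`,
#'   `Fy` (um^3 s^-1), `plane = "xy"`, `spacing`, `flow_rate`, `depth`.
#' @export
solve_depth_averaged <- function(depth, flow_rate, fluid = water(),
                                 channel_width = 5000) {
  if (flow_rate <= 0) stop("`flow_rate` must be positive", call. = FALSE)
  h <- depth$h; ds <- depth$spacing
  ny <- nrow(h); nx <- ncol(h)
  mu <- fluid$dynamic_viscosity
  k <- h^3 / (12 * mu) # um^3 / (Pa s), per unit width

  # sub-domain flow rate: scale by covered width fraction
  Ly <- ny * ds
  Q <- ul_min_to_um3_s(flow_rate) * Ly / channel_width # um^3/s
  q_in <- Q / Ly # um^2/s per unit width
  F_in <- q_in * ds # um^3/s per inlet face

  idx <- function(i, j) (j - 1L) * ny + i # column-major cell index
  n <- ny * nx

  # horizontal faces (between columns j and j+1): harmonic mean
  Tx <- 2 * k[, -nx, drop = FALSE] * k[, -1, drop = FALSE] /
    (k[, -nx, drop = FALSE] + k[, -1, drop = FALSE])
  Ty <- 2 * k[-ny, , drop = FALSE] * k[-1, , drop = FALSE] /
    (k[-ny, , drop = FALSE] + k[-1, , drop = FALSE])

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, t) {
    ii <<- c(ii, a, b, a, b); jj <<- c(jj, a, b, b, a); vv <<- c(vv, t, t, -t, -t)
  }
  ia <- rep(seq_len(ny), nx - 1); ja <- rep(seq_len(nx - 1), each = ny)
  add(idx(ia, ja), idx(ia, ja + 1L), as.vector(Tx))
  ib <- rep(seq_len(ny - 1), nx); jb <- rep(seq_len(nx), each = ny - 1)
  add(idx(ib, jb), idx(ib + 1L, jb), as.vector(Ty))

  # outlet Dirichlet p = 0 at the right boundary face (half-cell distance)
  out_cells <- idx(seq_len(ny), nx)
  ii <- c(ii, out_cells); jj <- c(jj, out_cells); vv <- c(vv, 2 * k[, nx])

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  b <- numeric(n)
  b[idx(seq_len(ny), 1L)] <- F_in
  p <- as.numeric(Matrix::solve(A, b))
  p <- matrix(p, nrow = ny, ncol = nx)

  # face fluxes (um^3/s): Fx has nx+1 columns (domain faces included)
  Fx <- matrix(0, ny, nx + 1)
  Fx[, 1] <- F_in
  Fx[, 2:nx] <- Tx * (p[, -nx, drop = FALSE] - p[, -1, drop = FALSE])
  Fx[, nx + 1] <- 2 * k[, nx] * p[, nx]
  Fy <- matrix(0, ny + 1, nx)
  Fy[2:ny, ] <- Ty * (p[-ny, , drop = FALSE] - p[-1, , drop = FALSE])

  # cell-centered depth-averaged velocities (um/s)
  u <- (Fx[, -(nx + 1), drop = FALSE] + Fx[, -1, drop = FALSE]) / 2 / (ds * h)
  v <- (Fy[-(ny + 1), , drop = FALSE] + Fy[-1, , drop = FALSE]) / 2 / (ds * h)

  structure(
    list(u = u, v = v, p = p, Fx = Fx, Fy = Fy, plane = "xy",
         spacing = ds, flow_rate = flow_rate, fluid = fluid,
         depth = depth, q_in = q_in),
    class = "flow_field"
  )
}

#' Construct a uniform (or custom) plan-view flow field
#'
#' Builds a `flow_field` directly from velocity components over a depth
#' map, bypassing the solver. Useful for testing transport and velocimetry
#' against exactly-known fields (uniform flow, rigid rotation, shear, or a
#' zero field for pure Brownian motion).
#'
#' @param depth A `depth_map`.
#' @param u,v Velocity components in um s^-1: scalars or matrices matching
#'   the depth grid.
#' @param fluid A [fluid_properties()].
#' @return A plan-view `flow_field` (without pressure or face fluxes).
#' @export
uniform_flow_field <- function(depth, u = 0, v = 0, fluid = water()) {
  ny <- nrow(depth$h); nx <- ncol(depth$h)
  if (length(u) == 1) u <- matrix(u, ny, nx)
  if (length(v) == 1) v <- matrix(v, ny, nx)
  stopifnot(all(dim(u) == c(ny, nx)), all(dim(v) == c(ny, nx)))
  structure(
    list(u = u, v = v, p = NULL, Fx = NULL, Fy = NULL, plane = "xy",
         spacing = depth$spacing, flow_rate = NULL, fluid = fluid,
         depth = depth, q_in = NULL),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field %s> %d x %d cells @ %g um, max speed %.3g um/s%s\n",
    x$plane, ncol(x$u), nrow(x$u), x$spacing, max(sqrt(x$u^2 + x$v^2)),
    if (!is.null(x$flow_rate)) sprintf(", Q = %g uL/min", x$flow_rate) else ""
  ))
  invisible(x)
}

#' Tidy a flow field into a tibble
#'
#' @param x A `flow_field`.
#' @param ... Unused.
#' @return A tibble with `x`, `y` (um; for vertical slices `y` is the height
#'   z), `u`, `v` (um/s) and `speed`.
#' @export
tidy.flow_field <- function(x, ...) {
  ds <- x$spacing
  ox <- if (!is.null(x$depth)) x$depth$origin else c(0, 0)
  tibble::tibble(
    x = rep(ox[1] + (seq_len(ncol(x$u)) - 0.5) * ds, each = nrow(x$u)),
    y = rep(ox[2] + (seq_len(nrow(x$u)) - 0.5) * ds, times = ncol(x$u)),
    u = as.vector(x$u),
    v = as.vector(x$v),
    speed = as.vector(sqrt(x$u^2 + x$v^2))
  )
}

#' Volumetric flux through every transverse cross-section
#'
#' Sums the depth-integrated face fluxes over each vertical grid line. For a
#' conservatively solved field every value equals the inlet flow rate.
#'
#' @param field A `flow_field` from [solve_depth_averaged()].
#' @return A tibble with `x` (face position, um) and `flux` (um^3 s^-1).
#' @export
cross_section_flux <- function(field) {
  stopifnot(identical(field$plane, "xy"))
  ox <- field$depth$origin[1]
  tibble::tibble(
    x = ox + (seq_len(ncol(field$Fx)) - 1) * field$spacing,
    flux = colSums(field$Fx)
  )
}

#' Relative depth-flux divergence of a solved field
#'
#' Maximum cell-wise divergence of the face fluxes, relative to the mean
#' absolute streamwise flux. Machine-small for fields produced by
#' [solve_depth_averaged()].
#'
#' @param field A `flow_field` from [solve_depth_averaged()].
#' @return A single non-negative number.
#' @export
depth_flux_divergence <- function(field) {
  nx <- ncol(field$u); ny <- nrow(field$u)
  div <- (field$Fx[, -1, drop = FALSE] - field$Fx[, -(nx + 1), drop = FALSE]) +
    (field$Fy[-1, , drop = FALSE] - field$Fy[-(ny + 1), , drop = FALSE])
  max(abs(div)) / mean(abs(field$Fx))
}
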