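#' Vertical-slice Stokes flow (streamfunction-vorticity)
#'
#' Solves steady two-dimensional incompressible Stokes flow in a streamwise
#' vertical (x-z) slice whose floor elevation follows a clearance profile:
#' features rise from the floor, the fluid occupies `z` between the feature
#' top and the channel lid. This resolves what the depth-averaged model
#' cannot: closed recirculation (Moffatt-type cavity eddies) driven inside
#' cavities by the stream passing over the feature tops.
#'
#' Formulation: `laplacian(psi) = omega`, `laplacian(omega) = 0` (biharmonic
#' streamfunction), assembled as one sparse linear system and solved
#' directly. No-slip on floor, feature surfaces and lid (Thom's wall-vorticity
#' closure); a plane-Poiseuille profile carrying the slice flux at the inlet;
#' zero-gradient outflow.
#'
#' @param depth_profile Numeric vector of clearances along the slice (um),
#'   e.g. one row of a depth map's `h`.
#' @param profile_spacing Streamwise extent of one `depth_profile` entry in
#'   um (a depth map's `spacing`); the profile is resampled onto the
#'   isotropic `dz` grid.
#' @param flow_rate Flow rate in uL min^-1 used to set the slice flux
#'   `q = U * H` via [mean_velocity()]; ignored when `flux` is given.
#' @param fluid A [fluid_properties()].
#' @param channel A [channel_spec()] giving height and width for the
#'   flux conversion.
#' @param flux Slice flux in um^2 s^-1 (per unit slice width). Overrides
#'   `flow_rate`.
#' @param dz Grid step in um (isotropic in x and z).
#' @return A `flow_field` with `plane = "xz"`: `u` (streamwise, um/s) and `v`
#'   (here the vertical velocity w) on the node grid (rows = z from the
#'   floor up, cols = x), the streamfunction `psi` (um^2/s), vorticity
#'   `omega` (s^-1) and a logical `solid` mask of feature nodes.
#' @export
solve_vertical_slice <- function(depth_profile, flow_rate = NULL,
                                 fluid = water(), channel = channel_spec(),
                                 flux = NULL, dz = 0.5,
                                 profile_spacing = 1) {
  H <- channel$height
  if (any(depth_profile <= 0) || any(depth_profile > H + 1e-9)) {
    stop("clearances must lie in (0, channel height]", call. = FALSE)
  }
  if (is.null(flux)) {
    if (is.null(flow_rate)) stop("give `flow_rate` or `flux`", call. = FALSE)
    flux <- mean_velocity(flow_rate, channel) * H # um^2/s
  }
  nz <- round(H / dz); nxc <- length(depth_profile)
  # resample the profile onto node columns of the isotropic dz grid
  Lx <- nxc * profile_spacing
  nxn <- round(Lx / dz) + 1L
  xn <- (seq_len(nxn) - 1) * dz
  cell_idx <- pmin(pmax(ceiling(xn / profile_spacing), 1L), nxc)
  prof_nodes <- depth_profile[cell_idx]
  b_elev <- H - prof_nodes # floor/feature-top elevation per column
  b_k <- round(b_elev / dz) # in grid steps, snapped

  nk <- nz + 1L # z nodes 0..nz
  node <- function(k, i) (i - 1L) * nk + k + 1L # k = z index 0..nz, i = col 1..nxn
  n <- nk * nxn
  zs <- (0:nz) * dz

  solid <- matrix(FALSE, nk, nxn) # rows = z (row 1 = floor), cols = x
  for (i in seq_len(nxn)) if (b_k[i] > 0) solid[seq_len(b_k[i]), i] <- TRUE
  # node types
  is_floor <- matrix(FALSE, nk, nxn) # on feature/floor surface (psi = 0)
  for (i in seq_len(nxn)) is_floor[b_k[i] + 1L, i] <- TRUE
  # staircase side walls: fluid node with a solid lateral neighbour
  fluid <- !solid
  side_wall <- matrix(FALSE, nk, nxn)
  if (nxn > 2) {
    for (i in 2:(nxn - 1)) {
      side_wall[, i] <- fluid[, i] &
        (solid[, i - 1] | solid[, i + 1])
    }
  }
  wall <- (is_floor | side_wall) & fluid
  lid <- matrix(FALSE, nk, nxn); lid[nk, ] <- TRUE

  if (flux == 0) {
    zero <- matrix(0, nk, nxn)
    return(structure(
      list(u = zero, v = zero, psi = zero, omega = zero, solid = solid,
           plane = "xz", spacing = dz, flow_rate = flow_rate %||% 0,
           fluid = fluid, flux = 0, depth = NULL),
      class = "flow_field"
    ))
  }

  # inlet Poiseuille profile through the inlet clearance
  h0 <- H - b_k[1] * dz
  zeta <- pmin(1, pmax(0, (zs - b_k[1] * dz) / h0))
  psi_in <- flux * (3 * zeta^2 - 2 * zeta^3)
  om_in <- flux * (6 - 12 * zeta) / h0^2

  NPSI <- 0L; NOM <- n # offsets into the unknown vector
  trip_i <- vector("list", 64); trip_j <- vector("list", 64); trip_x <- vector("list", 64)
  rhs <- numeric(2 * n)
  tc <- 0L
  push <- function(r, c, v) {
    tc <<- tc + 1L
    trip_i[[tc]] <<- r; trip_j[[tc]] <<- c; trip_x[[tc]] <<- v
  }

  K <- matrix(rep(0:nz, nxn), nk, nxn)
  I <- matrix(rep(seq_len(nxn), each = nk), nk, nxn)
  interior <- fluid & !wall & !lid
  interior[, c(1, nxn)] <- FALSE

  # --- psi equations ---
  # Dirichlet: floor/feature surface & side walls -> 0, lid -> flux,
  # inlet -> Poiseuille
  dir <- (wall | lid) & fluid
  dir[, 1] <- fluid[, 1]
  rpsi <- NPSI + node(K[dir], I[dir])
  push(rpsi, rpsi, rep(1, length(rpsi)))
  rhs[rpsi] <- 0 # floor, feature surfaces, side walls
  rhs[NPSI + node(nz, seq_len(nxn))] <- flux # lid
  rhs[NPSI + node(K[, 1][fluid[, 1]], 1L)] <- psi_in[(0:nz)[fluid[, 1]] + 1L]

  # outlet: d psi / dx = 0 (exclude nodes already Dirichlet)
  outn <- fluid[, nxn] & !dir[, nxn]
  ko <- (0:nz)[outn]
  push(NPSI + node(ko, nxn), NPSI + node(ko, nxn), rep(1, length(ko)))
  push(NPSI + node(ko, nxn), NPSI + node(ko, nxn - 1L), rep(-1, length(ko)))

  # interior: 5-point laplacian(psi) - omega = 0
  ki <- K[interior]; xi <- I[interior]
  rint <- NPSI + node(ki, xi)
  push(rint, rint, rep(-4 / dz^2, length(ki)))
  push(rint, NPSI + node(ki + 1L, xi), rep(1 / dz^2, length(ki)))
  push(rint, NPSI + node(ki - 1L, xi), rep(1 / dz^2, length(ki)))
  push(rint, NPSI + node(ki, xi + 1L), rep(1 / dz^2, length(ki)))
  push(rint, NPSI + node(ki, xi - 1L), rep(1 / dz^2, length(ki)))
  push(rint, NOM + node(ki, xi), rep(-1, length(ki)))

  # --- omega equations ---
  # inlet: prescribed
  kin <- (0:nz)[fluid[, 1]]
  rin <- NOM + node(kin, 1L)
  push(rin, rin, rep(1, length(kin)))
  rhs[rin] <- om_in[kin + 1L]

  # walls and lid: Thom closure omega_w = 2 (psi_adj - psi_w) / dz^2,
  # averaged over fluid normals
  wl <- (wall | lid) & fluid
  wl[, 1] <- FALSE
  kw <- K[wl]; xw <- I[wl]
  for (m in seq_along(kw)) {
    k <- kw[m]; i <- xw[m]
    r <- NOM + node(k, i)
    nbrs <- list(c(k + 1L, i), c(k - 1L, i), c(k, i + 1L), c(k, i - 1L))
    nbrs <- Filter(function(q) {
      q[1] >= 0 && q[1] <= nz && q[2] >= 1 && q[2] <= nxn &&
        fluid[q[1] + 1L, q[2]] && !wall[q[1] + 1L, q[2]] && !lid[q[1] + 1L, q[2]]
    }, nbrs)
    push(r, r, 1)
    if (length(nbrs) == 0) { # isolated (e.g. cavity corner): omega = 0 + psi term
      push(r, NPSI + node(k, i), 2 / dz^2)
      rhs[r] <- 0
      next
    }
    wgt <- 2 / dz^2 / length(nbrs)
    for (q in nbrs) push(r, NPSI + node(q[1], q[2]), -wgt)
    push(r, NPSI + node(k, i), 2 / dz^2)
  }

  # outlet: d omega / dx = 0
  push(NOM + node(ko, nxn), NOM + node(ko, nxn), rep(1, length(ko)))
  push(NOM + node(ko, nxn), NOM + node(ko, nxn - 1L), rep(-1, length(ko)))

  # interior: laplacian(omega) = 0
  rom <- NOM + node(ki, xi)
  push(rom, rom, rep(-4 / dz^2, length(ki)))
  push(rom, NOM + node(ki + 1L, xi), rep(1 / dz^2, length(ki)))
  push(rom, NOM + node(ki - 1L, xi), rep(1 / dz^2, length(ki)))
  push(rom, NOM + node(ki, xi + 1L), rep(1 / dz^2, length(ki)))
  push(rom, NOM + node(ki, xi - 1L), rep(1 / dz^2, length(ki)))

  # solid nodes: identity rows, zero
  if (any(solid)) {
    ks <- K[solid]; xs_ <- I[solid]
    rs <- node(ks, xs_)
    push(NPSI + rs, NPSI + rs, rep(1, length(rs)))
    push(NOM + rs, NOM + rs, rep(1, length(rs)))
  }

  A <- Matrix::sparseMatrix(
    i = unlist(trip_i[seq_len(tc)]), j = unlist(trip_j[seq_len(tc)]),
    x = unlist(trip_x[seq_len(tc)]), dims = c(2 * n, 2 * n)
  )
  sol <- as.numeric(Matrix::solve(A, rhs))
  psi <- matrix(sol[seq_len(n)], nk, nxn)
  omega <- matrix(sol[n + seq_len(n)], nk, nxn)
  psi[solid] <- 0; omega[solid] <- 0

  # velocities: u = d psi / dz, w = -d psi / dx (central differences)
  u <- matrix(0, nk, nxn); w <- matrix(0, nk, nxn)
  u[2:(nk - 1), ] <- (psi[3:nk, ] - psi[1:(nk - 2), ]) / (2 * dz)
  w[, 2:(nxn - 1)] <- -(psi[, 3:nxn] - psi[, 1:(nxn - 2)]) / (2 * dz)
  u[solid] <- 0; w[solid] <- 0

  structure(
    list(u = u, v = w, psi = psi, omega = omega, solid = solid,
         plane = "xz", spacing = dz, flow_rate = flow_rate, fluid = fluid,
         flux = flux, depth = NULL),
    class = "flow_field"
  )
}

#' Detect closed recirculation in a vertical-slice solution
#'
#' A cavity eddy shows as a region where the streamfunction falls below the
#' floor value (psi < 0 for positive through-flux): fluid circulating on
#' closed streamlines rather than passing through.
#'
#' @param field An `"xz"` `flow_field` from [solve_vertical_slice()].
#' @param tol Streamfunction threshold relative to the through-flux.
#' @return TRUE if a closed recirculation region exists.
#' @export
has_recirculation <- function(field, tol = 1e-6) {
  stopifnot(identical(field$plane, "xz"))
  if (field$flux == 0) return(FALSE)
  any(field$psi < -abs(field$flux) * tol)
}
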