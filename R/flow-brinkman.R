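#' Brinkman-extended depth-averaged creeping flow
#'
#' Solves the plan-view creeping flow over a depth map with the Brinkman
#' correction to the Hele-Shaw model:
#' `grad p = mu lap(u) - (12 mu / h^2) u`, `div(h u) = 0`.
#' The in-plane viscous term (absent from the pure lubrication model)
#' restores lateral momentum diffusion over the screening length
#' `h / sqrt(12)`, which is what allows closed in-plane recirculation —
#' the horizontal microvortices that funnel-gap jets drive inside trap
#' cavities. The pure Hele-Shaw field is curl-free wherever the depth is
#' uniform and therefore cannot represent them.
#'
#' Formulation: flux streamfunction `Psi` with `h u = dPsi/dy`,
#' `h v = -dPsi/dx` (so continuity is exact), and the curl of the momentum
#' equation closes the system in (`Psi`, `omega`):
#' `omega + div((1/h) grad Psi) = 0`,
#' `lap(omega) + 12 div((1/h^3) grad Psi) = 0`.
#' Boundary conditions: uniform-flow streamfunction on the inlet and side
#' boundaries (far-field), zero-gradient outflow; assembled sparse and
#' solved directly.
#'
#' @inheritParams solve_depth_averaged
#' @return A `flow_field` (plane `"xy"`) with `u`, `v` (um/s), the flux
#'   streamfunction `psi` (um^3/s per unit... i.e. um^2/s times depth) and
#'   `flux` (total through-flow, um^3/s per um of depth-integrated
#'   cross-section, equal to `max(psi) - min(psi)` on the boundary).
#' @export
solve_brinkman <- function(depth, flow_rate, fluid = water(),
                           channel_width = 5000) {
  if (flow_rate <= 0) stop("`flow_rate` must be positive", call. = FALSE)
  h <- depth$h; ds <- depth$spacing
  ny <- nrow(h); nx <- ncol(h)
  n <- ny * nx
  Ly <- ny * ds
  Q <- ul_min_to_um3_s(flow_rate) * Ly / channel_width # um^3/s over the domain
  q_in <- Q / Ly # per unit width

  idx <- function(i, j) (j - 1L) * ny + i
  NPSI <- 0L; NOM <- n

  # face coefficients (harmonic means) for div(c grad Psi), c = 1/h and 1/h^3
  cf <- function(cmat) {
    fx <- 2 * cmat[, -nx] * cmat[, -1] / (cmat[, -nx] + cmat[, -1]) # ny x nx-1
    fy <- 2 * cmat[-ny, ] * cmat[-1, ] / (cmat[-ny, ] + cmat[-1, ]) # ny-1 x nx
    list(fx = fx, fy = fy)
  }
  c1 <- cf(1 / h); c3 <- cf(1 / h^3)

  ti <- vector("list", 0); tj <- vector("list", 0); tx <- vector("list", 0)
  push <- function(r, c, v) {
    ti[[length(ti) + 1L]] <<- r; tj[[length(tj) + 1L]] <<- c
    tx[[length(tx) + 1L]] <<- v
  }
  rhs <- numeric(2 * n)

  I <- matrix(rep(seq_len(ny), nx), ny, nx)
  J <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  boundary_dir <- (J == 1) | (I == 1) | (I == ny) # inlet + side walls
  outlet <- (J == nx) & !boundary_dir
  interior <- !boundary_dir & !outlet

  ys <- (seq_len(ny) - 0.5) * ds
  psi_far <- q_in * ys # uniform-flow streamfunction (per row)

  # Dirichlet rows: Psi = far-field, omega = 0
  bi <- I[boundary_dir]; bj <- J[boundary_dir]
  rb <- idx(bi, bj)
  push(NPSI + rb, NPSI + rb, rep(1, length(rb)))
  rhs[NPSI + rb] <- psi_far[bi]
  push(NOM + rb, NOM + rb, rep(1, length(rb)))

  # outlet: zero x-gradient for both fields
  oi <- I[outlet]
  ro <- idx(oi, nx); ro2 <- idx(oi, nx - 1L)
  push(NPSI + ro, NPSI + ro, rep(1, length(oi)))
  push(NPSI + ro, NPSI + ro2, rep(-1, length(oi)))
  push(NOM + ro, NOM + ro, rep(1, length(oi)))
  push(NOM + ro, NOM + ro2, rep(-1, length(oi)))

  # interior: omega + div((1/h) grad Psi) = 0 ;
  #           lap(omega) + 12 div((1/h^3) grad Psi) = 0
  ii <- I[interior]; jj <- J[interior]
  rc <- idx(ii, jj)
  d2 <- ds^2
  west <- c1$fx[cbind(ii, jj - 1L)]; east <- c1$fx[cbind(ii, jj)]
  south <- c1$fy[cbind(ii - 1L, jj)]; north <- c1$fy[cbind(ii, jj)]
  push(NPSI + rc, NPSI + rc, -(west + east + south + north) / d2)
  push(NPSI + rc, NPSI + idx(ii, jj - 1L), west / d2)
  push(NPSI + rc, NPSI + idx(ii, jj + 1L), east / d2)
  push(NPSI + rc, NPSI + idx(ii - 1L, jj), south / d2)
  push(NPSI + rc, NPSI + idx(ii + 1L, jj), north / d2)
  push(NPSI + rc, NOM + rc, rep(1, length(rc)))

  west3 <- c3$fx[cbind(ii, jj - 1L)]; east3 <- c3$fx[cbind(ii, jj)]
  south3 <- c3$fy[cbind(ii - 1L, jj)]; north3 <- c3$fy[cbind(ii, jj)]
  push(NOM + rc, NOM + rc, rep(-4 / d2, length(rc)))
  push(NOM + rc, NOM + idx(ii, jj - 1L), rep(1 / d2, length(rc)))
  push(NOM + rc, NOM + idx(ii, jj + 1L), rep(1 / d2, length(rc)))
  push(NOM + rc, NOM + idx(ii - 1L, jj), rep(1 / d2, length(rc)))
  push(NOM + rc, NOM + idx(ii + 1L, jj), rep(1 / d2, length(rc)))
  push(NOM + rc, NPSI + rc, -12 * (west3 + east3 + south3 + north3) / d2)
  push(NOM + rc, NPSI + idx(ii, jj - 1L), 12 * west3 / d2)
  push(NOM + rc, NPSI + idx(ii, jj + 1L), 12 * east3 / d2)
  push(NOM + rc, NPSI + idx(ii - 1L, jj), 12 * south3 / d2)
  push(NOM + rc, NPSI + idx(ii + 1L, jj), 12 * north3 / d2)

  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(2 * n, 2 * n))
  sol <- as.numeric(Matrix::solve(A, rhs))
  psi <- matrix(sol[seq_len(n)], ny, nx)
  omega <- matrix(sol[n + seq_len(n)], ny, nx)

  u <- ddy(psi, ds) / h
  v <- -ddx(psi, ds) / h

  structure(
    list(u = u, v = v, p = NULL, Fx = NULL, Fy = NULL, psi = psi,
         omega = omega, plane = "xy", spacing = ds, flow_rate = flow_rate,
         fluid = fluid, depth = depth, q_in = q_in, flux = Q),
    class = "flow_field"
  )
}

#' Locate in-plane microvortex cores in a Brinkman solution
#'
#' Closed in-plane recirculation shows as streamfunction values outside the
#' through-flow range `[min, max]` of the far-field streamfunction. Reports
#' each region's core (streamfunction extremum) with the vorticity and
#' Q-criterion there.
#'
#' @param field A `flow_field` from [solve_brinkman()].
#' @param tol Relative streamfunction tolerance (fraction of the through
#'   flux).
#' @param mask Optional logical matrix restricting the search (e.g. the
#'   trap interior).
#' @return A tibble like [vortex_cores()]: `vortex`, `x`, `y`, `psi`,
#'   `vorticity`, `q`, `n_cells`.
#' @export
vortex_cores_xy <- function(field, tol = 1e-6, mask = NULL) {
  stopifnot(!is.null(field$psi))
  om <- vorticity(field)$values
  qf <- q_criterion(field)$values
  lo <- 0; hi <- field$flux
  thr <- abs(hi) * tol
  rec <- (field$psi < lo - thr) | (field$psi > hi + thr)
  if (!is.null(mask)) rec <- rec & mask
  lab <- t(EBImage::imageData(EBImage::bwlabel(t(rec) * 1)))
  origin <- field$depth$origin
  out <- list()
  for (l in seq_len(max(lab, 0))) {
    cells <- which(lab == l, arr.ind = TRUE)
    dev <- abs(field$psi[cells] -
                 pmin(pmax(field$psi[cells], lo), hi))
    core <- cells[which.max(dev), , drop = TRUE]
    out[[l]] <- tibble::tibble(
      vortex = l,
      x = origin[1] + (core[2] - 0.5) * field$spacing,
      y = origin[2] + (core[1] - 0.5) * field$spacing,
      psi = field$psi[core[1], core[2]],
      vorticity = om[core[1], core[2]],
      q = qf[core[1], core[2]],
      n_cells = nrow(cells)
    )
  }
  dplyr::bind_rows(out)
}
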