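test_that("plain channel solve reproduces slot Poiseuille flow", {
  dm <- plain_dm()
  fl <- solve_depth_averaged(dm, 0.5)
  U <- mean_velocity(0.5) # ~111 um/s
  expect_equal(max(abs(fl$u - U)) / U, 0, tolerance = 1e-9)
  expect_equal(max(abs(fl$v)), 0, tolerance = U * 1e-9)

  # pressure drop oracle: dp = 12 mu U L / h^2 between cell-center columns
  L <- (ncol(dm$h) - 1) * dm$spacing
  dp_oracle <- 12 * 1e-3 * U * L / 15^2
  dp <- mean(fl$p[, 1]) - mean(fl$p[, ncol(fl$p)])
  expect_equal(dp, dp_oracle, tolerance = 0.01)
})

test_that("depth-flux is conserved through every cross-section", {
  fl <- trap_field(3.0)
  expect_lt(depth_flux_divergence(fl), 1e-6)
  cf <- cross_section_flux(fl)
  expect_lt(diff(range(cf$flux)) / mean(cf$flux), 1e-3 * 1e-3) # 0.1% spec, met to ~1e-12
  # inlet flux equals the pump rate scaled by the covered width fraction
  Ly <- nrow(fl$u) * fl$spacing
  expect_equal(mean(cf$flux), 3.0e9 / 60 * Ly / 5000, tolerance = 1e-9)
})

test_that("Stokes linearity: velocities scale with flow rate", {
  lo <- trap_field(0.5); hi <- trap_field(3.0)
  expect_equal(hi$u, 6 * lo$u, tolerance = 1e-9)
  expect_equal(hi$v, 6 * lo$v, tolerance = 1e-9)
  # vorticity scales linearly, Q-criterion quadratically
  expect_equal(vorticity(hi)$values, 6 * vorticity(lo)$values,
               tolerance = 1e-9)
  expect_equal(q_criterion(hi)$values, 36 * q_criterion(lo)$values,
               tolerance = 1e-9)
})

test_that("a y-symmetric trap yields u even and v odd about the centerline", {
  fl <- trap_field(0.5)
  ny <- nrow(fl$u)
  flip <- ny:1
  scale <- max(abs(fl$u))
  expect_lt(max(abs(fl$u - fl$u[flip, ])) / scale, 1e-8)
  expect_lt(max(abs(fl$v + fl$v[flip, ])) / scale, 1e-8)
})

test_that("vertical slice over a flat floor is plane Poiseuille", {
  ch <- channel_spec()
  sl <- solve_vertical_slice(rep(15, 200), flow_rate = 0.5, channel = ch)
  # max/mean velocity ratio 1.5 for plane Poiseuille
  mid <- ncol(sl$u) %/% 2
  prof <- sl$u[, mid]
  # trapezoid mean over the full profile (endpoints are zero at the walls)
  wmean <- (sum(prof) - (prof[1] + prof[length(prof)]) / 2) / (length(prof) - 1)
  expect_equal(max(prof) / wmean, 1.5, tolerance = 0.02)
  # vertical velocity negligible (small inlet adjustment layer allowed)
  expect_lt(max(abs(sl$v)) / max(sl$u), 1e-2)
})

test_that("a rectangular cavity develops closed recirculation", {
  # single 60 um cavity between two 20 um walls, clearance 5 um over walls
  prof <- c(rep(15, 60), rep(5, 20), rep(15, 60), rep(5, 20), rep(15, 60))
  sl <- solve_vertical_slice(prof, flux = 1000, dz = 0.5)
  expect_true(has_recirculation(sl))
  cores <- vortex_cores(sl)
  expect_gt(nrow(cores), 0)
  # the eddy core sits inside the cavity, below the feature tops
  expect_true(any(cores$z < 10))
})

test_that("zero slice flux gives an identically zero field", {
  sl <- solve_vertical_slice(rep(15, 50), flux = 0)
  expect_true(all(sl$u == 0) && all(sl$v == 0) && all(sl$psi == 0))
})

test_that("vorticity and Q-criterion match analytic fields", {
  ch <- channel_spec(grid_spacing = 1)
  dm <- build_channel(ch, area = c(60, 60))
  xs <- (seq_len(60) - 0.5); ys <- (seq_len(60) - 0.5)
  X <- matrix(xs, 60, 60, byrow = TRUE); Y <- matrix(ys, 60, 60)
  w0 <- 2.5; g0 <- 1.7

  rigid <- uniform_flow_field(dm, u = -w0 * Y, v = w0 * X)
  expect_equal(max(abs(vorticity(rigid)$values - 2 * w0)), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(q_criterion(rigid)$values - w0^2)), 0,
               tolerance = 1e-8)

  unif <- uniform_flow_field(dm, u = 50)
  expect_true(all(vorticity(unif)$values == 0))

  shear <- uniform_flow_field(dm, u = g0 * Y, v = 0 * X)
  expect_equal(max(abs(q_criterion(shear)$values)), 0, tolerance = 1e-10)

  strain <- uniform_flow_field(dm, u = g0 * X, v = -g0 * Y)
  expect_equal(max(abs(q_criterion(strain)$values + g0^2)), 0,
               tolerance = 1e-8)
})

test_that("streamlines follow uniform flow and avoid blocking obstacles", {
  ch <- channel_spec(grid_spacing = 2)
  dm <- build_channel(ch, area = c(200, 100))
  unif <- uniform_flow_field(dm, u = 100)
  sl <- streamlines(unif, tibble::tibble(x = c(5, 5), y = c(30, 70)),
                    step = 2)
  expect_equal(sd(sl$y[sl$line == 1]), 0)
  expect_equal(sd(sl$y[sl$line == 2]), 0)
  expect_error(streamlines(unif, tibble::tibble(x = -5, y = 30)), "inside")

  # near-full-height obstacle: solved streamlines do not enter its footprint
  dm2 <- dm
  obst <- outer(dm_y_cells <- abs((seq_len(nrow(dm$h)) - 0.5) * 2 - 50) < 20,
                abs((seq_len(ncol(dm$h)) - 0.5) * 2 - 100) < 20, `&`)
  dm2$h[obst] <- 0.05
  dm2$solid <- obst
  fl <- solve_depth_averaged(dm2, 0.5)
  st <- streamlines(fl, tibble::tibble(x = rep(4, 4), y = c(20, 40, 60, 80)),
                    step = 1, stop_clearance = 1)
  inside_obst <- abs(st$y - 50) < 20 & abs(st$x - 100) < 20
  expect_false(any(inside_obst))
})

test_that("cavity eddy streamlines close on themselves", {
  # a deep, narrow cavity (10 x 10 um) forms one strong closed eddy
  prof <- c(rep(15, 40), rep(5, 20), rep(15, 10), rep(5, 20), rep(15, 40))
  sl <- solve_vertical_slice(prof, flux = 1000, dz = 0.5)
  cores <- vortex_cores(sl)
  core <- cores[which.max(cores$n_cells), ]
  expect_gt(core$n_cells, 50)
  # seed slightly off the core; the orbit must return near its start
  seed <- tibble::tibble(x = core$x + 1.5, y = core$z)
  orbit <- streamlines(sl, seed, step = 0.1, max_steps = 4000)
  d <- sqrt((orbit$x - seed$x)^2 + (orbit$y - seed$y)^2)
  # after leaving the start, it comes back within a grid cell
  away <- which(d > 1)[1]
  expect_false(is.na(away))
  expect_lt(min(d[away:length(d)]), 0.5)
})

test_that("microtrap vortex metrics scale with flow rate in the Stokes regime", {
  m3 <- cached("metrics_3", microtrap_vortex_metrics(3.0, field = trap_field(3.0),
                                                     depth = trap_dm()))
  m05 <- cached("metrics_05", microtrap_vortex_metrics(0.5, field = trap_field(0.5),
                                                       depth = trap_dm()))
  expect_gt(m3$n_vortices, 0)
  expect_equal(m3$max_vorticity / m05$max_vorticity, 6, tolerance = 1e-6)
  expect_equal(m3$max_q / m05$max_q, 36, tolerance = 1e-6)
})
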