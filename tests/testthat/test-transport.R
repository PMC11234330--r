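test_that("deterministic advection in a uniform field is exact", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 50, v = 10)
  traj <- advect(fld, particle_spec(diameter = 2, density = 1.0,
                                    diffusivity_override = 0),
                 n_particles = 5, duration = 0.5, dt = 1e-3, rng_seed = 1,
                 start = tibble::tibble(x = rep(10, 5), y = seq(20, 60, 10)),
                 record_every = 100L)
  fin <- traj[traj$t == max(traj$t), ]
  ini <- traj[traj$t == 0, ]
  expect_equal(fin$x - ini$x, rep(50 * 0.5, 5), tolerance = 1e-12)
  expect_equal(fin$y - ini$y, rep(10 * 0.5, 5), tolerance = 1e-12)
})

test_that("dt exceeding the advection guard is rejected", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 1000)
  expect_error(advect(fld, n_particles = 1, duration = 0.1, dt = 0.1),
               "guard")
})

test_that("settling makes dense particles sink at the Stokes velocity", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 0)
  spec <- particle_spec(diameter = 2, density = 1.3, diffusivity_override = 0)
  traj <- advect(fld, spec, n_particles = 3, duration = 2, dt = 1e-3,
                 rng_seed = 1,
                 start = tibble::tibble(x = rep(100, 3), y = rep(50, 3),
                                        z = rep(12, 3)),
                 record_every = 500L)
  vs <- settling_velocity(2, 1.3)
  fin <- traj[traj$t == max(traj$t), ]
  expect_equal(fin$z, rep(12 - vs * 2, 3), tolerance = 1e-9)

  # neutral density: z unchanged
  traj0 <- advect(fld, particle_spec(2, 1.0, diffusivity_override = 0),
                  n_particles = 2, duration = 1, dt = 1e-3, rng_seed = 1,
                  start = tibble::tibble(x = c(50, 60), y = c(50, 50),
                                         z = c(8, 8)))
  expect_true(all(traj0$z == 8))
})

test_that("Brownian displacement follows the Einstein relation", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 0)
  D <- 0.6
  spec <- particle_spec(diameter = 2, density = 1.0,
                        diffusivity_override = D)
  n <- 600; Tdur <- 0.5
  traj <- advect(fld, spec, n_particles = n, duration = Tdur, dt = 1e-3,
                 rng_seed = 99,
                 start = tibble::tibble(x = rep(100, n), y = rep(50, n)),
                 record_every = 500L)
  fin <- traj[traj$t == max(traj$t), ]
  r2 <- (fin$x - 100)^2 + (fin$y - 50)^2
  slope <- mean(r2) / Tdur
  se <- sd(r2) / sqrt(n) / Tdur
  expect_lt(abs(slope - 4 * D), 3 * se)
})

test_that("trajectories are reproducible under a fixed seed", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 30)
  a <- advect(fld, n_particles = 10, duration = 0.2, dt = 1e-3, rng_seed = 7)
  b <- advect(fld, n_particles = 10, duration = 0.2, dt = 1e-3, rng_seed = 7)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  c_ <- advect(fld, n_particles = 10, duration = 0.2, dt = 1e-3, rng_seed = 8)
  expect_false(identical(a$x, c_$x))
})

test_that("particle count is conserved at every recorded step", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 500)
  traj <- advect(fld, particle_spec(2, 1.0, diffusivity_override = 0),
                 n_particles = 50, duration = 1, dt = 2e-3, rng_seed = 3,
                 start = tibble::tibble(x = runif_seeded(50, 0, 190, 11),
                                        y = runif_seeded(50, 5, 95, 12)),
                 record_every = 50L)
  counts <- table(traj$t)
  expect_true(all(counts == 50))
  # some particles exit through the downstream boundary and stay flagged
  fin <- traj[traj$t == max(traj$t), ]
  expect_gt(sum(fin$exited), 0)
  expect_true(all(fin$x[!fin$exited] <= 200))
})

test_that("cavity occupancy summarizes residence and trapping", {
  trap <- trap_dm_coarse()
  centers <- trap$feature$cavity_centers
  # stationary particles parked in cavity 1 accrue full residence
  still <- uniform_flow_field(trap, u = 0)
  traj <- advect(still, particle_spec(2, 1.0, diffusivity_override = 0),
                 n_particles = 4, duration = 1, dt = 1e-2, rng_seed = 1,
                 start = tibble::tibble(x = rep(centers$x[1], 4),
                                        y = rep(centers$y[1], 4)),
                 record_every = 10L)
  oc <- trap_occupancy(traj, trap)
  expect_equal(oc$trapped_fraction, 1)
  expect_equal(oc$mean_residence, 1, tolerance = 0.11) # within one record bin
  expect_equal(oc$per_cavity$cavity, 1L)

  # plain channel: no cavities, empty stats
  plain <- plain_dm()
  fld <- uniform_flow_field(plain, u = 100)
  traj2 <- advect(fld, particle_spec(2, 1.0, diffusivity_override = 0),
                  n_particles = 5, duration = 0.1, dt = 1e-3, rng_seed = 1)
  oc2 <- trap_occupancy(traj2, plain)
  expect_equal(oc2$trapped_fraction, 0)
  expect_equal(nrow(oc2$per_cavity), 0)
})

test_that("particles crossing the microtrap slow down and some are trapped", {
  trap <- trap_dm()
  for (rate in c(0.5, 3.0)) {
    fl <- trap_field(rate)
    vmax <- max(sqrt(fl$u^2 + fl$v^2))
    trapped <- numeric(0)
    for (sd_ in 1:3) {
      traj <- advect(fl, particle_spec(diameter = 2), n_particles = 150,
                     duration = 2 / rate, dt = min(8e-4, 1.8 / vmax),
                     rng_seed = sd_,
                     start = tibble::tibble(
                       x = runif_seeded(150, 5, 60, sd_ + 20),
                       y = runif_seeded(150, 100, 290, sd_ + 40)),
                     record_every = 25L)
      oc <- trap_occupancy(traj, trap)
      trapped <- c(trapped, oc$trapped_fraction)
      steps <- traj |>
        dplyr::group_by(.data$particle) |>
        dplyr::mutate(sp = sqrt((dplyr::lead(.data$x) - .data$x)^2 +
                                (dplyr::lead(.data$y) - .data$y)^2) /
                        (dplyr::lead(.data$t) - .data$t)) |>
        dplyr::ungroup() |>
        dplyr::filter(!.data$exited, is.finite(.data$sp))
      upstream <- median(steps$sp[steps$x < 110])
      in_trap <- median(steps$sp[steps$x > 150 & steps$x < 500 &
                                 steps$y > 140 & steps$y < 250])
      expect_lt(in_trap, upstream)
    }
    expect_gt(mean(trapped), 0.05)
  }
})
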