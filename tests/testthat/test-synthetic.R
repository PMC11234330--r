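static_traj <- function(x, y, z = 7.5) {
  n <- length(x)
  z <- rep_len(z, n)
  traj <- tibble::tibble(particle = rep(seq_len(n), 2),
                         t = rep(c(0, 1e3), each = n),
                         x = rep(x, 2), y = rep(y, 2), z = rep(z, 2),
                         exited = rep(FALSE, 2 * n))
  attr(traj, "particle_spec") <- particle_spec(2)
  class(traj) <- c("trajectory_set", class(traj))
  traj
}

test_that("a static particle renders as one Gaussian spot, identically per frame", {
  optics <- optics_spec(frame_count = 3, noise_sigma = 0)
  st <- render_video(static_traj(20.31, 15.77), optics, origin = c(0, 0),
                     dim_px = c(64, 48), shot_noise = FALSE)
  expect_length(st$frames, 3)
  expect_identical(st$frames[[1]], st$frames[[2]])
  expect_identical(st$frames[[1]], st$frames[[3]])
  f <- get_frame(st, 1)
  # one local maximum at the mapped pixel
  det <- detect_spots(f, threshold_method = "absolute", threshold = 15)
  expect_equal(nrow(det), 1)
  expect_equal(round(det$x), round(st$truth$x_px[1]))
  expect_equal(round(det$y), round(st$truth$y_px[1]))
})

test_that("two spots 10 px apart give two local maxima", {
  optics <- optics_spec(frame_count = 1, noise_sigma = 0, pixel_size = 1)
  st <- render_video(static_traj(c(20, 30), c(24, 24)), optics,
                     origin = c(0, 0), dim_px = c(64, 48), shot_noise = FALSE)
  det <- detect_spots(get_frame(st, 1), threshold_method = "absolute",
                      threshold = 15)
  expect_equal(nrow(det), 2)
})

test_that("rendered spot centroid round-trips within 0.05 px", {
  optics <- optics_spec(frame_count = 1, noise_sigma = 0)
  for (xs in c(20.31, 33.5, 41.07)) {
    st <- render_video(static_traj(xs, 15.77), optics, origin = c(0, 0),
                       dim_px = c(96, 48), shot_noise = FALSE)
    det <- detect_spots(get_frame(st, 1), threshold_method = "absolute",
                        threshold = 15)
    expect_equal(nrow(det), 1)
    expect_lt(abs(det$x - st$truth$x_px), 0.05)
    expect_lt(abs(det$y - st$truth$y_px), 0.05)
  }
})

test_that("an empty trajectory set renders background-only frames", {
  optics <- optics_spec(frame_count = 2, noise_sigma = 0, background = 7)
  empty <- static_traj(numeric(0), numeric(0))
  st <- render_video(empty, optics, origin = c(0, 0), dim_px = c(32, 32),
                     shot_noise = FALSE)
  expect_true(all(get_frame(st, 1) == 7))
})

test_that("defocus widens the rendered point-spread function", {
  optics <- optics_spec(frame_count = 1, noise_sigma = 0)
  focus <- render_video(static_traj(30, 20, z = 7.5), optics, origin = c(0, 0),
                        dim_px = c(64, 48), shot_noise = FALSE, z_focus = 7.5)
  blur <- render_video(static_traj(30, 20, z = 14), optics, origin = c(0, 0),
                       dim_px = c(64, 48), shot_noise = FALSE, z_focus = 7.5)
  # same integrated signal spreads over more pixels: lower peak
  expect_lt(max(get_frame(blur, 1)), max(get_frame(focus, 1)))
})

test_that("video rendering is reproducible under a fixed noise seed", {
  dm <- plain_dm()
  fld <- uniform_flow_field(dm, u = 100)
  traj <- advect(fld, n_particles = 20, duration = 0.5, dt = 5e-3,
                 rng_seed = 5, record_every = 8L)
  optics <- optics_spec(frame_count = 12)
  a <- render_video(traj, optics, origin = c(0, 0), dim_px = c(96, 48),
                    rng_seed = 11)
  b <- render_video(traj, optics, origin = c(0, 0), dim_px = c(96, 48),
                    rng_seed = 11)
  expect_identical(a$frames, b$frames)
  c_ <- render_video(traj, optics, origin = c(0, 0), dim_px = c(96, 48),
                     rng_seed = 12)
  expect_false(identical(a$frames, c_$frames))
})

test_that("walls-regime biofilm intensity concentrates near the walls", {
  trap <- trap_dm_coarse()
  optics <- optics_spec(pixel_size = 4, noise_sigma = 1)
  bi <- generate_biofilm_image(regime_spec("walls", rng_seed = 3), trap,
                               optics)
  img <- bi$image
  bg <- median(img) + 3 * mad(img) # noise floor
  excess <- pmax(img - bg, 0)
  # within one wall thickness (20 um = 5 cells at this grid) of the footprint
  near <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(trap$solid) * 1), EBImage::makeBrush(11, "disc")))) > 0
  expect_gt(sum(excess[near]) / sum(excess), 0.8)
})

test_that("cavity-centers regime puts cavities 1-3 above cavities 4-5", {
  trap <- trap_dm_coarse()
  optics <- optics_spec(pixel_size = 4, noise_sigma = 1)
  for (sd_ in 1:3) {
    bi <- generate_biofilm_image(regime_spec("cavity_centers", rng_seed = sd_),
                                 trap, optics)
    oc <- occupancy(bi$image, trap, pixel_size = 4)
    front <- mean(oc$per_cavity$mean_intensity[1:3])
    back <- mean(oc$per_cavity$mean_intensity[4:5])
    expect_gt(front, back)
  }
})

test_that("a zero-colony regime renders pure background", {
  trap <- trap_dm_coarse()
  optics <- optics_spec(pixel_size = 4, noise_sigma = 0, background = 12)
  bi <- generate_biofilm_image(regime_spec("walls", rng_seed = 1), trap,
                               optics, n_colonies = 0)
  # Poisson noise around the constant background only
  expect_lt(abs(mean(bi$image) - 12), 1)
  expect_equal(nrow(bi$truth), 0)
})

test_that("regime/class mismatches are rejected", {
  expect_error(regime_spec("walls", concentration_class = "low"), "requires")
  expect_error(regime_spec("cavity_centers", flow_class = "low"), "requires")
  expect_s3_class(regime_spec("corners"), "regime_spec")
})

test_that("fixture bundles are deterministic and self-verifying", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_fixture_bundle(7, d1, grid_spacing = 8, video_frames = 10)
  m2 <- make_fixture_bundle(7, d2, grid_spacing = 8, video_frames = 10)
  expect_identical(m1$md5, m2$md5) # byte-identical bundles
  expect_true(verify_fixture_bundle(d1))
  # census: both flow rates and all three regimes are present
  files <- m1$file
  expect_true(all(c("flow_0.5.json", "flow_3.0.json") %in% files))
  expect_true(all(sprintf("biofilm_%s.tif",
                          c("walls", "corners", "cavity_centers")) %in% files))
  # tampering is caught
  tf <- file.path(d1, "biofilm_walls.tif")
  writeBin(as.raw(1:10), tf)
  expect_false(verify_fixture_bundle(d1))
})
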