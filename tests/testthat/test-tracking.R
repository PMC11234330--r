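# render a clean frame of Gaussian spots at given pixel positions
spot_frame <- function(x, y, dim_px = c(128, 128), amp = 100, sigma = 1.2,
                       bg = 10) {
  f <- matrix(bg, dim_px[2], dim_px[1])
  rr <- seq_len(dim_px[2]); cc <- seq_len(dim_px[1])
  for (m in seq_along(x)) {
    f <- f + amp * outer(exp(-(rr - y[m])^2 / (2 * sigma^2)),
                         exp(-(cc - x[m])^2 / (2 * sigma^2)))
  }
  f
}

test_that("blank frames yield no detections", {
  expect_equal(nrow(detect_spots(matrix(10, 64, 64),
                                 threshold_method = "absolute",
                                 threshold = 20)), 0)
  expect_equal(nrow(detect_spots(matrix(10, 64, 64))), 0)
})

test_that("all well-separated spots are detected with accurate centroids", {
  set.seed(31)
  # jittered grid: 50 spots, guaranteed >= 8 px separation
  g <- expand.grid(x = seq(12, 117, 15), y = seq(12, 117, 15))[1:50, ]
  x <- g$x + runif(50, -3, 3); y <- g$y + runif(50, -3, 3)
  f <- spot_frame(x, y)
  det <- detect_spots(f, threshold_method = "absolute", threshold = 25)
  expect_equal(nrow(det), 50)
  D2 <- outer(det$x, x, "-")^2 + outer(det$y, y, "-")^2
  expect_lt(max(sqrt(apply(D2, 2, min))), 0.1) # centroid error <= 0.1 px
})

test_that("PTV linking turns a constant pixel shift into the right speed", {
  # one particle moving +3 px/frame at 25 Hz and 0.65 um/px -> 48.75 um/s
  det <- tibble::tibble(frame = 1:10, x = 10 + 3 * (0:9), y = 20)
  tr <- link_ptv(det, expected_velocity = 48, optics = optics_spec())
  tv <- track_velocities(tr)
  expect_equal(nrow(tv), 1)
  expect_equal(tv$speed, 3 * 0.65 * 25) # 48.75
  expect_equal(tv$v, 0)
})

test_that("crossing particles at equal distance are dropped, not guessed", {
  # two detections in frame 2 exactly equidistant from one in frame 1
  det <- tibble::tibble(
    frame = c(1L, 2L, 2L),
    x = c(10, 13, 13),
    y = c(20, 22, 18)
  )
  tr <- link_ptv(det, expected_velocity = 48, optics = optics_spec(),
                 min_radius = 6)
  expect_equal(nrow(tr), 0) # ambiguous -> no link, no spurious velocity
})

test_that("PTV recovers uniform flow from a rendered video", {
  vid <- short_video()
  det <- detect_stack(vid)
  tr <- link_ptv(det, expected_velocity = 111, optics = vid$optics)
  tv <- track_velocities(tr)
  expect_gt(nrow(tv), 30)
  expect_lt(abs(mean(tv$speed) - 111.1) / 111.1, 0.05)
  vecs <- dplyr::inner_join(dplyr::select(tr, "track", "x", "y"),
                            tv, by = "track")
  hg <- flow_homogeneity(vecs)
  expect_lt(hg$direction_sd_deg, 2)
  expect_lt(hg$speed_cv, 0.05)
})

test_that("PTV link recovery on ground truth exceeds 95% with <= 1% false links", {
  vid <- short_video()
  det <- detect_stack(vid)
  tr <- link_ptv(det, expected_velocity = 111, optics = vid$optics)
  truth <- vid$truth
  nf <- length(vid$frames)
  # crowding flags on the ground truth (linking is only promised for
  # non-overlapping spots)
  iso <- truth |>
    dplyr::group_by(.data$frame) |>
    dplyr::mutate(crowded = purrr::map_lgl(seq_len(dplyr::n()), function(m) {
      d2 <- (.data$x_px - .data$x_px[m])^2 + (.data$y_px - .data$y_px[m])^2
      sum(d2 < 5^2) > 1
    })) |>
    dplyr::ungroup()
  # match detections to ground-truth particles (nearest within 1.5 px)
  matches <- purrr::map_dfr(seq_len(nf), function(f) {
    d <- det[det$frame == f, ]; tt <- iso[iso$frame == f, ]
    if (!nrow(d) || !nrow(tt)) return(NULL)
    D2 <- outer(d$x, tt$x_px, "-")^2 + outer(d$y, tt$y_px, "-")^2
    j <- apply(D2, 1, which.min)
    ok <- D2[cbind(seq_len(nrow(d)), j)] < 1.5^2
    tibble::tibble(frame = f, x = d$x, y = d$y,
                   particle = ifelse(ok, tt$particle[j], NA),
                   crowded = ifelse(ok, tt$crowded[j], NA))
  })
  linked <- dplyr::inner_join(tr, matches, by = c("frame", "x", "y")) |>
    dplyr::filter(!is.na(.data$u)) |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::mutate(next_p = dplyr::lead(.data$particle),
                  next_crowd = dplyr::lead(.data$crowded)) |>
    dplyr::filter(!is.na(.data$next_p)) |>
    dplyr::ungroup()
  clean <- linked |>
    dplyr::filter(!is.na(.data$crowded), !.data$crowded,
                  !is.na(.data$next_crowd), !.data$next_crowd)
  false_rate <- mean(clean$particle != clean$next_p)
  expect_lt(false_rate, 0.01)
  cons <- iso |>
    dplyr::group_by(.data$particle) |>
    dplyr::arrange(.data$frame) |>
    dplyr::mutate(nf2 = dplyr::lead(.data$frame),
                  nx = dplyr::lead(.data$x_px), ny2 = dplyr::lead(.data$y_px),
                  ncrowd = dplyr::lead(.data$crowded)) |>
    dplyr::filter(.data$nf2 == .data$frame + 1, !.data$crowded, !.data$ncrowd,
                  .data$x_px > 6, .data$x_px < 250,
                  .data$y_px > 6, .data$y_px < 174,
                  .data$nx > 6, .data$nx < 250,
                  .data$ny2 > 6, .data$ny2 < 174) |>
    dplyr::ungroup()
  recovered <- linked |>
    dplyr::filter(.data$particle == .data$next_p) |>
    dplyr::distinct(.data$particle, .data$frame)
  got <- dplyr::inner_join(cons, recovered, by = c("particle", "frame"))
  expect_gt(nrow(got) / nrow(cons), 0.95)
})

test_that("PIV recovers known shifts", {
  set.seed(2)
  n <- 150
  x <- runif(n, -5, 133); y <- runif(n, -5, 133)
  fa <- spot_frame(x, y)
  # identical frames: zero field
  vz <- piv(fa, fa, window = 32, overlap = 0.5)
  expect_lt(max(abs(vz$dx)), 1e-9)
  expect_lt(max(abs(vz$dy)), 1e-9)
  expect_true(all(vz$peak_dx == 0))

  # integer shift: exact at the correlation peak on all interior windows
  fb <- spot_frame(x + 5, y)
  v <- piv(fa, fb, window = 32, overlap = 0.5)
  interior <- v$x > 24 & v$x < 104 & v$y > 24 & v$y < 104
  expect_true(all(v$peak_dx[interior] == 5))
  expect_true(all(v$peak_dy[interior] == 0))

  # subpixel shift within 0.1 px (median over interior windows)
  fc <- spot_frame(x + 2.5, y)
  v2 <- piv(fa, fc, window = 32, overlap = 0.5)
  expect_lt(median(abs(v2$dx[interior] - 2.5)), 0.1)
  expect_lt(median(abs(v2$dy[interior])), 0.1)

  # velocity conversion: px/frame -> um/s round-trip
  ps <- 0.65; fr <- 25
  expect_equal(v2$u, v2$dx * ps * fr)
  expect_equal(v2$u / ps / fr, v2$dx)

  expect_error(piv(fa, fb, window = 256), "larger")
  expect_error(piv(fa, fb[1:64, ], window = 32), "shape")
})

test_that("PIV is translation-equivariant", {
  set.seed(5)
  n <- 180
  x <- runif(n, -5, 160); y <- runif(n, -5, 160)
  fa <- spot_frame(x, y, dim_px = c(160, 160))
  fb <- spot_frame(x + 2.5, y + 1, dim_px = c(160, 160))
  v1 <- piv(fa[1:128, 1:128], fb[1:128, 1:128], window = 32, overlap = 0.5)
  v2 <- piv(fa[17:144, 17:144], fb[17:144, 17:144], window = 32, overlap = 0.5)
  expect_lt(abs(median(v1$dx) - median(v2$dx)), 0.05)
  expect_lt(abs(median(v1$dy) - median(v2$dy)), 0.05)
})

test_that("homogeneity statistics behave on exact and degenerate input", {
  vecs <- tibble::tibble(x = runif(30, 0, 100), y = runif(30, 0, 100),
                         u = 80, v = 0)
  hg <- flow_homogeneity(vecs)
  expect_equal(hg$speed_cv, 0)
  expect_equal(hg$direction_sd_deg, 0)
  expect_equal(hg$mean_speed, 80)
  # ROI excluding everything -> error
  expect_error(flow_homogeneity(vecs, roi = c(1000, 2000, 0, 100)), "vectors")
})
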