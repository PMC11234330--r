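#' Detect fluorescent spots in a frame
#'
#' Finds local intensity maxima above a threshold (Otsu's method on the
#' frame by default, or an absolute value), suppresses maxima closer than
#' `min_separation`, and refines each to an intensity-weighted subpixel
#' centroid over a small window (local background subtracted).
#'
#' @param frame Numeric matrix (rows = y, grayscale).
#' @param threshold_method `"otsu"` or `"absolute"`.
#' @param threshold Absolute threshold (counts), used when
#'   `threshold_method = "absolute"`.
#' @param min_separation Minimum distance between detections in px.
#' @param window Centroid window half-width in px.
#' @param bit_depth Bit depth used to scale the frame for Otsu.
#' @return A tibble of detections: `x`, `y` (subpixel, px; x = column),
#'   `intensity` (integrated above local background), `peak`.
#' @export
detect_spots <- function(frame, threshold_method = c("otsu", "absolute"),
                         threshold = NULL, min_separation = 3, window = 3,
                         bit_depth = 8) {
  threshold_method <- match.arg(threshold_method)
  thr <- if (threshold_method == "absolute") {
    if (is.null(threshold)) stop("give `threshold`", call. = FALSE)
    threshold
  } else {
    maxv <- max(2^bit_depth - 1, max(frame))
    ot <- EBImage::otsu(EBImage::Image(t(frame) / maxv), range = c(0, 1)) * maxv
    # noise-floor guard: Otsu undershoots on sparse-spot frames whose
    # histogram is dominated by background noise
    max(ot, median(frame) + 5 * mad(frame))
  }
  ny <- nrow(frame); nx <- ncol(frame)
  if (ny < 3 || nx < 3) return(empty_detections())
  core <- frame[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= frame[2:(ny - 1) + di, 2:(nx - 1) + dj]
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) == 0) return(empty_detections())
  py <- pk[, 1] + 1; px <- pk[, 2] + 1
  ints <- frame[cbind(py, px)]
  # greedy non-maximum suppression by peak intensity
  ord <- order(-ints)
  keep <- logical(length(ord))
  kx <- numeric(0); ky <- numeric(0)
  for (m in ord) {
    if (length(kx) == 0 ||
        min((kx - px[m])^2 + (ky - py[m])^2) >= min_separation^2) {
      keep[m] <- TRUE
      kx <- c(kx, px[m]); ky <- c(ky, py[m])
    }
  }
  py <- py[keep]; px <- px[keep]
  # subpixel centroid per detection
  n <- length(px)
  cx <- numeric(n); cy <- numeric(n); ci <- numeric(n)
  ok <- logical(n)
  for (m in seq_len(n)) {
    r0 <- max(1, py[m] - window); r1 <- min(ny, py[m] + window)
    c0 <- max(1, px[m] - window); c1 <- min(nx, px[m] + window)
    w <- frame[r0:r1, c0:c1]
    w <- pmax(w - min(w), 0)
    s <- sum(w)
    if (s == 0) next
    cx[m] <- sum(colSums(w) * (c0:c1)) / s
    cy[m] <- sum(rowSums(w) * (r0:r1)) / s
    ci[m] <- s
    ok[m] <- TRUE
  }
  tibble::tibble(x = cx[ok], y = cy[ok], intensity = ci[ok],
                 peak = frame[cbind(py, px)][ok])
}

empty_detections <- function() {
  tibble::tibble(x = double(), y = double(), intensity = double(),
                 peak = double())
}

#' Detect spots in every frame of a stack
#'
#' @param stack A `frame_stack`.
#' @param ... Passed to [detect_spots()].
#' @return A tibble of detections with a `frame` column.
#' @export
detect_stack <- function(stack, ...) {
  purrr::map_dfr(seq_along(stack$frames), function(f) {
    d <- detect_spots(stack$frames[[f]], bit_depth = stack$optics$bit_depth, ...)
    if (nrow(d)) d$frame <- f
    d
  })
}

#' Link detections into tracks (mean-flow-guided PTV)
#'
#' For each consecutive frame pair, candidate matches are sought inside a
#' search disk centered at the expected displacement (the mean flow velocity
#' times the frame interval, in pixels) with radius `radius_factor` times
#' the expected shift (floor 3 px). Assignments are mutual nearest
#' neighbors; candidates at equal distance (ambiguous) are dropped rather
#' than guessed. Per-step velocities are attached via the pixel size and
#' frame interval.
#'
#' @param detections A tibble with `frame`, `x`, `y` (px), e.g. from
#'   [detect_stack()].
#' @param expected_velocity Mean flow velocity in um s^-1; a scalar (flow
#'   along +x) or length-2 vector `c(u, v)`.
#' @param optics An [optics_spec()] providing pixel size and frame rate.
#' @param radius_factor Search radius as a fraction of the expected shift.
#' @param min_radius Floor on the search radius in px.
#' @return A `track_set` tibble: `track`, `frame`, `x`, `y`, `u`, `v`
#'   (um s^-1, the step velocity leaving this detection; NA on the last
#'   detection of a track).
#' @export
link_ptv <- function(detections, expected_velocity, optics = optics_spec(),
                     radius_factor = 0.5, min_radius = 3) {
  if (is.null(optics$pixel_size) || is.null(optics$frame_rate)) {
    stop("optics calibration (pixel size, frame rate) required", call. = FALSE)
  }
  if (length(expected_velocity) == 1) expected_velocity <- c(expected_velocity, 0)
  ps <- optics$pixel_size; fr <- optics$frame_rate
  shift_px <- expected_velocity / ps / fr
  radius <- max(min_radius, radius_factor * sqrt(sum(shift_px^2)))

  frames <- sort(unique(detections$frame))
  det <- split(detections, detections$frame)
  # assign track ids progressively
  det <- lapply(det, function(d) { d$track <- NA_integer_; d })
  next_id <- 1L
  links <- list()
  for (fi in seq_along(frames)[-length(frames)]) {
    fa <- as.character(frames[fi]); fb <- as.character(frames[fi + 1])
    if (frames[fi + 1] != frames[fi] + 1) next
    A <- det[[fa]]; B <- det[[fb]]
    if (nrow(A) == 0 || nrow(B) == 0) next
    # distance of each B to each A's predicted position
    pred_x <- A$x + shift_px[1]; pred_y <- A$y + shift_px[2]
    d2 <- outer(pred_x, B$x, function(p, b) (p - b)^2) +
      outer(pred_y, B$y, function(p, b) (p - b)^2)
    d2[d2 > radius^2] <- Inf
    match_ab <- apply(d2, 1, function(r) if (all(is.infinite(r))) NA_integer_
                      else which.min(r))
    match_ba <- apply(d2, 2, function(c_) if (all(is.infinite(c_))) NA_integer_
                      else which.min(c_))
    eps <- 1e-9
    for (a in seq_len(nrow(A))) {
      b <- match_ab[a]
      if (is.na(b) || is.na(match_ba[b]) || match_ba[b] != a) next
      # ambiguity: another candidate at (numerically) the same distance
      if (sum(abs(d2[a, ] - d2[a, b]) < eps) > 1) next
      if (sum(abs(d2[, b] - d2[a, b]) < eps) > 1) next
      id <- A$track[a]
      if (is.na(id)) { id <- next_id; next_id <- next_id + 1L
        det[[fa]]$track[a] <- id }
      det[[fb]]$track[b] <- id
      links[[length(links) + 1L]] <- tibble::tibble(
        track = id, frame = frames[fi],
        u = (B$x[b] - A$x[a]) * ps * fr,
        v = (B$y[b] - A$y[a]) * ps * fr
      )
    }
  }
  all_det <- dplyr::bind_rows(det)
  all_det <- all_det[!is.na(all_det$track), ]
  lk <- dplyr::bind_rows(links)
  if (nrow(lk) == 0) {
    lk <- tibble::tibble(track = integer(), frame = integer(),
                         u = double(), v = double())
  }
  out <- dplyr::left_join(all_det, lk, by = c("track", "frame")) |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::select("track", "frame", "x", "y", "u", "v")
  class(out) <- c("track_set", class(out))
  out
}

#' Per-track velocity summary
#'
#' Aggregates step velocities per track by the median (robust to single
#' mislinks).
#'
#' @param tracks A `track_set` from [link_ptv()].
#' @return A tibble: `track`, `n_steps`, `u`, `v`, `speed` (um s^-1),
#'   `direction` (radians).
#' @export
track_velocities <- function(tracks) {
  tracks |>
    dplyr::filter(!is.na(.data$u)) |>
    dplyr::group_by(.data$track) |>
    dplyr::summarise(n_steps = dplyr::n(),
                     u = median(.data$u), v = median(.data$v),
                     .groups = "drop") |>
    dplyr::mutate(speed = sqrt(.data$u^2 + .data$v^2),
                  direction = atan2(.data$v, .data$u))
}

#' Flow-homogeneity statistics over a region of interest
#'
#' Mean speed, coefficient of variation of speed and circular standard
#' deviation of the flow direction over vectors inside the ROI; the summary
#' used to verify that the central analysis area carries uniform flow in
#' speed and direction.
#'
#' @param vectors A tibble with `x`, `y` (position, um or px — the ROI is in
#'   the same units), `u`, `v` (um s^-1): PIV vectors or PTV track
#'   velocities with positions.
#' @param roi Length-4 numeric `c(xmin, xmax, ymin, ymax)`, or `NULL` for
#'   all vectors.
#' @param min_vectors Minimum number of vectors required.
#' @return A one-row tibble: `n`, `mean_speed`, `speed_cv`,
#'   `direction_sd_deg` (circular SD, degrees).
#' @export
flow_homogeneity <- function(vectors, roi = NULL, min_vectors = 10) {
  v <- vectors
  if (!is.null(roi)) {
    v <- dplyr::filter(v, .data$x >= roi[1], .data$x <= roi[2],
                       .data$y >= roi[3], .data$y <= roi[4])
  }
  v <- dplyr::filter(v, is.finite(.data$u), is.finite(.data$v))
  if (nrow(v) < min_vectors) {
    stop(sprintf("only %d vectors in ROI (need >= %d)", nrow(v), min_vectors),
         call. = FALSE)
  }
  sp <- sqrt(v$u^2 + v$v^2)
  th <- atan2(v$v, v$u)
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  circ_sd <- sqrt(pmax(-2 * log(R), 0)) * 180 / pi
  tibble::tibble(
    n = nrow(v),
    mean_speed = mean(sp),
    speed_cv = if (mean(sp) > 0) sd(sp) / mean(sp) else 0,
    direction_sd_deg = circ_sd
  )
}
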