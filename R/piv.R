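#' Particle image velocimetry on a frame pair
#'
#' Splits the frames into interrogation windows, estimates each window's
#' displacement from the peak of the frequency-domain cross-correlation
#' (mean-subtracted windows), refines the peak with a three-point Gaussian
#' fit in each axis, and converts displacements to velocities with the pixel
#' size and frame interval.
#'
#' @param frame_a,frame_b Numeric matrices of equal size (rows = y).
#' @param window Interrogation window size in px (>= 16).
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @param optics An [optics_spec()] (pixel size, frame rate).
#' @return A `vector_grid` tibble: window centers `x`, `y` (px), refined
#'   displacements `dx`, `dy` (px), the integer correlation-peak
#'   displacements `peak_dx`, `peak_dy`, velocities `u`, `v` (um s^-1) and
#'   `quality` (normalized correlation peak, in `[0, 1]`).
#' @export
piv <- function(frame_a, frame_b, window = 32, overlap = 0.5,
                optics = optics_spec()) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop("frames must have the same shape", call. = FALSE)
  }
  if (window < 16) stop("`window` must be >= 16 px", call. = FALSE)
  if (window > min(dim(frame_a))) {
    stop("`window` larger than the frame", call. = FALSE)
  }
  step <- max(1, round(window * (1 - overlap)))
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  r0s <- seq(1, ny - window + 1, by = step)
  c0s <- seq(1, nx - window + 1, by = step)
  ps <- optics$pixel_size; fr <- optics$frame_rate

  # search lags up to a quarter window (one-quarter rule), so the window
  # overlap never drops below 75% and the unbiased estimate stays stable
  L <- window %/% 4
  lag_idx <- c(seq_len(L + 1), (2 * window - L + 1):(2 * window)) # 0..L, -L..-1
  lags <- c(0:L, -L:-1)
  ord <- order(lags)
  lags_s <- lags[ord]
  overlap <- window - abs(lags_s)
  unbias <- outer(overlap, overlap) # linear-correlation overlap counts

  res <- list()
  for (r0 in r0s) for (c0 in c0s) {
    wa <- frame_a[r0:(r0 + window - 1), c0:(c0 + window - 1)]
    wb <- frame_b[r0:(r0 + window - 1), c0:(c0 + window - 1)]
    # zero-padded linear cross-correlation (no wrap-around artifacts)
    pa <- matrix(0, 2 * window, 2 * window); pa[1:window, 1:window] <- wa - mean(wa)
    pb <- matrix(0, 2 * window, 2 * window); pb[1:window, 1:window] <- wb - mean(wb)
    cc_full <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / (4 * window^2)
    cc <- cc_full[lag_idx, lag_idx][ord, ord] / unbias # rows/cols: lag -L..L
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, , drop = TRUE]
    sy <- lags_s[pk[1]]; sx <- lags_s[pk[2]]
    # three-point Gaussian subpixel refinement (within the lag table)
    gy <- if (pk[1] > 1 && pk[1] < nrow(cc)) {
      gauss3(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]], cc[pk[1] + 1, pk[2]])
    } else 0
    gx <- if (pk[2] > 1 && pk[2] < ncol(cc)) {
      gauss3(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]], cc[pk[1], pk[2] + 1])
    } else 0
    na <- sqrt(sum((wa - mean(wa))^2)); nb <- sqrt(sum((wb - mean(wb))^2))
    q <- if (na > 0 && nb > 0) max(cc) * window^2 / (na * nb) else 0
    res[[length(res) + 1L]] <- tibble::tibble(
      x = c0 + (window - 1) / 2, y = r0 + (window - 1) / 2,
      dx = sx + gx, dy = sy + gy,
      peak_dx = sx, peak_dy = sy,
      quality = min(max(q, 0), 1)
    )
  }
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(u = .data$dx * ps * fr, v = .data$dy * ps * fr) |>
    dplyr::select("x", "y", "dx", "dy", "peak_dx", "peak_dy", "u", "v",
                  "quality")
  class(out) <- c("vector_grid", class(out))
  attr(out, "window") <- window
  attr(out, "overlap") <- overlap
  out
}

wrap_idx <- function(i, n) ((i - 1) %% n) + 1

# three-point Gaussian peak interpolation; returns offset in (-0.5, 0.5)
gauss3 <- function(cm, c0, cp) {
  if (any(c(cm, c0, cp) <= 0)) { # fall back to parabola for non-positive lobes
    den <- cm - 2 * c0 + cp
    if (den == 0) return(0)
    off <- 0.5 * (cm - cp) / den
    return(max(min(off, 0.5), -0.5))
  }
  den <- log(cm) - 2 * log(c0) + log(cp)
  if (den == 0) return(0)
  off <- 0.5 * (log(cm) - log(cp)) / den
  max(min(off, 0.5), -0.5)
}
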