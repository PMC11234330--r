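#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||%
#' @importFrom stats fft median sd rnorm runif rpois rlnorm setNames mad approx
#' @importFrom utils head tail
NULL

# centered-difference gradients on a matrix field (one-sided at edges)
# along columns (x) ...
ddx <- function(m, ds) {
  nx <- ncol(m)
  g <- matrix(0, nrow(m), nx)
  if (nx >= 3) g[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * ds)
  g[, 1] <- (m[, 2] - m[, 1]) / ds
  g[, nx] <- (m[, nx] - m[, nx - 1]) / ds
  g
}

# ... and along rows (y or z)
ddy <- function(m, ds) {
  ny <- nrow(m)
  g <- matrix(0, ny, ncol(m))
  if (ny >= 3) g[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * ds)
  g[1, ] <- (m[2, ] - m[1, ]) / ds
  g[ny, ] <- (m[ny, ] - m[ny - 1, ]) / ds
  g
}

# vectorized bilinear interpolation of a matrix at physical points
# (rows = second coordinate, cols = first); clamps to the domain
interp_bilinear <- function(m, x, y, origin, spacing) {
  gx <- (x - origin[1]) / spacing + 0.5 # fractional column
  gy <- (y - origin[2]) / spacing + 0.5
  gx <- pmin(pmax(gx, 1), ncol(m)); gy <- pmin(pmax(gy, 1), nrow(m))
  j0 <- pmin(floor(gx), ncol(m) - 1); i0 <- pmin(floor(gy), nrow(m) - 1)
  fx <- gx - j0; fy <- gy - i0
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    m[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    m[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# run code with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
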