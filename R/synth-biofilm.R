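#' Generate a synthetic biofilm fluorescence image
#'
#' Places blurred fluorescent colonies on a microtrap depth map according to
#' the localization regime: on the walls (high inoculum, low flow), in the
#' walls' corners (low inoculum, low flow) or at the cavity centers of the
#' first three cavities in flow direction (low inoculum, high flow, where
#' single microvortices deposit cells). Colony count scales with the
#' concentration class; sizes, positions and brightness are stochastic but
#' fully determined by the regime's seed. The ground truth (colony table and
#' the region each was drawn for) is returned alongside.
#'
#' @param regime A [regime_spec()].
#' @param depth A microtrap `depth_map` from [build_microtrap()].
#' @param optics An [optics_spec()]; its pixel size sets the image
#'   resolution, its background/noise fields the noise model.
#' @param n_colonies Number of colonies; default 60 for the high
#'   concentration class, 20 for low. Zero gives a background-only image.
#' @param amplitude Median peak brightness of a colony (counts).
#' @return A `biofilm_image`: list with `image` (numeric matrix, rows = y),
#'   `optics`, `origin` (um), `truth` (tibble: x, y and sigma in um,
#'   amplitude, region), and `regime`.
#' @export
generate_biofilm_image <- function(regime, depth, optics = optics_spec(),
                                   n_colonies = NULL, amplitude = 90) {
  if (is.null(depth$feature$cavities)) {
    stop("`depth` must carry microtrap feature metadata", call. = FALSE)
  }
  ps <- optics$pixel_size
  ext_x <- ncol(depth$h) * depth$spacing
  ext_y <- nrow(depth$h) * depth$spacing
  nxp <- round(ext_x / ps); nyp <- round(ext_y / ps)
  origin <- depth$origin
  n_colonies <- n_colonies %||%
    if (regime$concentration_class == "high") 60L else 20L

  with_seed(regime$rng_seed, {
    truth <- sample_colonies(regime$pattern, n_colonies, depth, amplitude)
    img <- matrix(optics$background, nyp, nxp)
    for (m in seq_len(nrow(truth))) {
      cx <- (truth$x[m] - origin[1]) / ps + 0.5
      cy <- (truth$y[m] - origin[2]) / ps + 0.5
      sg <- truth$sigma[m] / ps # colony radius is stored in um
      wr <- ceiling(4 * sg)
      c0 <- max(1, floor(cx) - wr); c1 <- min(nxp, floor(cx) + wr)
      r0 <- max(1, floor(cy) - wr); r1 <- min(nyp, floor(cy) + wr)
      if (c0 > c1 || r0 > r1) next
      cc <- c0:c1; rr <- r0:r1
      img[rr, cc] <- img[rr, cc] + truth$amplitude[m] *
        outer(exp(-(rr - cy)^2 / (2 * sg^2)), exp(-(cc - cx)^2 / (2 * sg^2)))
    }
    img[] <- rpois(length(img), pmax(img, 0)) +
      rnorm(length(img), 0, optics$noise_sigma)
    img[] <- pmin(pmax(round(img), 0), 2^optics$bit_depth - 1)

    structure(
      list(image = img, optics = optics, origin = origin, truth = truth,
           regime = regime),
      class = "biofilm_image"
    )
  })
}

# draw colony centers for a pattern from the depth-map feature metadata
sample_colonies <- function(pattern, n, depth, amplitude) {
  if (n == 0) {
    return(tibble::tibble(x = double(), y = double(), sigma = double(),
                          amplitude = double(), region = character()))
  }
  feat <- depth$feature
  xs <- dm_x(depth); ys <- dm_y(depth)
  jitter_cell <- depth$spacing / 2
  pos <- switch(pattern,
    walls = {
      cells <- which(feat$solid_sealed)
      pick <- sample(cells, n, replace = TRUE)
      tibble::tibble(
        x = xs[col(feat$solid_sealed)[pick]] + runif(n, -jitter_cell, jitter_cell),
        y = ys[row(feat$solid_sealed)[pick]] + runif(n, -jitter_cell, jitter_cell),
        region = "walls"
      )
    },
    corners = {
      pick <- sample(nrow(feat$corners), n, replace = TRUE)
      tibble::tibble(
        x = feat$corners$x[pick] + rnorm(n, 0, 4),
        y = feat$corners$y[pick] + rnorm(n, 0, 4),
        region = "corners"
      )
    },
    cavity_centers = {
      cc <- feat$cavity_centers
      n_front <- max(1L, round(0.85 * n))
      front <- cc[cc$cavity <= 3, ]
      back <- cc[cc$cavity > 3, ]
      pf <- sample(nrow(front), n_front, replace = TRUE)
      pb <- if (n - n_front > 0) sample(nrow(back), n - n_front, replace = TRUE)
        else integer(0)
      cx <- c(front$x[pf], back$x[pb]); cy <- c(front$y[pf], back$y[pb])
      x <- cx + rnorm(n, 0, 5); y <- cy + rnorm(n, 0, 4)
      # colonies sit at vortex cores inside the cavities: redraw any jitter
      # that lands outside the enclosed cavity region
      in_cavity <- function(x, y) {
        j <- pmin(pmax(ceiling((x - depth$origin[1]) / depth$spacing), 1),
                  ncol(feat$cavities))
        i <- pmin(pmax(ceiling((y - depth$origin[2]) / depth$spacing), 1),
                  nrow(feat$cavities))
        feat$cavities[cbind(i, j)] > 0
      }
      for (try in 1:50) {
        bad <- !in_cavity(x, y)
        if (!any(bad)) break
        x[bad] <- cx[bad] + rnorm(sum(bad), 0, 5)
        y[bad] <- cy[bad] + rnorm(sum(bad), 0, 4)
      }
      bad <- !in_cavity(x, y)
      x[bad] <- cx[bad]; y[bad] <- cy[bad]
      tibble::tibble(
        x = x, y = y,
        region = rep(c("cavity_front", "cavity_back"),
                     c(n_front, n - n_front))
      )
    }
  )
  pos$x <- pmin(pmax(pos$x, xs[1]), xs[length(xs)])
  pos$y <- pmin(pmax(pos$y, ys[1]), ys[length(ys)])
  # colony radius in um: single colonies a few cell lengths across; kept
  # below the cavity half-width so localization regimes stay resolvable
  pos$sigma <- if (pattern == "cavity_centers") runif(n, 2.5, 5) else
    runif(n, 3, 6)
  pos$amplitude <- rlnorm(n, log(amplitude), 0.3) *
    ifelse(pos$region == "cavity_back", 0.35, 1)
  pos[, c("x", "y", "sigma", "amplitude", "region")]
}

#' @export
print.biofilm_image <- function(x, ...) {
  cat(sprintf("<biofilm_image> %s regime, %d x %d px, %d colonies\n",
              x$regime$pattern, ncol(x$image), nrow(x$image), nrow(x$truth)))
  invisible(x)
}
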