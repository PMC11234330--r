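#' Region masks of a microtrap at image resolution
#'
#' Partitions an image grid covering a microtrap depth map into the regions
#' used for biofilm occupancy analysis: `wall` (the feature footprint
#' dilated by half a wall thickness, wide enough to absorb wall-adherent
#' colonies without swallowing the narrow inter-funnel cavities), `corner`
#' (the wall band intersected with
#' disks of one wall-thickness radius around the wall junction/apex
#' points), `cavity` (the enclosed cavity regions minus the wall band) and
#' `outside` (everything else, used for background estimation). Also
#' returns the per-cavity label map restricted to the cavity region.
#'
#' @param depth A microtrap `depth_map`.
#' @param dim_px Length-2 integer image size `c(width, height)` in px.
#' @param pixel_size Image pixel size in um.
#' @param origin Physical coordinates (um) of the image's lower-left corner.
#' @return A list of logical matrices `wall`, `corner`, `cavity`, `outside`
#'   and an integer matrix `cavity_labels`, all of size `rev(dim_px)`.
#' @export
region_masks <- function(depth, dim_px, pixel_size, origin = depth$origin) {
  t_um <- depth$feature$spec$wall_thickness
  # dilate the solid footprint by half a wall thickness (disc brush), on the
  # depth-map grid
  rad_cells <- max(1, round(t_um / 2 / depth$spacing))
  brush_size <- 2 * rad_cells + 1
  solid_x <- EBImage::Image(t(depth$solid) * 1)
  wall_dm <- t(EBImage::imageData(
    EBImage::dilate(solid_x, EBImage::makeBrush(brush_size, "disc")))) > 0

  nxp <- dim_px[1]; nyp <- dim_px[2]
  px_x <- origin[1] + (seq_len(nxp) - 0.5) * pixel_size
  px_y <- origin[2] + (seq_len(nyp) - 0.5) * pixel_size
  # nearest depth-map cell per pixel
  jj <- pmin(pmax(ceiling((px_x - depth$origin[1]) / depth$spacing), 1),
             ncol(depth$h))
  ii <- pmin(pmax(ceiling((px_y - depth$origin[2]) / depth$spacing), 1),
             nrow(depth$h))
  wall <- wall_dm[ii, jj, drop = FALSE]
  labs <- depth$feature$cavities[ii, jj, drop = FALSE]

  corner <- matrix(FALSE, nyp, nxp)
  corners <- depth$feature$corners
  if (!is.null(corners) && nrow(corners)) {
    X <- matrix(px_x, nyp, nxp, byrow = TRUE)
    Y <- matrix(px_y, nyp, nxp)
    for (m in seq_len(nrow(corners))) {
      corner <- corner |
        ((X - corners$x[m])^2 + (Y - corners$y[m])^2 <= t_um^2)
    }
    corner <- corner & wall
  }
  cavity <- labs > 0 & !wall
  outside <- !wall & !cavity
  list(wall = wall, corner = corner, cavity = cavity, outside = outside,
       cavity_labels = ifelse(cavity, labs, 0L))
}

#' Register replicate trap images and average them
#'
#' Aligns each image to the reference trap footprint by translation: the
#' integer shift is estimated by normalized cross-correlation against a
#' template rendered from the depth map's trap footprint, images whose
#' correlation peak falls below `min_confidence` are excluded with a
#' warning, and the aligned images are averaged pixelwise.
#'
#' @param images A list of numeric matrices of identical size (rows = y).
#' @param reference A microtrap `depth_map` whose footprint serves as the
#'   alignment template, or a numeric matrix template of the same size as
#'   the images.
#' @param pixel_size Image pixel size in um (to render the template).
#' @param min_confidence Phase-correlation peak below which an image is
#'   excluded.
#' @return The averaged image (numeric matrix) with attributes `offsets`
#'   (tibble: image, dx, dy, confidence, included) describing the
#'   registration.
#' @export
register_and_average <- function(images, reference, pixel_size = NULL,
                                 min_confidence = 0.1) {
  if (length(images) < 1) stop("no images given", call. = FALSE)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(im) all(dim(im) == d), TRUE))) {
    stop("images must share one size", call. = FALSE)
  }
  tmpl <- if (inherits(reference, "depth_map")) {
    ps <- pixel_size %||% reference$spacing
    masks <- region_masks(reference, c(d[2], d[1]), ps)
    # walls carry most fluorescence mass across regimes; a blurred footprint
    # correlates with any of them
    blur_matrix((!masks$outside) * 1, sigma = 2)
  } else reference
  offs <- purrr::map_dfr(seq_along(images), function(m) {
    pc <- phase_correlate(tmpl, images[[m]])
    tibble::tibble(image = m, dx = pc$dx, dy = pc$dy, confidence = pc$peak)
  })
  offs$included <- offs$confidence >= min_confidence
  if (!any(offs$included)) {
    stop("no image passed the alignment confidence threshold", call. = FALSE)
  }
  if (any(!offs$included)) {
    warning(sprintf("%d image(s) excluded by alignment confidence",
                    sum(!offs$included)), call. = FALSE)
  }
  # remove the consensus offset: template matching against stochastic colony
  # images can carry a small common bias; relative alignment is what keeps
  # the average sharp
  offs$dx <- offs$dx - median(offs$dx[offs$included])
  offs$dy <- offs$dy - median(offs$dy[offs$included])
  acc <- matrix(0, d[1], d[2])
  for (m in which(offs$included)) {
    acc <- acc + roll_matrix(images[[m]], offs$dy[m], offs$dx[m])
  }
  avg <- acc / sum(offs$included)
  attr(avg, "offsets") <- offs
  avg
}

# normalized cross-correlation: returns the integer shift that, applied to
# `img` (roll_matrix), aligns it onto `tmpl`; `peak` is the normalized
# correlation coefficient at that shift
phase_correlate <- function(tmpl, img) {
  a <- img - mean(img); b <- tmpl - mean(tmpl)
  r <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / length(a)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  r <- r / max(na * nb, 1e-300)
  pk <- which(r == max(r), arr.ind = TRUE)[1, , drop = TRUE]
  sy <- pk[1] - 1; sx <- pk[2] - 1
  if (sy > nrow(r) / 2) sy <- sy - nrow(r)
  if (sx > ncol(r) / 2) sx <- sx - ncol(r)
  list(dy = unname(sy), dx = unname(sx), peak = max(r))
}

# circularly shift a matrix by (dy, dx)
roll_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[wrap_idx(seq_len(ny) - dy, ny), wrap_idx(seq_len(nx) - dx, nx)]
}

# small separable Gaussian blur used for templates
blur_matrix <- function(m, sigma) {
  w <- ceiling(3 * sigma)
  k <- exp(-((-w):w)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) as.numeric(stats::filter(c(rep(v[1], w), v,
    rep(v[length(v)], w)), k, sides = 2))[(w + 1):(w + length(v))]
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

#' Intensity profile versus downstream distance
#'
#' Column-wise mean intensity over the trap's cross-flow extent, binned at
#' pixel resolution over a downstream window (default 0-650 um: margins
#' plus the 410 um trap).
#'
#' @param image Numeric matrix (rows = y).
#' @param depth The microtrap `depth_map` the image covers.
#' @param window Length-2 numeric, downstream window in um (absolute domain
#'   coordinates).
#' @param y_extent Length-2 numeric cross-flow extent in um; default the
#'   trap footprint width.
#' @param pixel_size Image pixel size in um.
#' @param origin Image origin (um).
#' @return An `intensity_profile` tibble: `x` (um, bin center),
#'   `intensity` (mean counts), `n` (pixels per bin).
#' @export
intensity_profile <- function(image, depth, window = NULL, y_extent = NULL,
                              pixel_size = depth$spacing,
                              origin = depth$origin) {
  bb <- depth$feature$bbox
  window <- window %||% c(origin[1], origin[1] + 650)
  y_extent <- y_extent %||% c(bb["ymin"], bb["ymax"])
  nyp <- nrow(image); nxp <- ncol(image)
  px_x <- origin[1] + (seq_len(nxp) - 0.5) * pixel_size
  px_y <- origin[2] + (seq_len(nyp) - 0.5) * pixel_size
  cols <- which(px_x >= window[1] & px_x <= window[2])
  rows <- which(px_y >= y_extent[1] & px_y <= y_extent[2])
  if (length(cols) == 0 || length(rows) == 0) {
    stop("profile window lies outside the image", call. = FALSE)
  }
  out <- tibble::tibble(
    x = px_x[cols],
    intensity = colMeans(image[rows, cols, drop = FALSE]),
    n = length(rows)
  )
  class(out) <- c("intensity_profile", class(out))
  out
}

#' Wall / corner / cavity occupancy of a biofilm image
#'
#' Estimates the background as the median of outside-trap pixels plus a
#' noise floor (`noise_k` times the MAD of the same pixels, so shot/read
#' noise does not masquerade as diffuse signal), then partitions the
#' above-background intensity mass among the wall band, the corner disks
#' and the cavity regions (see [region_masks()]). Fractions are of the
#' total above-background mass, so they sum to at most 1 (the remainder
#' sits outside the trap).
#'
#' @param image Numeric matrix (rows = y).
#' @param depth The microtrap `depth_map`.
#' @param pixel_size Image pixel size in um.
#' @param origin Image origin (um).
#' @param noise_k Noise-floor multiplier on the outside-pixel MAD.
#' @return An `occupancy_report`: list with `wall_fraction`,
#'   `corner_fraction`, `cavity_fraction`, `background`,
#'   `corner_area_share` (fraction of the wall band covered by corner
#'   disks, the uniform-coverage baseline used by [classify_regime()]),
#'   and `per_cavity` (tibble: cavity, mean above-background intensity).
#' @export
occupancy <- function(image, depth, pixel_size = depth$spacing,
                      origin = depth$origin, noise_k = 3) {
  if (max(image) > 0 && min(image) == max(image)) {
    stop("degenerate (saturated or constant) image: background undefined",
         call. = FALSE)
  }
  masks <- region_masks(depth, c(ncol(image), nrow(image)), pixel_size,
                        origin)
  bg <- median(image[masks$outside]) +
    noise_k * mad(image[masks$outside])
  excess <- pmax(image - bg, 0)
  total <- sum(excess)
  frac <- function(mask) if (total > 0) sum(excess[mask]) / total else 0
  per_cavity <- purrr::map_dfr(seq_len(max(masks$cavity_labels, 0)),
    function(k) tibble::tibble(
      cavity = k,
      mean_intensity = mean(excess[masks$cavity_labels == k])
    ))
  structure(list(
    wall_fraction = frac(masks$wall),
    corner_fraction = frac(masks$corner),
    cavity_fraction = frac(masks$cavity),
    background = bg,
    corner_area_share = sum(masks$corner) / max(sum(masks$wall), 1),
    per_cavity = per_cavity
  ), class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf(
    "<occupancy_report> wall %.2f, corner %.2f, cavity %.2f (background %g)\n",
    x$wall_fraction, x$corner_fraction, x$cavity_fraction, x$background))
  invisible(x)
}

#' @rdname occupancy
#' @param x An `occupancy_report`.
#' @param ... Unused.
#' @export
tidy.occupancy_report <- function(x, ...) x$per_cavity

#' @rdname occupancy
#' @export
glance.occupancy_report <- function(x, ...) {
  tibble::tibble(wall_fraction = x$wall_fraction,
                 corner_fraction = x$corner_fraction,
                 cavity_fraction = x$cavity_fraction,
                 background = x$background)
}

#' Classify the biofilm localization regime
#'
#' Rule-based decision over an occupancy report: if the cavity fraction
#' dominates the wall fraction the image is a cavity-centers regime;
#' otherwise the corner share of the wall-band intensity, compared with
#' the share expected under uniform wall coverage (the corner disks' area
#' fraction of the wall band), separates corners from walls: an enrichment
#' of at least `corner_enrichment` flags corners. The enrichment baseline
#' is needed because the corner disks cover a sizable area fraction of the
#' wall band, so even uniformly wall-adherent biofilm places roughly that
#' share of its mass inside them. Exact ties or an all-zero report give
#' `"indeterminate"`.
#'
#' @param report An `occupancy_report`.
#' @param corner_enrichment Corner-share enrichment over the uniform
#'   baseline above which a wall-dominated image is classified as corners.
#' @return One of `"walls"`, `"corners"`, `"cavity_centers"`,
#'   `"indeterminate"`.
#' @export
classify_regime <- function(report, corner_enrichment = 1.5) {
  w <- report$wall_fraction; cv <- report$cavity_fraction
  if (w == 0 && cv == 0) return("indeterminate")
  if (cv > w) return("cavity_centers")
  if (cv == w) return("indeterminate")
  share <- report$corner_fraction / w
  baseline <- max(report$corner_area_share %||% 0.5, 1e-6)
  if (share / baseline >= corner_enrichment) "corners" else "walls"
}
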