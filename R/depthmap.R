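#' Depth maps
#'
#' A `depth_map` rasterizes the local vertical clearance h(x, y) of the
#' channel: h equals the channel height over open floor and channel height
#' minus feature height over microstructure walls (features reach only 2/3 of
#' the channel height, so h > 0 everywhere and flow passes over them).
#'
#' Coordinates: x increases downstream, y across the channel; the raster is
#' stored row-major with row = y index, column = x index; row 1 is the
#' smallest physical y (when displayed as an image, physical y increases down
#' the frame).
#'
#' @param h Numeric matrix of clearances in um (rows = y, cols = x).
#' @param spacing Cell size in um.
#' @param origin Length-2 numeric, physical coordinates (um) of the lower-left
#'   domain corner.
#' @param solid Logical matrix, TRUE over the feature footprint.
#' @param channel_height Channel height in um.
#' @param feature Optional list of feature metadata (type, footprint bbox,
#'   cavity labels, cavity centers, corner points, wall thickness).
#' @return An object of class `depth_map`.
#' @keywords internal
new_depth_map <- function(h, spacing, origin, solid, channel_height,
                          feature = NULL) {
  stopifnot(is.matrix(h), all(dim(h) == dim(solid)))
  if (any(h <= 0)) stop("clearance must be positive everywhere", call. = FALSE)
  structure(
    list(h = h, spacing = spacing, origin = origin, solid = solid,
         channel_height = channel_height, feature = feature),
    class = "depth_map"
  )
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf(
    "<depth_map> %d x %d cells @ %g um (%g x %g um), clearance %g-%g um%s\n",
    ncol(x$h), nrow(x$h), x$spacing,
    ncol(x$h) * x$spacing, nrow(x$h) * x$spacing,
    min(x$h), max(x$h),
    if (is.null(x$feature)) "" else paste0(", feature: ", x$feature$type)
  ))
  invisible(x)
}

# cell-center coordinate vectors (physical um)
dm_x <- function(dm) dm$origin[1] + (seq_len(ncol(dm$h)) - 0.5) * dm$spacing
dm_y <- function(dm) dm$origin[2] + (seq_len(nrow(dm$h)) - 0.5) * dm$spacing

#' Tidy a depth map into a tibble
#'
#' @param x A `depth_map`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `h`, `solid`.
#' @export
tidy.depth_map <- function(x, ...) {
  tibble::tibble(
    x = rep(dm_x(x), each = nrow(x$h)),
    y = rep(dm_y(x), times = ncol(x$h)),
    h = as.vector(x$h),
    solid = as.vector(x$solid)
  )
}

# rasterize a thick segment (capsule): TRUE where distance to segment <= radius
# xs, ys: coordinate vectors of the grid
rasterize_capsule <- function(xs, ys, p1, p2, radius) {
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) {
    d2 <- (X - p1[1])^2 + (Y - p1[2])^2
  } else {
    t <- pmin(1, pmax(0, ((X - p1[1]) * vx + (Y - p1[2]) * vy) / L2))
    d2 <- (X - p1[1] - t * vx)^2 + (Y - p1[2] - t * vy)^2
  }
  d2 <= radius^2
}

rasterize_rect <- function(xs, ys, x0, x1, y0, y1) {
  inx <- xs >= x0 & xs <= x1
  iny <- ys >= y0 & ys <= y1
  outer(iny, inx, `&`)
}

#' Build a plain channel depth map
#'
#' Uniform clearance equal to the channel height over the analysis area (or a
#' custom area).
#'
#' @param spec A [channel_spec()].
#' @param area Length-2 numeric `c(x, y)` domain extent in um; defaults to the
#'   spec's analysis area.
#' @param origin Physical coordinates of the lower-left corner (um).
#' @return A [new_depth_map()] object.
#' @examples
#' build_channel(channel_spec(grid_spacing = 10))
#' @export
build_channel <- function(spec = channel_spec(), area = spec$analysis_area,
                          origin = c(0, 0)) {
  ds <- spec$grid_spacing
  if (!is.numeric(ds) || ds <= 0) stop("grid_spacing must be positive", call. = FALSE)
  nx <- max(1L, round(area[1] / ds))
  ny <- max(1L, round(area[2] / ds))
  h <- matrix(spec$height, nrow = ny, ncol = nx)
  solid <- matrix(FALSE, nrow = ny, ncol = nx)
  new_depth_map(h, ds, origin, solid, spec$height,
                feature = list(type = "none"))
}

# chevron apex positions and arm geometry for a microtrap spec (local coords,
# footprint x in [0, length], y in [0, width])
microtrap_layout <- function(spec) {
  W <- spec$width; L <- spec$length; t <- spec$wall_thickness
  dx_arm <- (W / 2 - t) / tan(spec$funnel_half_angle * pi / 180)
  n <- spec$funnels_with_flow + spec$funnels_against_flow
  a_first <- dx_arm + t / 2
  a_last <- L - dx_arm - t / 2
  if (a_last <= a_first) {
    stop("microtrap too short for the requested funnels", call. = FALSE)
  }
  apex_x <- seq(a_first, a_last, length.out = n)
  direction <- rep(c(1L, -1L),
                   c(spec$funnels_with_flow, spec$funnels_against_flow))
  list(apex_x = apex_x, direction = direction, dx_arm = dx_arm)
}

#' Build the microtrap depth map
#'
#' Rasterizes the nested-funnel microtrap (side rails plus chevron funnel
#' walls with apex gaps on the centerline) into a depth map with open margins
#' on all sides, and records cavity labels, cavity centers and wall-corner
#' points as feature metadata. The default margins place the trap leading
#' edge 120 um downstream of the domain inlet, so the standard 650 um
#' analysis window spans the whole domain length.
#'
#' @param spec A [microtrap_spec()].
#' @param channel A [channel_spec()] (supplies channel height and grid
#'   spacing).
#' @param margin Length-2 numeric, open margin in um upstream/downstream (x)
#'   and on each side (y) of the trap footprint.
#' @param origin Physical coordinates of the lower-left domain corner (um).
#' @return A [new_depth_map()] with `feature` metadata: `type`, `spec`,
#'   `bbox` (footprint, um), `cavities` (integer label matrix, 0 = not a
#'   cavity), `cavity_centers` (tibble, ordered downstream), `corners`
#'   (tibble of wall-junction and apex points).
#' @export
build_microtrap <- function(spec = microtrap_spec(), channel = channel_spec(),
                            margin = c(120, 120), origin = c(0, 0)) {
  if (spec$feature_height >= channel$height) {
    stop("feature height must be below the channel height", call. = FALSE)
  }
  if (spec$width + 2 * margin[2] > channel$width) {
    stop("microtrap and margins exceed the channel width", call. = FALSE)
  }
  ds <- channel$grid_spacing
  Lx <- spec$length + 2 * margin[1]
  Ly <- spec$width + 2 * margin[2]
  nx <- round(Lx / ds); ny <- round(Ly / ds)
  # rasterize in domain-local coordinates so the raster is exactly
  # translation-invariant; the origin only relabels coordinates
  xs <- (seq_len(nx) - 0.5) * ds
  ys <- (seq_len(ny) - 0.5) * ds

  # trap local frame -> domain frame
  x0 <- margin[1]; y0 <- margin[2]
  W <- spec$width; t <- spec$wall_thickness; r <- t / 2
  lay <- microtrap_layout(spec)
  cy <- y0 + W / 2

  solid_sealed <- rasterize_rect(xs, ys, x0, x0 + spec$length, y0, y0 + t) |
    rasterize_rect(xs, ys, x0, x0 + spec$length, y0 + W - t, y0 + W)
  corners <- list()
  for (k in seq_along(lay$apex_x)) {
    ax <- x0 + lay$apex_x[k]
    jx <- ax - lay$direction[k] * lay$dx_arm
    lower <- c(jx, y0 + t); upper <- c(jx, y0 + W - t); apex <- c(ax, cy)
    solid_sealed <- solid_sealed |
      rasterize_capsule(xs, ys, lower, apex, r) |
      rasterize_capsule(xs, ys, upper, apex, r)
    corners[[k]] <- tibble::tibble(
      funnel = k,
      type = c("junction_lower", "junction_upper", "apex"),
      x = c(lower[1], upper[1], apex[1]),
      y = c(lower[2], upper[2], apex[2])
    )
  }
  # apex gaps: open a slit of funnel_gap_width through each apex
  gap_band <- abs(ys - cy) < spec$funnel_gap_width / 2
  solid <- solid_sealed
  solid[gap_band, ] <- FALSE & solid[gap_band, ]

  h <- matrix(channel$height, nrow = ny, ncol = nx)
  h[solid] <- channel$height - spec$feature_height

  bbox <- c(xmin = x0, xmax = x0 + spec$length, ymin = y0, ymax = y0 + W)
  cav <- label_cavities(solid_sealed, xs, ys, bbox)
  cav$centers$x <- cav$centers$x + origin[1]
  cav$centers$y <- cav$centers$y + origin[2]
  corners <- dplyr::bind_rows(corners)
  corners$x <- corners$x + origin[1]
  corners$y <- corners$y + origin[2]
  bbox <- bbox + c(origin[1], origin[1], origin[2], origin[2])

  new_depth_map(h, ds, origin, solid, channel$height, feature = list(
    type = "microtrap", spec = spec, bbox = bbox,
    solid_sealed = solid_sealed,
    cavities = cav$labels, cavity_centers = cav$centers,
    corners = corners
  ))
}

# label topologically enclosed cavities: connected open regions (with funnel
# gaps sealed) inside the footprint that do not reach the footprint's
# upstream/downstream edges; relabelled 1..n in downstream order
label_cavities <- function(solid_sealed, xs, ys, bbox) {
  inside <- outer(ys >= bbox["ymin"] & ys <= bbox["ymax"],
                  xs >= bbox["xmin"] & xs <= bbox["xmax"], `&`)
  open <- (!solid_sealed) & inside
  lab <- EBImage::bwlabel(t(open) * 1) # EBImage uses (x, y) index order
  lab <- t(EBImage::imageData(lab))
  cols_in <- which(xs >= bbox["xmin"] & xs <= bbox["xmax"])
  edge_cols <- c(min(cols_in), max(cols_in))
  edge_labels <- setdiff(unique(as.vector(lab[, edge_cols])), 0)
  keep <- setdiff(setdiff(unique(as.vector(lab)), 0), edge_labels)
  out <- matrix(0L, nrow = nrow(lab), ncol = ncol(lab))
  centers <- tibble::tibble(cavity = integer(), x = double(), y = double(),
                            area = double())
  if (length(keep)) {
    cx <- vapply(keep, function(l) mean(xs[col(lab)[lab == l]]), 0)
    ord <- order(cx)
    for (i in seq_along(ord)) {
      l <- keep[ord[i]]
      cells <- lab == l
      out[cells] <- i
      centers <- dplyr::bind_rows(centers, tibble::tibble(
        cavity = i,
        x = mean(xs[col(lab)[cells]]),
        y = mean(ys[row(lab)[cells]]),
        area = sum(cells) * (xs[2] - xs[1])^2
      ))
    }
  }
  list(labels = out, centers = centers)
}

#' Count enclosed cavities of a feature depth map
#'
#' @param dm A `depth_map` built by [build_microtrap()].
#' @return Integer number of enclosed cavity regions.
#' @export
count_cavities <- function(dm) {
  if (is.null(dm$feature$cavities)) return(0L)
  max(dm$feature$cavities)
}

#' Build the arrow-array depth map
#'
#' Rasterizes a row of chevron arrows pointing against the flow (apex
#' upstream), each formed by two 45-degree strokes, so that a sheltered
#' cavity opens downstream of every arrow. Arrows are placed along the
#' channel axis with pitch `length + spacing`.
#'
#' @param spec An [arrow_spec()].
#' @param channel A [channel_spec()].
#' @param margin Length-2 numeric margins in um (x, y) around the array.
#' @param origin Physical coordinates of the lower-left domain corner.
#' @return A [new_depth_map()]; `feature$arrows` holds apex coordinates.
#' @export
build_arrow_array <- function(spec = arrow_spec(), channel = channel_spec(),
                              margin = c(120, 120), origin = c(0, 0)) {
  if (spec$feature_height >= channel$height) {
    stop("feature height must be below the channel height", call. = FALSE)
  }
  ds <- channel$grid_spacing
  if (spec$count == 0) {
    return(build_channel(channel, area = 2 * margin, origin = origin))
  }
  half_span <- (spec$length - spec$width) / 2 # wing tip center offset
  r <- spec$width / 2
  dx_arm <- half_span # 45-degree strokes
  pitch <- spec$length + spec$spacing
  body_x <- (spec$count - 1) * pitch + dx_arm + spec$width
  Lx <- body_x + 2 * margin[1]
  Ly <- spec$length + 2 * margin[2]
  nx <- round(Lx / ds); ny <- round(Ly / ds)
  xs <- (seq_len(nx) - 0.5) * ds # local frame (translation-invariant raster)
  ys <- (seq_len(ny) - 0.5) * ds
  cy <- Ly / 2

  solid <- matrix(FALSE, nrow = ny, ncol = nx)
  apexes <- numeric(spec$count)
  for (k in seq_len(spec$count)) {
    ax <- margin[1] + r + (k - 1) * pitch
    apex <- c(ax, cy)
    solid <- solid |
      rasterize_capsule(xs, ys, apex, c(ax + dx_arm, cy - half_span), r) |
      rasterize_capsule(xs, ys, apex, c(ax + dx_arm, cy + half_span), r)
    apexes[k] <- ax
  }
  h <- matrix(channel$height, nrow = ny, ncol = nx)
  h[solid] <- channel$height - spec$feature_height
  new_depth_map(h, ds, origin, solid, channel$height, feature = list(
    type = "arrow", spec = spec,
    bbox = c(xmin = origin[1] + margin[1],
             xmax = origin[1] + margin[1] + body_x,
             ymin = origin[2] + cy - spec$length / 2,
             ymax = origin[2] + cy + spec$length / 2),
    arrows = tibble::tibble(arrow = seq_len(spec$count),
                            x = apexes + origin[1], y = cy + origin[2])
  ))
}

#' Count disjoint solid components of a depth map
#'
#' @param dm A `depth_map`.
#' @return Integer count of 4-connected solid components.
#' @export
count_solid_components <- function(dm) {
  lab <- EBImage::bwlabel(t(dm$solid) * 1)
  max(EBImage::imageData(lab))
}

#' Export a depth map as TIFF plus JSON sidecar
#'
#' Writes the clearance raster as a single-channel 32-bit float TIFF (values
#' in um) and a JSON sidecar recording origin, spacing and channel height.
#'
#' @param dm A `depth_map`.
#' @param prefix Output path prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_depth_map <- function(dm, prefix) {
  tif <- paste0(prefix, ".tif"); js <- paste0(prefix, ".json")
  tiff::writeTIFF(dm$h / dm$channel_height, tif, bits.per.sample = 32L)
  jsonlite::write_json(
    list(origin = dm$origin, spacing = dm$spacing,
         channel_height = dm$channel_height,
         h_scale = dm$channel_height,
         feature = dm$feature$type %||% "none"),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tif, js))
}

#' Read a depth map written by [write_depth_map()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `depth_map` (feature metadata reduced to its type).
#' @export
read_depth_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  h <- tiff::readTIFF(paste0(prefix, ".tif")) * meta$h_scale
  solid <- (meta$channel_height - h) > 1e-3 # float32 storage tolerance
  new_depth_map(h, meta$spacing, meta$origin, solid, meta$channel_height,
                feature = list(type = meta$feature))
}
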