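#' Channel specification
#'
#' Geometry of the straight analysis channel: a 5 mm wide, 15 um high slot
#' with a central analysis area of about 1.5 x 1 mm where the flow is
#' homogeneous. All lengths are in um.
#'
#' @param width Channel width (cross-flow, y) in um.
#' @param height Channel height (z) in um.
#' @param analysis_area Length-2 numeric, `c(x, y)` extent of the central
#'   analysis area in um.
#' @param grid_spacing Raster cell size in um for depth maps built from this
#'   spec.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(width = 5000, height = 15,
                         analysis_area = c(1500, 1000), grid_spacing = 2) {
  stopifnot(length(analysis_area) == 2)
  if (any(c(width, height, analysis_area, grid_spacing) <= 0)) {
    stop("all channel dimensions must be positive", call. = FALSE)
  }
  if (analysis_area[2] > width) {
    stop("analysis area must fit within the channel width", call. = FALSE)
  }
  structure(
    list(width = width, height = height, analysis_area = analysis_area,
         grid_spacing = grid_spacing),
    class = "channel_spec"
  )
}

#' Microtrap specification
#'
#' The nested-funnel microtrap: three V-shaped funnels opening into the flow
#' followed by three opening against it, enclosing five inner cavities. The
#' footprint is 410 x 150 um, walls 20 um thick, feature height 10 um in a
#' 15 um channel (walls reach 2/3 of the channel height, so flow also passes
#' over them with 5 um clearance). Each funnel apex carries a small gap on the
#' channel centerline through which particles can be funneled into the next
#' cavity; its width is a design parameter at cell scale.
#'
#' @param length,width Footprint extent in um (x = downstream, y = cross-flow).
#' @param feature_height Wall height in um (must be below the channel height).
#' @param wall_thickness Wall/ridge thickness in um.
#' @param funnels_with_flow,funnels_against_flow Number of funnels opening
#'   with / against the flow direction.
#' @param funnel_gap_width Width of the apex opening in um.
#' @param funnel_half_angle Funnel arm half-angle in degrees (45 = arms at 45
#'   degrees to the flow axis).
#' @param traps_per_channel Number of trap replicates along one channel.
#' @return An object of class `microtrap_spec`.
#' @export
microtrap_spec <- function(length = 410, width = 150, feature_height = 10,
                           wall_thickness = 20,
                           funnels_with_flow = 3, funnels_against_flow = 3,
                           funnel_gap_width = 5, funnel_half_angle = 60,
                           traps_per_channel = 7) {
  if (any(c(length, width, feature_height, wall_thickness,
            funnel_gap_width, funnel_half_angle) <= 0)) {
    stop("all microtrap dimensions must be positive", call. = FALSE)
  }
  if (funnels_with_flow < 1 || funnels_against_flow < 1) {
    stop("need at least one funnel in each direction", call. = FALSE)
  }
  spec <- structure(
    list(length = length, width = width, feature_height = feature_height,
         wall_thickness = wall_thickness,
         funnels_with_flow = funnels_with_flow,
         funnels_against_flow = funnels_against_flow,
         cavities = funnels_with_flow + funnels_against_flow - 1,
         funnel_gap_width = funnel_gap_width,
         funnel_half_angle = funnel_half_angle,
         traps_per_channel = traps_per_channel),
    class = "microtrap_spec"
  )
  spec
}

#' Arrow-array specification
#'
#' The simpler vortex-generating feature: chevron "arrows" of 20 um stroke
#' width spanning 140 um across the flow, pointing against the flow so that a
#' sheltered cavity forms downstream of each. Seven arrows separated by one
#' arrow length.
#'
#' @param width Stroke (wall) thickness in um.
#' @param length Arrow span in um (tip-to-wing extent across the flow).
#' @param count Number of arrows in the array.
#' @param spacing Gap between consecutive arrows in um (pitch = length +
#'   spacing).
#' @param feature_height Arrow height in um.
#' @return An object of class `arrow_spec`.
#' @export
arrow_spec <- function(width = 20, length = 140, count = 7, spacing = 140,
                       feature_height = 10) {
  if (count < 0) stop("`count` must be >= 0", call. = FALSE)
  if (any(c(width, length, spacing, feature_height) <= 0)) {
    stop("arrow dimensions must be positive", call. = FALSE)
  }
  structure(
    list(width = width, length = length, count = count, spacing = spacing,
         feature_height = feature_height),
    class = "arrow_spec"
  )
}

#' Tracer particle specification
#'
#' Fluorescent polymer microspheres (1-5 um diameter, 1.3 g mL^-1) used as
#' passive tracers of the flow; similar in size to E. coli but slightly
#' denser.
#'
#' @param diameter Particle diameter in um, within 0.5-10.
#' @param density Particle density in g mL^-1.
#' @param diffusivity_override Optional diffusion coefficient in um^2 s^-1;
#'   when `NULL` the Stokes-Einstein value is used.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(diameter = 2, density = 1.3,
                          diffusivity_override = NULL) {
  if (diameter < 0.5 || diameter > 10) {
    stop("`diameter` must lie in [0.5, 10] um", call. = FALSE)
  }
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  structure(
    list(diameter = diameter, density = density,
         diffusivity_override = diffusivity_override),
    class = "particle_spec"
  )
}

#' Imaging optics specification
#'
#' Camera/optics model for synthetic fluorescence microscopy: pixel size,
#' Gaussian PSF width, frame rate and count (500 frames over ~20 s -> 25 Hz),
#' background level and noise, and output bit depth.
#'
#' @param pixel_size um per pixel.
#' @param psf_sigma PSF standard deviation in pixels.
#' @param frame_rate Frames per second.
#' @param frame_count Number of frames in a recording.
#' @param background Background intensity level (counts).
#' @param noise_sigma Gaussian read-noise standard deviation (counts).
#' @param bit_depth Output bit depth (8 or 16).
#' @return An object of class `optics_spec`.
#' @export
optics_spec <- function(pixel_size = 0.65, psf_sigma = 1.2, frame_rate = 25,
                        frame_count = 500, background = 10, noise_sigma = 2,
                        bit_depth = 8) {
  if (pixel_size <= 0 || frame_rate <= 0) {
    stop("`pixel_size` and `frame_rate` must be positive", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(
    list(pixel_size = pixel_size, psf_sigma = psf_sigma,
         frame_rate = frame_rate, frame_count = frame_count,
         background = background, noise_sigma = noise_sigma,
         bit_depth = bit_depth),
    class = "optics_spec"
  )
}

#' Biofilm regime specification
#'
#' The three localization regimes observed for biofilms in the microtrap:
#' high inoculum + low flow -> growth on the walls; low inoculum + low flow ->
#' growth in the walls' corners; low inoculum + high flow -> growth at the
#' cavity centers (especially the first three cavities in flow direction),
#' where single microvortices reside.
#'
#' @param pattern One of `"walls"`, `"corners"`, `"cavity_centers"`.
#' @param concentration_class `"low"` or `"high"` inoculum density. Defaults
#'   to the class consistent with `pattern`.
#' @param flow_class `"low"` or `"high"` flow rate. Defaults likewise.
#' @param rng_seed Integer seed controlling the stochastic colony layout.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(pattern = c("walls", "corners", "cavity_centers"),
                        concentration_class = NULL, flow_class = NULL,
                        rng_seed = 1) {
  pattern <- match.arg(pattern)
  default <- switch(pattern,
    walls = c("high", "low"),
    corners = c("low", "low"),
    cavity_centers = c("low", "high")
  )
  concentration_class <- concentration_class %||% default[1]
  flow_class <- flow_class %||% default[2]
  if (!identical(c(concentration_class, flow_class), default)) {
    stop(sprintf(
      "pattern '%s' requires concentration_class '%s' and flow_class '%s'",
      pattern, default[1], default[2]), call. = FALSE)
  }
  structure(
    list(pattern = pattern, concentration_class = concentration_class,
         flow_class = flow_class, rng_seed = as.integer(rng_seed)),
    class = "regime_spec"
  )
}

#' Read a geometry configuration file
#'
#' Reads channel/microtrap/arrow specification fields from a YAML or JSON
#' file with top-level keys `channel`, `microtrap` and/or `arrow`, each
#' holding the arguments of the corresponding `*_spec()` constructor.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with elements among `channel`, `microtrap`, `arrow`.
#' @export
read_geometry_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON", call. = FALSE)
  )
  out <- list()
  if (!is.null(cfg$channel)) out$channel <- do.call(channel_spec, cfg$channel)
  if (!is.null(cfg$microtrap)) out$microtrap <- do.call(microtrap_spec, cfg$microtrap)
  if (!is.null(cfg$arrow)) out$arrow <- do.call(arrow_spec, cfg$arrow)
  out
}
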