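#' Fluid properties
#'
#' Bundle of the physical properties of the carrier fluid used throughout the
#' flow solvers and dimensionless numbers. Defaults are round-number water
#' properties (rho = 1000 kg m^-3, mu = 1.0 mPa s); the chips are operated
#' close to ambient temperature, where these round values are accurate to a
#' few percent.
#'
#' @param density Fluid density in kg m^-3.
#' @param dynamic_viscosity Dynamic viscosity in Pa s.
#' @param temperature Temperature in degrees Celsius (used by
#'   [stokes_einstein_diffusivity()]).
#' @return An object of class `fluid_properties`.
#' @examples
#' water()
#' @export
fluid_properties <- function(density = 1000, dynamic_viscosity = 1e-3,
                             temperature = 25) {
  if (!is.numeric(density) || density <= 0) {
    stop("`density` must be a positive number (kg m^-3)", call. = FALSE)
  }
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0) {
    stop("`dynamic_viscosity` must be a positive number (Pa s)", call. = FALSE)
  }
  structure(
    list(density = density, dynamic_viscosity = dynamic_viscosity,
         temperature = temperature),
    class = "fluid_properties"
  )
}

#' @rdname fluid_properties
#' @export
water <- function(temperature = 25) {
  fluid_properties(1000, 1e-3, temperature)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> rho = %g kg m^-3, mu = %g Pa s, T = %g degC\n",
              x$density, x$dynamic_viscosity, x$temperature))
  invisible(x)
}

# micro-litre per minute -> cubic micrometre per second
ul_min_to_um3_s <- function(flow_rate) flow_rate * 1e9 / 60

#' Mean (superficial) velocity in a rectangular channel
#'
#' Converts a volumetric flow rate into the cross-section-averaged velocity
#' `U = Q / (width * height)`.
#'
#' @param flow_rate Volumetric flow rate in uL min^-1 (non-negative).
#' @param channel A [channel_spec()].
#' @return Mean velocity in um s^-1.
#' @examples
#' mean_velocity(0.5, channel_spec()) # ~111 um/s in the 5 mm x 15 um channel
#' @export
mean_velocity <- function(flow_rate, channel = channel_spec()) {
  if (!is.numeric(flow_rate) || any(flow_rate < 0)) {
    stop("`flow_rate` must be non-negative (uL min^-1)", call. = FALSE)
  }
  area <- channel$width * channel$height # um^2
  if (area <= 0) stop("channel cross-section is degenerate", call. = FALSE)
  ul_min_to_um3_s(flow_rate) / area
}

#' Reynolds number of the channel flow
#'
#' `Re = rho * U * L / mu` with `U = Q/(width*height)`. Because shallow-channel
#' work mixes conventions, the characteristic length is an explicit choice:
#' the hydraulic diameter `2wh/(w+h)`, the channel height, or the feature
#' height of an embedded microstructure.
#'
#' @inheritParams mean_velocity
#' @param fluid A [fluid_properties()].
#' @param length_scale One of `"hydraulic_diameter"`, `"channel_height"`,
#'   `"feature_height"`.
#' @param feature_height Feature height in um, used when
#'   `length_scale = "feature_height"`.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(0.5)                                  # ~0.003
#' reynolds_number(0.5, length_scale = "feature_height") # ~0.001
#' @export
reynolds_number <- function(flow_rate, channel = channel_spec(),
                            fluid = water(),
                            length_scale = c("hydraulic_diameter",
                                             "channel_height",
                                             "feature_height"),
                            feature_height = 10) {
  length_scale <- match.arg(length_scale)
  U <- mean_velocity(flow_rate, channel) # um/s
  L <- switch(length_scale,
    hydraulic_diameter = 2 * channel$width * channel$height /
      (channel$width + channel$height),
    channel_height = channel$height,
    feature_height = feature_height
  )
  fluid$density * (U * 1e-6) * (L * 1e-6) / fluid$dynamic_viscosity
}

#' Peclet number
#'
#' `Pe = v * L / D`: ratio of advective to diffusive transport for a particle,
#' bacterium or solute.
#'
#' @param velocity Advection velocity in um s^-1 (non-negative).
#' @param length Characteristic length in um (non-negative).
#' @param diffusivity Diffusion coefficient in um^2 s^-1 (positive).
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(velocity, length, diffusivity) {
  if (any(velocity < 0) || any(length < 0)) {
    stop("`velocity` and `length` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(diffusivity) || any(diffusivity <= 0)) {
    stop("`diffusivity` must be positive (um^2 s^-1)", call. = FALSE)
  }
  velocity * length / diffusivity
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T / (6 pi mu r)` for a sphere of the given diameter in the given
#' fluid, returned in um^2 s^-1.
#'
#' @param diameter Particle diameter in um.
#' @param fluid A [fluid_properties()]; its `temperature` (degC) sets T.
#' @export
stokes_einstein_diffusivity <- function(diameter, fluid = water()) {
  if (any(diameter <= 0)) stop("`diameter` must be positive", call. = FALSE)
  kB <- 1.380649e-23 # J/K
  TK <- fluid$temperature + 273.15
  r <- diameter / 2 * 1e-6 # m
  D_m2s <- kB * TK / (6 * pi * fluid$dynamic_viscosity * r)
  D_m2s * 1e12
}

#' Stokes settling velocity
#'
#' Terminal sinking speed of a small sphere, `v = delta_rho * g * d^2 /
#' (18 mu)`. Positive values mean the particle sinks (its density exceeds the
#' fluid's); the tracer microspheres used for velocimetry (1.3 g mL^-1) sink
#' slowly, slightly faster than live E. coli (1.1 g mL^-1).
#'
#' @param diameter Particle diameter in um (positive).
#' @param particle_density Particle density in g mL^-1.
#' @param fluid A [fluid_properties()].
#' @return Settling velocity in um s^-1 (signed; positive = sinking).
#' @examples
#' settling_velocity(2, 1.3) # ~0.65 um/s
#' @export
settling_velocity <- function(diameter, particle_density, fluid = water()) {
  if (any(diameter <= 0)) stop("`diameter` must be positive", call. = FALSE)
  delta_rho <- particle_density * 1000 - fluid$density # kg/m^3
  g <- 9.80665
  v_ms <- delta_rho * g * (diameter * 1e-6)^2 / (18 * fluid$dynamic_viscosity)
  v_ms * 1e6
}
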