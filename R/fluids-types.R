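#' Microchannel cross-section and flow-rate parameters
#'
#' Describes the perfusion channel in which the nodules grow: a wide, flat
#' rectangular duct (width \eqn{w} across the flow, height \eqn{h}) perfused
#' at volumetric rate \eqn{Q}. Because \eqn{w \gg h} the flow away from the
#' side walls is plane Poiseuille flow, which is the closed-form reference
#' used throughout. Defaults are the chip used in the experiments:
#' 4 mm x 254 um at 2 uL/min.
#'
#' @param width Channel width \eqn{w} in metres (default 4 mm).
#' @param height Channel height \eqn{h} in metres (default 254 um, the
#'   adhesive-film thickness of the chip; the simulated domain in the
#'   figures uses 250 um -- pass `height = 250e-6` to reproduce it).
#' @param length Streamwise length of the simulated central section in
#'   metres. Must be at least 10x the nodule semi-major axis so that
#'   entrance effects cannot reach the nodule.
#' @param flow_rate Volumetric flow rate \eqn{Q} in m^3/s (default
#'   2 uL/min; see [ul_per_min()]).
#' @return An object of class `"channel_geometry"`.
#' @seealso [wall_shear_stress()], [mean_inlet_velocity()],
#'   [solve_channel_flow()]
#' @export
channel_geometry <- function(width = 4e-3, height = 254e-6,
                             length = 2.2e-3, flow_rate = ul_per_min(2)) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(length),
            is.numeric(flow_rate))
  if (width <= 0 || height <= 0 || length <= 0)
    stop("channel dimensions must be positive", call. = FALSE)
  if (flow_rate < 0)
    stop("flow_rate must be non-negative", call. = FALSE)
  structure(list(width = width, height = height, length = length,
                 flow_rate = flow_rate),
            class = "channel_geometry")
}

#' Fluid properties and inlet condition
#'
#' Water-like defaults reproduce the printed wall shear stress of the
#' culture-medium perfusion (0.008 dyn/cm^2 at 2 uL/min). The mean inlet
#' velocity is derived as \eqn{U = Q/(wh)} unless overridden.
#'
#' @param viscosity Dynamic viscosity \eqn{\mu} in Pa s.
#' @param density Density \eqn{\rho} in kg/m^3 (unused by the Stokes
#'   solver, kept for completeness).
#' @param mean_velocity Optional override of the cross-section mean inlet
#'   velocity in m/s; `NULL` derives it from the channel geometry.
#' @param outlet_pressure Gauge outlet pressure in Pa (0 = atmospheric).
#' @return An object of class `"fluid_properties"`.
#' @export
fluid_properties <- function(viscosity = 1.0e-3, density = 1000,
                             mean_velocity = NULL, outlet_pressure = 0) {
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  if (!is.null(mean_velocity) && mean_velocity < 0)
    stop("mean_velocity must be non-negative", call. = FALSE)
  structure(list(viscosity = viscosity, density = density,
                 mean_velocity = mean_velocity,
                 outlet_pressure = outlet_pressure),
            class = "fluid_properties")
}

#' Elliptical micronodule geometry
#'
#' The tumor surrogate is an ellipse in the streamwise XZ plane with
#' semi-major axis \eqn{a} along the flow (X) and semi-minor axis \eqn{b}
#' vertically (Z). The nodule sits partly embedded in the gel bed on the
#' channel floor: its centre is at height \eqn{z_0 = p - b} so that it
#' protrudes a distance \eqn{p} into the channel. Defaults follow the
#' simulated geometry: b = 40 um, protrusion 60 um (centre at z0 = 20 um),
#' a varied over 40--100 um.
#'
#' @param a Semi-major axis (X direction) in metres, 40--100 um in the
#'   reference sweeps.
#' @param b Semi-minor axis (Z direction) in metres (default 40 um).
#' @param protrusion Height of the apex above the channel floor in metres
#'   (default 60 um).
#' @param x_center Streamwise position of the nodule centre in metres,
#'   relative to the centre of the simulated section (default 0).
#' @return An object of class `"nodule_geometry"` with the derived centre
#'   height `z_center = protrusion - b`.
#' @export
nodule_geometry <- function(a = 40e-6, b = 40e-6, protrusion = 60e-6,
                            x_center = 0) {
  if (b <= 0 || a < b * (1 - 1e-9))
    stop("nodule semi-axes must satisfy a >= b > 0", call. = FALSE)
  z0 <- protrusion - b
  if (protrusion <= 0 || protrusion > b + z0 + 1e-12)
    stop("protrusion must be positive and equal z_center + b", call. = FALSE)
  if (z0 + b <= 0)
    stop("nodule must protrude above the channel floor", call. = FALSE)
  structure(list(a = a, b = b, protrusion = protrusion,
                 x_center = x_center, z_center = z0),
            class = "nodule_geometry")
}

#' Porous (Brinkman) properties of the nodule
#'
#' When `porous = TRUE` the flow inside the nodule obeys the Brinkman
#' equations with Darcy drag \eqn{(\mu/\kappa) u}. A solid nodule is the
#' \eqn{\kappa \to 0} limit and is realized by penalization with
#' `solid_permeability`.
#'
#' The default permeability of 1e-10 m^2 gives a Brinkman screening length
#' \eqn{\sqrt{\kappa} = 10} um, a quarter of the reference semi-minor axis,
#' so the flow visibly permeates the nodule and the porous shear profile is
#' markedly lower than the solid one, as in the reference simulations.
#' (Much smaller published values, e.g. 1e-13 m^2, yield screening lengths
#' far below any affordable grid and make the porous nodule numerically
#' indistinguishable from solid; see the methods vignette.)
#'
#' @param permeability Darcy permeability \eqn{\kappa} in m^2.
#' @param porosity Volume fraction \eqn{\epsilon} of fluid in the nodule,
#'   in (0, 1). Recorded in outputs; the steady Brinkman momentum balance
#'   used here does not otherwise depend on it.
#' @param porous Logical; `FALSE` models an impermeable solid nodule.
#' @param solid_permeability Penalization permeability used for solid
#'   nodules (default 1e-18 m^2).
#' @return An object of class `"porous_properties"`.
#' @export
porous_properties <- function(permeability = 1e-10, porosity = 0.3,
                              porous = TRUE, solid_permeability = 1e-18) {
  if (porous) {
    if (permeability <= 0) stop("permeability must be positive", call. = FALSE)
    if (porosity <= 0 || porosity >= 1)
      stop("porosity must be in (0, 1)", call. = FALSE)
  }
  if (solid_permeability <= 0 || solid_permeability > 1e-16)
    stop("solid_permeability must be positive and <= 1e-16 m^2", call. = FALSE)
  structure(list(permeability = permeability, porosity = porosity,
                 porous = porous, solid_permeability = solid_permeability),
            class = "porous_properties")
}

#' Solid-nodule shorthand
#' @return A `"porous_properties"` object with `porous = FALSE`.
#' @export
solid_nodule <- function() porous_properties(porous = FALSE)

#' Discretization parameters for the channel-flow solver
#'
#' @param cell_size Target grid spacing in metres. The solver requires the
#'   spacing to resolve the nodule surface: `cell_size <= b / 10`.
#' @param refinement_levels Integer >= 1; each level halves the cell size.
#' @param tolerance Relative residual threshold below which the (direct)
#'   solve is declared converged.
#' @return An object of class `"mesh_spec"`.
#' @export
mesh_spec <- function(cell_size = 4e-6, refinement_levels = 1L,
                      tolerance = 1e-8) {
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  refinement_levels <- as.integer(refinement_levels)
  if (refinement_levels < 1L) stop("refinement_levels must be >= 1", call. = FALSE)
  structure(list(cell_size = cell_size / 2^(refinement_levels - 1L),
                 refinement_levels = refinement_levels,
                 tolerance = tolerance),
            class = "mesh_spec")
}

#' Convert a flow rate in uL/min to m^3/s
#' @param x Flow rate in microlitres per minute.
#' @return Flow rate in m^3/s.
#' @export
ul_per_min <- function(x) x * 1e-9 / 60

#' Convert a stress in Pa to dyn/cm^2
#' @param pa Stress in pascals.
#' @return The same stress in dyn/cm^2 (1 Pa = 10 dyn/cm^2).
#' @export
pa_to_dyn_cm2 <- function(pa) pa * 10

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "Channel: %.3g mm (w) x %.3g um (h), section length %.3g mm, Q = %.3g uL/min\n",
    x$width * 1e3, x$height * 1e6, x$length * 1e3, x$flow_rate * 60e9))
  invisible(x)
}

#' @export
print.nodule_geometry <- function(x, ...) {
  cat(sprintf(
    "Nodule: a = %.3g um, b = %.3g um, protrusion %.3g um, centre (%g, %g) um\n",
    x$a * 1e6, x$b * 1e6, x$protrusion * 1e6,
    x$x_center * 1e6, x$z_center * 1e6))
  invisible(x)
}

#' @export
print.porous_properties <- function(x, ...) {
  if (x$porous)
    cat(sprintf("Porous nodule: kappa = %.3g m^2, porosity = %.2f\n",
                x$permeability, x$porosity))
  else
    cat(sprintf("Solid nodule (penalized, kappa = %.3g m^2)\n",
                x$solid_permeability))
  invisible(x)
}
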