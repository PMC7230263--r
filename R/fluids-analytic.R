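#' Closed-form wall shear stress of the empty channel
#'
#' For fully developed plane Poiseuille flow between parallel plates the
#' shear stress on either wall is
#' \deqn{\tau_w = \frac{6 \mu Q}{w h^2},}
#' the analytic solution of the velocity field in the empty channel. With
#' the default chip geometry (Q = 2 uL/min, w = 4 mm, h = 254 um) and
#' water-like viscosity this is about 7.7e-4 Pa = 0.008 dyn/cm^2, the value
#' used to normalize all nodule-surface shear profiles.
#'
#' @param fluid A [fluid_properties()] object.
#' @param geom A [channel_geometry()] object.
#' @return Wall shear stress in Pa. Multiply by 10 (or use
#'   [pa_to_dyn_cm2()]) for dyn/cm^2.
#' @examples
#' tau <- wall_shear_stress(fluid_properties(), channel_geometry())
#' pa_to_dyn_cm2(tau)  # ~0.008 dyn/cm^2
#' @export
wall_shear_stress <- function(fluid = fluid_properties(),
                              geom = channel_geometry()) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "channel_geometry"))
  6 * fluid$viscosity * geom$flow_rate / (geom$width * geom$height^2)
}

#' Cross-section mean inlet velocity
#'
#' \eqn{U = Q / (w h)}; about 0.033 mm/s for the default chip at 2 uL/min.
#' Used as the mean of the parabolic inlet profile in the solver.
#'
#' @inheritParams wall_shear_stress
#' @return Mean velocity in m/s.
#' @export
mean_inlet_velocity <- function(fluid = fluid_properties(),
                                geom = channel_geometry()) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "channel_geometry"))
  if (!is.null(fluid$mean_velocity)) return(fluid$mean_velocity)
  geom$flow_rate / (geom$width * geom$height)
}
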