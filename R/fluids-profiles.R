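#' Shear-stress profile on the exposed nodule surface
#'
#' Samples the tangential viscous stress \eqn{\sigma(s) = \mu \,
#' \partial u_t / \partial n} along the part of the elliptical surface that
#' protrudes above the channel floor, and normalizes it by the analytic
#' empty-channel wall shear \eqn{\tau_w = 6\mu U / h}. The normal
#' derivative is estimated by a quadratic fit through the interpolated
#' tangential velocity at one, two and three cell sizes outward along the
#' surface normal, extrapolated to the surface.
#'
#' The surface is parameterized by the ellipse angle \eqn{t} (so that the
#' point is \eqn{(x_0 + a\cos t,\; z_0 + b\sin t)}); `n_points` evenly
#' spaced angles cover the exposed arc symmetrically about the apex.
#'
#' @param field A `"flow_field"` from [solve_channel_flow()] with a nodule.
#' @param n_points Number of surface sample points (odd keeps a sample
#'   exactly at the apex; default 181).
#' @return A `"shear_profile"` data frame with columns `angle` (ellipse
#'   angle, radians), `arc_position` (signed arc length from the apex,
#'   normalized to \[-1, 1\]; negative = upstream), `shear_raw` (Pa),
#'   `shear_normalized`, plus attributes `wall_shear` (Pa) and `peak`
#'   (max normalized shear).
#' @export
shear_profile <- function(field, n_points = 181L) {
  stopifnot(inherits(field, "flow_field"))
  nod <- field$nodule
  if (is.null(nod))
    stop("shear_profile requires a field solved with a nodule", call. = FALSE)
  geo <- .exposed_arc(nod, n_points)
  d0 <- max(field$dx, field$dz)
  dists <- d0 * c(1, 2, 3)
  ut <- sapply(dists, function(d) {
    px <- geo$x + d * geo$nx_
    pz <- geo$z + d * geo$nz_
    v <- velocity_at(field, field$nodule_x + px, pz)
    v[, "u"] * geo$tx + v[, "w"] * geo$tz
  })
  ## quadratic extrapolation of d(u_t)/dn to the surface
  V <- cbind(1, dists, dists^2)
  co <- t(solve(V, t(ut)))          # rows: c0, c1, c2 per point
  sigma <- abs(field$fluid$viscosity * co[, 2])
  tau_w <- 6 * field$fluid$viscosity * field$U / field$height
  out <- data.frame(angle = geo$t,
                    arc_position = geo$s_norm,
                    shear_raw = sigma,
                    shear_normalized = sigma / tau_w)
  class(out) <- c("shear_profile", "data.frame")
  attr(out, "wall_shear") <- tau_w
  attr(out, "peak") <- max(out$shear_normalized)
  out
}

## geometry of the exposed arc: sample points, tangents, outward normals,
## signed normalized arc position (negative upstream of the apex)
.exposed_arc <- function(nod, n_points) {
  a <- nod$a; b <- nod$b; z0 <- nod$z_center
  th <- asin(min(1, max(-1, z0 / b)))   # arc dips below apex to the floor
  t <- seq(-th, pi + th, length.out = n_points)
  x <- a * cos(t)
  z <- z0 + b * sin(t)
  ## outward normal ~ (cos t / a, sin t / b); tangent ~ (-a sin t, b cos t)
  nn <- sqrt((cos(t) / a)^2 + (sin(t) / b)^2)
  nx_ <- (cos(t) / a) / nn
  nz_ <- (sin(t) / b) / nn
  tn <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  tx <- -a * sin(t) / tn
  tz <- b * cos(t) / tn
  ## cumulative arc length; s = 0 at the apex (t = pi/2)
  speed <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  ds <- diff(t) * (speed[-1] + speed[-length(t)]) / 2
  s <- c(0, cumsum(ds))
  s_apex <- stats::approx(t, s, xout = pi / 2)$y
  s_rel <- s - s_apex
  half <- max(abs(range(s_rel)))
  ## downstream (x > x0, t < pi/2) taken as positive arc position
  list(t = t, x = x, z = z, nx_ = nx_, nz_ = nz_, tx = tx, tz = tz,
       s_norm = -s_rel / half, arc = s)
}

#' Penetration-flux profile on a porous nodule surface
#'
#' Computes the signed normal velocity of fluid through the nodule
#' surface, positive where flow enters the nodule. The measurement surface
#' is the ellipse offset slightly inward (two cell sizes along the inward
#' normal), where the Brinkman (Darcy-like) interior flow is smooth and
#' free of the staircase artefacts of the penalized boundary; the
#' interpolated normal component is sampled at `n_points` evenly spaced
#' ellipse angles over the exposed arc. By interior mass conservation the
#' integral of the flux over the closed surface (the exposed arc plus the
#' no-flow base) vanishes to discretization accuracy.
#'
#' @param field A `"flow_field"` solved with a porous nodule.
#' @param n_points Number of surface sample points (default 181).
#' @return A `"flux_profile"` data frame with columns `angle`,
#'   `arc_position` (as in [shear_profile()]), `normal_flux` (m/s,
#'   positive into the nodule), with attributes `scale_velocity`
#'   (max \eqn{|q|}, m/s), `net_flux` (the closed-surface integral,
#'   m^2/s per unit depth) and `abs_flux` (the integral of \eqn{|q|},
#'   m^2/s, a scale for judging how close `net_flux` is to zero).
#' @export
flux_profile <- function(field, n_points = 181L) {
  stopifnot(inherits(field, "flow_field"))
  nod <- field$nodule
  if (is.null(nod))
    stop("flux_profile requires a field solved with a nodule", call. = FALSE)
  if (!isTRUE(field$porous$porous))
    stop("flux_profile is only defined for porous nodules", call. = FALSE)
  geo <- .exposed_arc(nod, n_points)
  dd <- 2 * max(field$dx, field$dz)
  if (dd >= nod$b)
    stop("nodule is not resolved by the grid", call. = FALSE)
  px <- field$nodule_x + geo$x - dd * geo$nx_
  pz <- pmax(geo$z - dd * geo$nz_, 1e-12)
  v <- velocity_at(field, px, pz)
  q <- -(v[, "u"] * geo$nx_ + v[, "w"] * geo$nz_)  # positive into the nodule
  ## trapezoid integrals along the arc
  speed <- sqrt((nod$a * sin(geo$t))^2 + (nod$b * cos(geo$t))^2)
  dsz <- diff(geo$t) * (speed[-1] + speed[-n_points]) / 2
  net <- sum((q[-1] + q[-n_points]) / 2 * dsz)
  abs_tot <- sum(abs(q[-1] + q[-n_points]) / 2 * dsz)
  out <- data.frame(angle = geo$t, arc_position = geo$s_norm,
                    normal_flux = q)
  class(out) <- c("flux_profile", "data.frame")
  attr(out, "scale_velocity") <- max(abs(q))
  attr(out, "net_flux") <- net
  attr(out, "abs_flux") <- abs_tot
  out
}

#' Sweep nodule geometries and porosities
#'
#' Solves the channel flow for each combination of semi-major axis and
#' porous/solid state and tabulates the peak normalized surface shear (and,
#' for porous cases, the penetration-flux velocity scale). Individual
#' solver failures are recorded per row instead of aborting the sweep.
#'
#' @param a_values Semi-major axes in metres (default the reference sweep
#'   40, 60, 80, 100 um).
#' @param porous_states Logical vector of porosity states to cross with
#'   `a_values`.
#' @param geom,fluid,mesh Passed to [solve_channel_flow()]. The default
#'   channel uses the 250 um simulated height.
#' @param b,protrusion Nodule semi-minor axis and protrusion (metres).
#' @param porous [porous_properties()] used for the porous cases.
#' @return A data frame with one row per case: `a_um`, `porous`,
#'   `peak_shear_pa`, `peak_shear_normalized`, `scale_velocity`,
#'   `converged`, `failed`, `message`.
#' @export
sweep_nodule_geometry <- function(a_values = c(40, 60, 80, 100) * 1e-6,
                                  porous_states = c(FALSE, TRUE),
                                  geom = channel_geometry(height = 250e-6),
                                  fluid = fluid_properties(),
                                  mesh = mesh_spec(),
                                  b = 40e-6, protrusion = 60e-6,
                                  porous = porous_properties()) {
  cases <- expand.grid(a = a_values, porous = porous_states)
  rows <- lapply(seq_len(nrow(cases)), function(k) {
    aa <- cases$a[k]; por <- cases$porous[k]
    res <- tryCatch({
      nod <- nodule_geometry(a = aa, b = b, protrusion = protrusion)
      pp <- if (por) porous else solid_nodule()
      ff <- solve_channel_flow(geom, fluid, nod, pp, mesh)
      sp <- shear_profile(ff)
      sv <- if (por) attr(flux_profile(ff), "scale_velocity") else NA_real_
      data.frame(a_um = aa * 1e6, porous = por,
                 peak_shear_pa = max(sp$shear_raw),
                 peak_shear_normalized = attr(sp, "peak"),
                 scale_velocity = sv,
                 converged = ff$converged, failed = FALSE,
                 message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(a_um = aa * 1e6, porous = por,
                 peak_shear_pa = NA_real_, peak_shear_normalized = NA_real_,
                 scale_velocity = NA_real_, converged = FALSE, failed = TRUE,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' @export
plot.shear_profile <- function(x, ...) {
  graphics::plot(x$arc_position, x$shear_normalized, type = "l",
                 xlab = "arc position (apex = 0, downstream > 0)",
                 ylab = expression(sigma / tau[w]), ...)
  invisible(x)
}

#' @export
plot.flux_profile <- function(x, ...) {
  graphics::plot(x$arc_position, x$normal_flux * 1e9, type = "h",
                 xlab = "arc position (apex = 0, downstream > 0)",
                 ylab = "normal flux (nm/s, + into nodule)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
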