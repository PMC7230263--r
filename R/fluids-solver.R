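#' Solve steady channel flow around (and through) a micronodule
#'
#' Discretizes the steady incompressible Stokes equations on a staggered
#' (MAC) finite-difference grid over the XZ cross-section of the channel
#' and solves the resulting saddle-point system with a sparse direct
#' factorization. Inside the nodule the Brinkman drag \eqn{(\mu/\kappa)u}
#' is added to the momentum balance, so a single discretization covers the
#' empty channel, the porous nodule, and (by penalization with a very small
#' permeability) the impermeable solid nodule; velocity is continuous
#' across the nodule surface in the porous case and vanishes on it in the
#' solid limit.
#'
#' Boundary conditions: no slip on floor and ceiling; fully developed
#' parabolic profile with mean \eqn{U} at inlet and outlet (the nodule is
#' kept at least ~1 mm from either end so this is exact to solver
#' accuracy); pressure fixed to the outlet gauge value in one reference
#' cell. The system is nondimensionalized (lengths by the cell size,
#' velocities by \eqn{U}) before assembly so that the strongly penalized
#' solid case stays within the conditioning bounds of the sparse LU.
#'
#' @param geom [channel_geometry()]. `geom$length` is the simulated
#'   streamwise extent; the nodule sits at its centre.
#' @param fluid [fluid_properties()].
#' @param nodule [nodule_geometry()] or `NULL` for an empty channel.
#' @param porous [porous_properties()]; ignored when `nodule` is `NULL`.
#' @param mesh [mesh_spec()].
#' @return An object of class `"flow_field"`: matrices `u` (streamwise
#'   velocity at vertical cell faces, `(nx+1) x nz`), `w` (vertical
#'   velocity at horizontal faces, `nx x (nz+1)`), `p` (pressure at cell
#'   centres, `nx x nz`), the grid spacings, a `converged` flag with the
#'   relative residual, and the input objects.
#' @examples
#' \donttest{
#' geom <- channel_geometry(length = 1e-3)
#' ff <- solve_channel_flow(geom, fluid_properties(), mesh = mesh_spec(10e-6))
#' ff$converged
#' }
#' @export
solve_channel_flow <- function(geom = channel_geometry(),
                               fluid = fluid_properties(),
                               nodule = NULL,
                               porous = porous_properties(),
                               mesh = mesh_spec()) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(mesh, "mesh_spec"))
  if (!is.null(nodule)) {
    stopifnot(inherits(nodule, "nodule_geometry"))
    if (nodule$protrusion >= geom$height)
      stop("nodule is taller than the channel", call. = FALSE)
    if (2 * nodule$a >= geom$length)
      stop("nodule does not fit in the simulated section", call. = FALSE)
    if (mesh$cell_size > nodule$b / 10 * (1 + 1e-9))
      stop(sprintf(
        "mesh does not resolve the nodule surface: cell_size %.3g > b/10 = %.3g",
        mesh$cell_size, nodule$b / 10), call. = FALSE)
    if (geom$length < 10 * nodule$a)
      stop("section length must be >= 10 x nodule semi-major axis", call. = FALSE)
  }

  mu <- fluid$viscosity
  U <- mean_inlet_velocity(fluid, geom)
  h <- geom$height
  Lx <- geom$length
  nz <- max(8L, as.integer(round(h / mesh$cell_size)))
  nx <- max(8L, as.integer(round(Lx / mesh$cell_size)))
  if (nx %% 2L == 1L) nx <- nx + 1L  # keep the grid symmetric about mid-length
  dx <- Lx / nx
  dz <- h / nz

  ## Brinkman drag coefficient alpha = mu/kappa at a set of points
  xc <- Lx / 2 + if (is.null(nodule)) 0 else nodule$x_center
  alpha_at <- function(x, z) {
    if (is.null(nodule)) return(numeric(length(x)))
    kap <- if (porous$porous) porous$permeability else porous$solid_permeability
    inside <- ((x - xc)^2 / nodule$a^2 +
               (z - nodule$z_center)^2 / nodule$b^2) <= 1
    ifelse(inside, mu / kap, 0)
  }

  sys <- .assemble_stokes(nx, nz, dx, dz, mu, U, h, alpha_at)
  sol <- tryCatch(as.numeric(Matrix::solve(sys$A, sys$b)),
                  error = function(e)
                    stop("flow solver failed: ", conditionMessage(e),
                         call. = FALSE))
  resid <- sqrt(sum((as.numeric(sys$A %*% sol) - sys$b)^2)) /
    max(sqrt(sum(sys$b^2)), .Machine$double.eps)

  nu <- (nx + 1L) * nz
  nw <- nx * (nz + 1L)
  field <- structure(list(
    u = matrix(sol[seq_len(nu)], nx + 1L, nz) * U,
    w = matrix(sol[nu + seq_len(nw)], nx, nz + 1L) * U,
    p = matrix(sol[nu + nw + seq_len(nx * nz)], nx, nz) * mu * U / dz +
      fluid$outlet_pressure,
    nx = nx, nz = nz, dx = dx, dz = dz,
    length = Lx, height = h, U = U,
    nodule = nodule, nodule_x = xc, porous = if (is.null(nodule)) NULL else porous,
    geom = geom, fluid = fluid, mesh = mesh,
    converged = resid < mesh$tolerance, residual = resid),
    class = "flow_field")
  if (!field$converged)
    stop(sprintf("flow solver did not converge: relative residual %.3g", resid),
         call. = FALSE)
  field
}

## Assemble the nondimensional MAC discretization.
## Unknown ordering: u (faces i = 0..nx, rows j = 1..nz), then w
## (i = 1..nx, j = 0..nz), then p (cells). Scales: length dz, velocity U,
## pressure mu*U/dz.
.assemble_stokes <- function(nx, nz, dx, dz, mu, U, h, alpha_at) {
  nu <- (nx + 1L) * nz
  nw <- nx * (nz + 1L)
  np <- nx * nz
  N <- nu + nw + np
  iu <- function(i, j) i + 1L + (j - 1L) * (nx + 1L)
  iw <- function(i, j) nu + i + j * nx
  ip <- function(i, j) nu + nw + i + (j - 1L) * nx

  b <- numeric(N)
  rx <- (dz / dx)^2
  Ri <- vector("list", 32L); Ci <- Ri; Xi <- Ri; k <- 0L
  addv <- function(r, c, x) {
    k <<- k + 1L
    Ri[[k]] <<- r; Ci[[k]] <<- c
    Xi[[k]] <<- if (length(x) == 1L) rep(x, length(r)) else x
  }
  uin <- function(z) 6 * (z / h) * (1 - z / h)  # in units of U

  ## drag (nondimensional: alpha * dz^2 / mu) at staggered node positions
  ug <- expand.grid(i = 0:nx, j = 1:nz)
  au <- alpha_at(ug$i * dx, (ug$j - 0.5) * dz) * dz^2 / mu
  wg <- expand.grid(i = 1:nx, j = 0:nz)
  aw <- alpha_at((wg$i - 0.5) * dx, wg$j * dz) * dz^2 / mu

  ## u: Dirichlet parabolic profile at inlet (i = 0) and outlet (i = nx)
  for (ii in c(0L, nx)) {
    j <- 1:nz
    r <- iu(ii, j)
    addv(r, r, 1)
    b[r] <- uin((j - 0.5) * dz)
  }
  ## u momentum, interior faces; wall ghosts u(i,0) = -u(i,1) etc.
  g <- expand.grid(i = 1:(nx - 1L), j = 1:nz)
  i <- g$i; j <- g$j; r <- iu(i, j)
  jb <- j == 1L; jt <- j == nz
  addv(r, r, 2 * rx + 2 + au[r] + jb + jt)
  addv(r, iu(i + 1L, j), -rx)
  addv(r, iu(i - 1L, j), -rx)
  s <- !jt; addv(r[s], iu(i[s], j[s] + 1L), -1)
  s <- !jb; addv(r[s], iu(i[s], j[s] - 1L), -1)
  addv(r, ip(i + 1L, j), dz / dx)
  addv(r, ip(i, j), -dz / dx)

  ## w: Dirichlet 0 on floor and ceiling
  for (jj in c(0L, nz)) {
    i2 <- 1:nx
    r2 <- iw(i2, jj)
    addv(r2, r2, 1)
  }
  ## w momentum, interior; inlet/outlet ghosts w(0,j) = -w(1,j) etc.
  g <- expand.grid(i = 1:nx, j = 1:(nz - 1L))
  i <- g$i; j <- g$j; r <- iw(i, j)
  ib <- i == 1L; it <- i == nx
  addv(r, r, 2 * rx + 2 + aw[i + j * nx] + rx * ib + rx * it)
  s <- !it; addv(r[s], iw(i[s] + 1L, j[s]), -rx)
  s <- !ib; addv(r[s], iw(i[s] - 1L, j[s]), -rx)
  addv(r, iw(i, j + 1L), -1)
  addv(r, iw(i, j - 1L), -1)
  addv(r, ip(i, j + 1L), 1)
  addv(r, ip(i, j), -1)

  ## continuity in every cell; pressure pinned in cell (1,1)
  g <- expand.grid(i = 1:nx, j = 1:nz)
  i <- g$i; j <- g$j; r <- ip(i, j)
  pin <- i == 1L & j == 1L
  rr <- r[!pin]; i2 <- i[!pin]; j2 <- j[!pin]
  addv(rr, iu(i2, j2), dz / dx)
  addv(rr, iu(i2 - 1L, j2), -dz / dx)
  addv(rr, iw(i2, j2), 1)
  addv(rr, iw(i2, j2 - 1L), -1)
  addv(r[pin], r[pin], 1)

  A <- Matrix::sparseMatrix(i = unlist(Ri[seq_len(k)]),
                            j = unlist(Ci[seq_len(k)]),
                            x = unlist(Xi[seq_len(k)]),
                            dims = c(N, N))
  list(A = A, b = b)
}

#' Interpolate the velocity field at arbitrary points
#'
#' Bilinear interpolation of the staggered components at physical
#' coordinates (x from 0 to the section length, z from 0 to the channel
#' height).
#'
#' @param field A `"flow_field"`.
#' @param x,z Coordinates in metres (vectors of equal length).
#' @return A two-column matrix with components `u` and `w` in m/s.
#' @export
velocity_at <- function(field, x, z) {
  stopifnot(inherits(field, "flow_field"))
  cbind(u = .interp_stag(field$u, x, z, 0, 0.5, field$dx, field$dz),
        w = .interp_stag(field$w, x, z, 0.5, 0, field$dx, field$dz))
}

## generic bilinear interpolation on a staggered grid whose node (i, j)
## (1-based) sits at ((i - 1 + off_i) * dx, (j - 1 + off_j) * dz)
.interp_stag <- function(m, x, z, off_i, off_j, dx, dz) {
  fi <- x / dx - off_i  # fractional 0-based index
  fj <- z / dz - off_j
  ni <- nrow(m); nj <- ncol(m)
  i0 <- pmin(pmax(floor(fi), 0), ni - 2L)
  j0 <- pmin(pmax(floor(fj), 0), nj - 2L)
  tx <- pmin(pmax(fi - i0, 0), 1)
  tz <- pmin(pmax(fj - j0, 0), 1)
  i0 <- i0 + 1L; j0 <- j0 + 1L  # back to 1-based
  m[cbind(i0, j0)] * (1 - tx) * (1 - tz) +
    m[cbind(i0 + 1L, j0)] * tx * (1 - tz) +
    m[cbind(i0, j0 + 1L)] * (1 - tx) * tz +
    m[cbind(i0 + 1L, j0 + 1L)] * tx * tz
}

#' Numerical wall shear stress of a solved field
#'
#' One-sided second-order estimate of \eqn{\mu \, du/dz} on the channel
#' floor, by default at the inlet quarter of the section (away from any
#' nodule). For an empty channel this converges to the closed-form
#' [wall_shear_stress()] under grid refinement.
#'
#' @param field A `"flow_field"`.
#' @param x Streamwise position in metres at which to sample (defaults to
#'   a quarter of the section length).
#' @return Shear stress in Pa.
#' @export
numeric_wall_shear <- function(field, x = field$length / 4) {
  stopifnot(inherits(field, "flow_field"))
  i <- pmin(pmax(round(x / field$dx), 1L), field$nx - 1L) + 1L
  u1 <- field$u[i, 1L]
  u2 <- field$u[i, 2L]
  field$fluid$viscosity * (9 * u1 - u2) / (3 * field$dz)
}

#' Net streamwise flux through a cross-section
#'
#' Per-unit-depth volumetric flux (m^2/s) through the vertical
#' cross-section nearest to `x`; equals \eqn{Q/w = U h} by mass
#' conservation, to discretization accuracy, at every station.
#'
#' @param field A `"flow_field"`.
#' @param x Streamwise position in metres.
#' @return Flux per unit depth in m^2/s.
#' @export
cross_section_flux <- function(field, x = field$length / 2) {
  stopifnot(inherits(field, "flow_field"))
  i <- pmin(pmax(round(x / field$dx), 0L), field$nx) + 1L
  sum(field$u[i, ]) * field$dz
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Stokes%s flow field: %d x %d cells (%.2g x %.2g um), U = %.3g mm/s\n",
              if (is.null(x$nodule)) "" else "-Brinkman",
              x$nx, x$nz, x$dx * 1e6, x$dz * 1e6, x$U * 1e3))
  if (!is.null(x$nodule)) print(x$nodule)
  cat(sprintf("converged: %s (relative residual %.2e)\n",
              x$converged, x$residual))
  invisible(x)
}
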