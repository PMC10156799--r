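#' Blood fluid properties
#'
#' Newtonian, incompressible blood model: density 1060 kg/m^3 and dynamic
#' viscosity 3.2 cP (3.2e-3 Pa s), the constants used throughout the
#' energetics calculations.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @export
fluid_properties <- function(density = 1060, viscosity = 3.2e-3) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Uniform-flow phantom
#'
#' Every voxel carries the same velocity vector at every frame; the mask is
#' the full grid. A gradient-free oracle: any viscous dissipation estimate
#' must vanish identically on it.
#'
#' @param grid a [grid_spec()].
#' @param velocity_vector m/s, length 3.
#' @return a [velocity_series()].
#' @export
make_uniform_flow <- function(grid, velocity_vector) {
  stopifnot(length(velocity_vector) == 3, all(is.finite(velocity_vector)))
  d <- c(grid$shape, grid$n_frames, 3L)
  v <- array(0, d)
  for (comp in 1:3) v[, , , , comp] <- velocity_vector[comp]
  velocity_series(grid, v,
                  venc = max(150, 1.5 * max(abs(velocity_vector)) * 100))
}

#' Steady Poiseuille tube phantom with analytic energetics
#'
#' A rigid straight tube along `axis` with the parabolic profile
#' `v(r) = 2 * mean_velocity * (1 - r^2 / R^2)` inside radius `R` and zero
#' outside. The returned truth carries the closed-form total viscous
#' dissipation rate `8 mu L Q^2 / (pi R^4)` (with `Q = pi R^2 Vbar`) and the
#' closed-form kinetic energy `(2 pi / 3) rho Vbar^2 R^2 L`, the oracles for
#' the voxel-wise energy-loss and kinetic-energy maps.
#'
#' The tube axis is placed at a fixed generic sub-voxel offset
#' (`spacing/6`, `spacing/3`) from the voxel lattice. Aligning the axis
#' exactly with voxel centres is a degenerate configuration (lattice points
#' fall exactly on the lumen boundary circle when `R` is a multiple of the
#' spacing) that breaks the first-order convergence of the discrete volume
#' integrals; any generic offset restores it.
#'
#' @param spacing isotropic voxel size in mm (scalar) or length-3 vector.
#' @param radius tube radius R in mm.
#' @param length tube length L in mm.
#' @param mean_velocity cross-sectional mean axial velocity in m/s.
#' @param axis one of "z" (default), "x", "y".
#' @param fluid a [fluid_properties()].
#' @param n_frames number of (identical) frames.
#' @param frame_duration frame duration in ms.
#' @param margin mm of empty space around the lumen.
#' @return list with elements `series` ([velocity_series()]) and `truth`
#'   (list: `analytic_el_rate` W, `analytic_ke` J, `peak_velocity` m/s,
#'   `under_resolved` flag).
#' @export
make_poiseuille_tube <- function(spacing, radius, length, mean_velocity,
                                 axis = c("z", "x", "y"),
                                 fluid = fluid_properties(),
                                 n_frames = 1L, frame_duration = 50,
                                 margin = 3) {
  axis <- match.arg(axis)
  if (base::length(spacing) == 1L) spacing <- rep(spacing, 3)
  h <- spacing
  under_resolved <- radius < 3 * max(h[1:2])
  if (under_resolved)
    warning("tube radius spans fewer than 3 voxels; gradients will be poorly resolved")
  # build along z then permute
  xs <- seq(-radius - margin, radius + margin, by = h[1]) + h[1] / 6
  ys <- seq(-radius - margin, radius + margin, by = h[2]) + h[2] / 3
  zs <- seq(0, length, by = h[3])
  nx <- base::length(xs); ny <- base::length(ys); nz <- base::length(zs)
  r2 <- outer(xs^2, ys^2, `+`)
  prof <- 2 * mean_velocity * (1 - r2 / radius^2)
  m2 <- r2 <= radius^2
  prof[!m2] <- 0
  vz <- array(prof, c(nx, ny, nz))
  mask <- array(m2, c(nx, ny, nz))
  vel <- array(0, c(nx, ny, nz, n_frames, 3L))
  for (k in seq_len(n_frames)) vel[, , , k, 3] <- vz
  origin <- c(xs[1], ys[1], zs[1])
  perm <- switch(axis, z = 1:3, x = c(3, 1, 2), y = c(2, 3, 1))
  if (axis != "z") {
    vel <- aperm(vel, c(perm, 4, 5))[, , , , perm, drop = FALSE]
    mask <- aperm(mask, perm)
    h <- h[perm]
    origin <- origin[perm]
  }
  grid <- grid_spec(dim(mask), h, n_frames, frame_duration, origin)
  series <- velocity_series(grid, vel, mask = mask,
                            venc = max(100, 2 * mean_velocity * 100 * 1.2))
  Rm <- radius * 1e-3; Lm <- length * 1e-3
  Q <- pi * Rm^2 * mean_velocity
  truth <- list(
    analytic_el_rate = 8 * fluid$viscosity * Lm * Q^2 / (pi * Rm^4),
    analytic_ke = (2 * pi / 3) * fluid$density * mean_velocity^2 * Rm^2 * Lm,
    peak_velocity = 2 * mean_velocity,
    under_resolved = under_resolved)
  list(series = series, truth = truth)
}

#' Solid-body rotation phantom
#'
#' `v = omega x r` inside a cylindrical lumen about the chosen axis. Rigid
#' rotation has a purely antisymmetric velocity gradient, so the symmetric
#' strain rate -- and with it any correct viscous dissipation estimate -- is
#' identically zero, while pathlines are exact circles with period
#' `2 pi / omega`.
#'
#' @param grid a [grid_spec()].
#' @param omega angular velocity in rad/s.
#' @param axis rotation axis, "z", "x" or "y".
#' @param radius lumen cylinder radius in mm (default: 90% of the largest
#'   inscribed radius).
#' @param center world (mm) point on the axis; defaults to the grid centre.
#' @return a [velocity_series()].
#' @export
make_solid_body_rotation <- function(grid, omega, axis = c("z", "x", "y"),
                                     radius = NULL, center = NULL) {
  axis <- match.arg(axis)
  stopifnot(is.finite(omega))
  ax <- grid_axes(grid)
  if (is.null(center))
    center <- c(mean(range(ax$x)), mean(range(ax$y)), mean(range(ax$z)))
  co <- coord_arrays(grid)
  dx <- co$x - center[1]; dy <- co$y - center[2]; dz <- co$z - center[3]
  # in-plane radius about the rotation axis, mm
  r2 <- switch(axis, z = dx^2 + dy^2, x = dy^2 + dz^2, y = dz^2 + dx^2)
  if (is.null(radius)) {
    half <- switch(axis,
                   z = min(diff(range(ax$x)), diff(range(ax$y))) / 2,
                   x = min(diff(range(ax$y)), diff(range(ax$z))) / 2,
                   y = min(diff(range(ax$z)), diff(range(ax$x))) / 2)
    radius <- 0.9 * half
  }
  mask <- r2 <= radius^2
  # omega x r, r in mm -> m
  vx <- vy <- vz <- array(0, grid$shape)
  if (axis == "z") { vx <- -omega * dy * 1e-3; vy <- omega * dx * 1e-3 }
  if (axis == "x") { vy <- -omega * dz * 1e-3; vz <- omega * dy * 1e-3 }
  if (axis == "y") { vz <- -omega * dx * 1e-3; vx <- omega * dz * 1e-3 }
  vx[!mask] <- 0; vy[!mask] <- 0; vz[!mask] <- 0
  vel <- array(0, c(grid$shape, grid$n_frames, 3L))
  for (k in seq_len(grid$n_frames)) {
    vel[, , , k, 1] <- vx; vel[, , , k, 2] <- vy; vel[, , , k, 3] <- vz
  }
  vmax <- abs(omega) * radius * 1e-3
  velocity_series(grid, vel, mask = mask, venc = max(100, 150 * vmax))
}
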