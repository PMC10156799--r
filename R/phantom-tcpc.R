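#' Streamfunction of the planar caval-junction phantom
#'
#' Builds the 2-D streamfunction psi of a cross-shaped total cavopulmonary
#' connection: IVC entering from below, SVC from above, LPA exiting left,
#' RPA exiting right, channels of half-width `a` (mm). The in-plane velocity
#' is `(u, v) = (dpsi/dy, -dpsi/dx)`, so the continuous field is exactly
#' divergence-free and streamlines are level sets of psi.
#'
#' Limb profiles are plug flow (psi linear across the channel), which makes
#' three quantities coincide exactly: the flux fraction of IVC flow leaving
#' through the LPA, the psi-level fraction, and the fraction of uniformly
#' seeded IVC particles whose streamline exits the LPA. The junction square
#' is a transfinite (Coons) interpolation of the four limb profiles with a
#' smoothstep blend, plus a closed-form compact correction that pins a
#' stagnation point at the junction centre with
#' `psi = (1 - split_ivc_to_lpa) * q_ivc`. The psi value at the interior
#' stagnation point is what selects how the incoming psi-levels are divided
#' between the two outlets, so pinning it realises the requested splits
#' exactly in the continuous field.
#'
#' @param split_ivc_to_lpa,split_svc_to_lpa fractions in `[0, 1]`.
#' @param v_ivc,v_svc plug inflow speeds, m/s.
#' @param a channel half-width, mm.
#' @return list with `psi(x, y)` (vectorised), per-unit-depth fluxes and
#'   wall values. psi is extended continuously outside the cross (constant
#'   beyond walls) so finite differences may be taken anywhere.
#' @keywords internal
tcpc_streamfunction <- function(split_ivc_to_lpa, split_svc_to_lpa,
                                v_ivc = 0.2, v_svc = 0.2, a = 8) {
  f <- split_ivc_to_lpa; g <- split_svc_to_lpa
  stopifnot(f >= 0, f <= 1, g >= 0, g <= 1, v_ivc > 0, v_svc > 0, a > 0)
  qI <- v_ivc * 2 * a
  qS <- v_svc * 2 * a
  qL <- f * qI + g * qS
  qR <- qI + qS - qL
  pSW <- qI; pSE <- 0; pNW <- qI - qL; pNE <- qI - qL + qS
  psiS <- function(x) qI * (a - x) / (2 * a)          # IVC (bottom edge)
  psiN <- function(x) pNE - qS * (a - x) / (2 * a)    # SVC (top edge)
  psiW <- function(y) pNW + qL * (a - y) / (2 * a)    # LPA (left edge)
  psiE <- function(y) pNE - qR * (a - y) / (2 * a)    # RPA (right edge)
  H <- function(s) {
    s <- pmin(pmax(s, 0), 1)
    3 * s^2 - 2 * s^3
  }
  coons <- function(x, y) {
    A <- H((x + a) / (2 * a)); B <- H((y + a) / (2 * a))
    (1 - A) * psiW(y) + A * psiE(y) + (1 - B) * psiS(x) + B * psiN(x) -
      ((1 - A) * (1 - B) * pSW + A * (1 - B) * pSE +
         (1 - A) * B * pNW + A * B * pNE)
  }
  # pin a stagnation point at the origin: psi(0,0) = (1 - f) qI, grad = 0
  eps <- 1e-6 * a
  c0 <- (1 - f) * qI - coons(0, 0)
  c1 <- -(coons(eps, 0) - coons(-eps, 0)) / (2 * eps)
  c2 <- -(coons(0, eps) - coons(0, -eps)) / (2 * eps)
  bump <- function(x, y) ((1 - (x / a)^2) * (1 - (y / a)^2))^2
  psi <- function(x, y) {
    px <- pmin(pmax(x, -a), a)
    py <- pmin(pmax(y, -a), a)
    out <- numeric(length(px))
    inJ <- abs(x) <= a & abs(y) <= a
    s <- y < -a
    n <- y > a
    w <- x < -a & !s & !n
    e <- x > a & !s & !n
    out[s] <- psiS(px[s])
    out[n] <- psiN(px[n])
    out[w] <- psiW(py[w])
    out[e] <- psiE(py[e])
    out[inJ] <- coons(x[inJ], y[inJ]) +
      (c0 + c1 * x[inJ] + c2 * y[inJ]) * bump(x[inJ], y[inJ])
    out
  }
  list(psi = psi, q_ivc = qI, q_svc = qS, q_lpa = qL, q_rpa = qR,
       psi_saddle = (1 - f) * qI, half_width = a)
}

#' TCPC junction phantom with known flow-split ground truth
#'
#' Generates a synthetic 4D flow dataset of a planar cross-shaped total
#' cavopulmonary connection extruded over a slab, with prescribed caval flow
#' splits, optional global sinusoidal pulsatility, and a surrounding static
#' tissue shell (zero velocity, intermediate magnitude) for preprocessing
#' tests. Voxel velocities are central differences of the streamfunction, so
#' the discrete in-plane divergence vanishes identically at interior voxels.
#'
#' @param split_ivc_to_lpa fraction of IVC flow directed to the LPA.
#' @param split_svc_to_lpa fraction of SVC flow directed to the LPA;
#'   defaults to `split_ivc_to_lpa`.
#' @param pulsatility fractional amplitude in `[0, 1)` of the sinusoidal
#'   modulation `v(t) = v0 (1 + pulsatility * sin(2 pi t / T))`.
#' @param spacing isotropic voxel size, mm.
#' @param n_frames,frame_duration temporal sampling (frames x ms).
#' @param half_width channel half-width `a`, mm.
#' @param limb_length length of each limb beyond the junction, mm.
#' @param slab slab thickness in z, mm.
#' @param v_ivc,v_svc caval plug speeds, m/s.
#' @param shell_width static-shell thickness, mm (0 disables).
#' @return list with `series` ([velocity_series()]), `truth` (splits, label
#'   volume, static shell, the streamfunction closure) and `regions`
#'   (a [region_model()] with boundary planes at the four limb entrances).
#' @export
make_tcpc_phantom <- function(split_ivc_to_lpa = 0.5,
                              split_svc_to_lpa = split_ivc_to_lpa,
                              pulsatility = 0,
                              spacing = 1,
                              n_frames = 12L, frame_duration = 50,
                              half_width = 8, limb_length = 32, slab = 20,
                              v_ivc = 0.2, v_svc = 0.2,
                              shell_width = 3) {
  stopifnot(split_ivc_to_lpa >= 0, split_ivc_to_lpa <= 1,
            split_svc_to_lpa >= 0, split_svc_to_lpa <= 1,
            pulsatility >= 0, pulsatility < 1)
  a <- half_width
  sf <- tcpc_streamfunction(split_ivc_to_lpa, split_svc_to_lpa,
                            v_ivc, v_svc, a)
  h <- spacing
  ext <- a + limb_length + shell_width + 2 * h
  # half-voxel lattice offset: voxel centres sit off the walls and off the
  # symmetry axes, and the discrete lumen is exactly mirror-symmetric
  xs <- seq(-ext, ext - h / 2, by = h) + h / 2
  ys <- seq(-ext, ext - h / 2, by = h) + h / 2
  zs <- seq(0, slab + 2 * (shell_width + 2 * h), by = h)
  z0 <- shell_width + 2 * h   # slab occupies [z0, z0 + slab]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  X <- matrix(rep(xs, ny), nx, ny)
  Y <- matrix(rep(ys, each = nx), nx, ny)
  in_cross2d <- (abs(X) <= a & Y >= -a - limb_length & Y <= a + limb_length) |
                (abs(Y) <= a & X >= -a - limb_length & X <= a + limb_length)
  in_slab <- zs >= z0 & zs <= z0 + slab
  # discrete curl of psi: exactly divergence-free central differences
  u2d <-  (matrix(sf$psi(as.vector(X), as.vector(Y) + h), nx, ny) -
           matrix(sf$psi(as.vector(X), as.vector(Y) - h), nx, ny)) / (2 * h)
  v2d <- -(matrix(sf$psi(as.vector(X) + h, as.vector(Y)), nx, ny) -
           matrix(sf$psi(as.vector(X) - h, as.vector(Y)), nx, ny)) / (2 * h)
  u2d[!in_cross2d] <- 0
  v2d[!in_cross2d] <- 0

  mask <- array(FALSE, c(nx, ny, nz))
  mask[, , which(in_slab)] <- in_cross2d
  grid <- grid_spec(c(nx, ny, nz), rep(h, 3), n_frames, frame_duration,
                    origin = c(xs[1], ys[1], zs[1]))
  tt <- frame_times_s(grid)
  Tcyc <- cycle_duration_s(grid)
  scale_t <- 1 + pulsatility * sin(2 * pi * tt / Tcyc)
  vel <- array(0, c(nx, ny, nz, n_frames, 3L))
  for (k in seq_len(n_frames)) {
    for (kz in which(in_slab)) {
      vel[, , kz, k, 1] <- u2d * scale_t[k]
      vel[, , kz, k, 2] <- v2d * scale_t[k]
    }
  }

  # region labels: 1 IVC, 2 SVC, 3 connection, 4 LPA, 5 RPA
  lab2d <- array(0L, c(nx, ny))
  lab2d[in_cross2d & abs(X) <= a & Y < -a] <- 1L
  lab2d[in_cross2d & abs(X) <= a & Y > a] <- 2L
  lab2d[in_cross2d & abs(X) <= a & abs(Y) <= a] <- 3L
  lab2d[in_cross2d & X < -a & abs(Y) <= a] <- 4L
  lab2d[in_cross2d & X > a & abs(Y) <= a] <- 5L
  labels <- array(0L, c(nx, ny, nz))
  labels[, , which(in_slab)] <- lab2d

  # static shell: tissue band around the lumen, zero velocity,
  # intermediate magnitude
  shell <- array(FALSE, c(nx, ny, nz))
  if (shell_width > 0) {
    n_dil <- ceiling(shell_width / h)
    dil <- mask
    for (i in seq_len(n_dil)) {
      grown <- dil
      for (axis in 1:3) {
        grown <- grown | shift_array(dil, axis, 1L) | shift_array(dil, axis, -1L)
      }
      dil <- grown
    }
    shell <- dil & !mask
  }
  magnitude <- array(0, c(nx, ny, nz, n_frames))
  for (k in seq_len(n_frames)) {
    m3 <- array(0, c(nx, ny, nz))
    m3[mask] <- 1
    m3[shell] <- 0.6
    magnitude[, , , k] <- m3
  }

  vmax <- max(sqrt(vel[, , , , 1]^2 + vel[, , , , 2]^2))
  series <- velocity_series(grid, vel, magnitude = magnitude, mask = mask,
                            venc = max(100, 150 * vmax))
  zmid <- z0 + slab / 2
  rad <- sqrt(a^2 + (slab / 2)^2) + 2
  planes <- list(
    lpa = analysis_plane(c(-a, 0, zmid), c(-1, 0, 0), rad, "LPA_entrance"),
    rpa = analysis_plane(c(a, 0, zmid), c(1, 0, 0), rad, "RPA_entrance"),
    ivc = analysis_plane(c(0, -a, zmid), c(0, -1, 0), rad, "region_boundary"),
    svc = analysis_plane(c(0, a, zmid), c(0, 1, 0), rad, "region_boundary"))
  regions <- region_model(labels, grid, centerlines = list(),
                          boundary_planes = planes)
  truth <- list(split_fraction_lpa_from_ivc = split_ivc_to_lpa,
                split_fraction_lpa_from_svc = split_svc_to_lpa,
                mask_labels = labels, static_shell = shell,
                streamfunction = sf,
                v_ivc = v_ivc, v_svc = v_svc, half_width = a,
                limb_length = limb_length, slab = c(z0, z0 + slab))
  list(series = series, truth = truth, regions = regions)
}

#' Mirror a TCPC phantom left-right
#'
#' Reflects the volume about the mid-sagittal (x) axis: flips all volumes
#' along x, negates the x velocity component, swaps the LPA/RPA labels and
#' entrance planes. Used to check that the flow-distribution estimate is
#' equivariant under reflection.
#'
#' @param phantom a list as returned by [make_tcpc_phantom()].
#' @return a phantom list of the same structure.
#' @export
reflect_tcpc_lr <- function(phantom) {
  s <- phantom$series
  g <- s$grid
  nx <- g$shape[1]
  flip <- function(a) {
    nd <- length(dim(a))
    idx <- c(list(rev(seq_len(nx))), rep(list(quote(expr = )), nd - 1))
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  vel <- flip(s$velocity)
  vel[, , , , 1] <- -vel[, , , , 1]
  mask <- array(flip(s$mask), g$shape)
  mag <- array(flip(s$magnitude), dim(s$magnitude))
  # world x-axis is reversed: new origin keeps voxel centres at the same
  # mirrored world positions
  ax <- grid_axes(g)
  new_origin <- c(-ax$x[nx], g$origin[2], g$origin[3])
  g2 <- grid_spec(g$shape, g$spacing, g$n_frames, g$frame_duration, new_origin)
  series <- velocity_series(g2, vel, magnitude = mag, mask = mask,
                            venc = s$venc, cycle_fraction = s$cycle_fraction)
  labels <- array(as.integer(flip(phantom$truth$mask_labels)), g$shape)
  swap <- labels == 4L
  labels[labels == 5L] <- 4L
  labels[swap] <- 5L
  mirror_plane <- function(p, role) {
    analysis_plane(c(-p$origin[1], p$origin[2], p$origin[3]),
                   c(-p$normal[1], p$normal[2], p$normal[3]),
                   p$in_plane_radius, role)
  }
  op <- phantom$regions$boundary_planes
  planes <- list(lpa = mirror_plane(op$rpa, "LPA_entrance"),
                 rpa = mirror_plane(op$lpa, "RPA_entrance"),
                 ivc = op$ivc, svc = op$svc)
  regions <- region_model(labels, g2, centerlines = list(),
                          boundary_planes = planes)
  truth <- phantom$truth
  truth$mask_labels <- labels
  truth$static_shell <- array(flip(phantom$truth$static_shell), g$shape)
  truth$split_fraction_lpa_from_ivc <- 1 - truth$split_fraction_lpa_from_ivc
  truth$split_fraction_lpa_from_svc <- 1 - truth$split_fraction_lpa_from_svc
  list(series = series, truth = truth, regions = regions)
}
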