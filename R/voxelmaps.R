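#' Truncate a set of acquisitions to a common cardiac-cycle fraction
#'
#' Gating differences mean different scans cover different fractions of the
#' cardiac cycle. The minimum covered fraction is selected and every series
#' keeps its first `floor(common / per_frame)` frames, so all outputs cover
#' the same fraction within one frame (truncation removes late diastole).
#'
#' @param series_list list of [velocity_series()].
#' @return list of truncated series.
#' @export
truncate_to_common_fraction <- function(series_list) {
  if (!length(series_list)) stop("empty series list")
  common <- min(vapply(series_list, function(s) s$cycle_fraction, 0))
  lapply(series_list, function(s) {
    per_frame <- s$cycle_fraction / s$grid$n_frames
    keep <- max(1L, min(s$grid$n_frames, floor(common / per_frame + 1e-9)))
    if (keep == s$grid$n_frames) return(s)
    g <- s$grid
    g2 <- grid_spec(g$shape, g$spacing, keep, g$frame_duration, g$origin)
    velocity_series(g2,
                    s$velocity[, , , seq_len(keep), , drop = FALSE],
                    magnitude = s$magnitude[, , , seq_len(keep), drop = FALSE],
                    mask = s$mask, venc = s$venc,
                    cycle_fraction = keep * per_frame)
  })
}

#' Resample a series to isotropic resolution
#'
#' Trilinear interpolation of every velocity component and the magnitude,
#' frame by frame, onto an isotropic grid covering the same world extent;
#' the lumen mask is resampled nearest-neighbour.
#'
#' @param series a [velocity_series()].
#' @param target isotropic voxel size in mm (default 1).
#' @return a [velocity_series()] on the resampled grid.
#' @export
resample_isotropic <- function(series, target = 1) {
  stopifnot(target > 0)
  g <- series$grid
  ax <- grid_axes(g)
  new_ax <- lapply(ax, function(a) seq(a[1], a[length(a)], by = target))
  shape2 <- unname(vapply(new_ax, length, 0L))
  g2 <- grid_spec(shape2, rep(target, 3), g$n_frames, g$frame_duration,
                  origin = c(new_ax$x[1], new_ax$y[1], new_ax$z[1]))
  idx <- world_to_index(g, as.matrix(expand.grid(new_ax$x, new_ax$y,
                                                 new_ax$z)))
  vel <- array(0, c(shape2, g$n_frames, 3L))
  mag <- array(0, c(shape2, g$n_frames))
  for (k in seq_len(g$n_frames)) {
    for (comp in 1:3) {
      vol <- array(series$velocity[, , , k, comp], g$shape)
      vel[, , , k, comp] <- array(interp_trilinear(vol, idx), shape2)
    }
    mag[, , , k] <- array(
      interp_trilinear(array(series$magnitude[, , , k], g$shape), idx),
      shape2)
  }
  mask_num <- array(as.numeric(series$mask), g$shape)
  ridx <- round(idx)
  for (a in 1:3) ridx[, a] <- pmin(pmax(ridx[, a], 1), g$shape[a])
  lin <- (ridx[, 3] - 1) * prod(g$shape[1:2]) +
    (ridx[, 2] - 1) * g$shape[1] + ridx[, 1]
  mask2 <- array(series$mask[lin], shape2)
  velocity_series(g2, vel, magnitude = mag, mask = mask2,
                  venc = series$venc, cycle_fraction = series$cycle_fraction)
}

# mask-aware spatial gradient (1/s units when v is m/s): central differences
# at interior lumen voxels, second-order one-sided where only one neighbour
# is inside the lumen (falling back to first-order two-point at single-voxel
# spans), zero where no in-mask neighbour exists along the axis.
# Out-of-mask neighbours are excluded rather than read as zero, so wall
# voxels never see artificial shear against the background.
grad_masked <- function(vol, mask, axis, h_mm) {
  h <- h_mm * 1e-3
  vp <- shift_array(vol, axis, 1L);  vm <- shift_array(vol, axis, -1L)
  vp2 <- shift_array(vol, axis, 2L); vm2 <- shift_array(vol, axis, -2L)
  mp <- shift_mask(mask, axis, 1L);  mm <- shift_mask(mask, axis, -1L)
  mp2 <- shift_mask(mask, axis, 2L); mm2 <- shift_mask(mask, axis, -2L)
  g <- array(0, dim(vol))
  both <- mask & mp & mm
  fw2 <- mask & mp & !mm & mp2
  fw1 <- mask & mp & !mm & !mp2
  bw2 <- mask & !mp & mm & mm2
  bw1 <- mask & !mp & mm & !mm2
  g[both] <- (vp[both] - vm[both]) / (2 * h)
  g[fw2] <- (-3 * vol[fw2] + 4 * vp[fw2] - vp2[fw2]) / (2 * h)
  g[fw1] <- (vp[fw1] - vol[fw1]) / h
  g[bw2] <- (3 * vol[bw2] - 4 * vm[bw2] + vm2[bw2]) / (2 * h)
  g[bw1] <- (vol[bw1] - vm[bw1]) / h
  g
}

#' Peak-velocity map and regional 98th percentile
#'
#' Per voxel, the maximum speed over all frames. The regional reduction is
#' the 98th percentile (linear interpolation between order statistics) over
#' the region's voxels.
#'
#' @param series a [velocity_series()].
#' @return volume (m/s), zero outside the lumen.
#' @export
peak_velocity_map <- function(series) {
  sp <- speed_map(series)
  pk <- apply(sp, 1:3, max)
  pk[!series$mask] <- 0
  pk
}

#' Stasis map
#'
#' Percentage of cardiac frames in which a voxel's speed stays below the
#' threshold (0.1 m/s by default).
#'
#' @param series a [velocity_series()].
#' @param threshold m/s, must be positive.
#' @return volume in percent (0-100), zero outside the lumen.
#' @export
stasis_map <- function(series, threshold = 0.1) {
  stopifnot(threshold > 0)
  sp <- speed_map(series)
  st <- 100 * apply(sp < threshold, 1:3, mean)
  st[!series$mask] <- 0
  st
}

#' Kinetic-energy map
#'
#' Per voxel and frame `KE = 1/2 rho V_voxel |v|^2`, summed over frames.
#'
#' @param series a [velocity_series()].
#' @param fluid a [fluid_properties()].
#' @return volume in J (time-summed), zero outside the lumen.
#' @export
kinetic_energy_map <- function(series, fluid = fluid_properties()) {
  sp <- speed_map(series)
  ke <- 0.5 * fluid$density * voxel_volume_m3(series$grid) *
    apply(sp^2, 1:3, sum)
  ke[!series$mask] <- 0
  ke
}

# viscous dissipation function phi_v (1/s^2) for one frame:
# 1/2 sum_ij [ (dv_j/dx_i + dv_i/dx_j) - (2/3)(div V) delta_ij ]^2
dissipation_function <- function(vframe, mask, spacing) {
  gr <- vector("list", 3L)
  for (i in 1:3) {
    gr[[i]] <- lapply(1:3, function(j)
      grad_masked(array(vframe[, , , j], dim(mask)), mask, i, spacing[i]))
  }
  div <- gr[[1]][[1]] + gr[[2]][[2]] + gr[[3]][[3]]
  phi <- array(0, dim(mask))
  for (i in 1:3) for (j in 1:3) {
    term <- gr[[i]][[j]] + gr[[j]][[i]]
    if (i == j) term <- term - (2 / 3) * div
    phi <- phi + term^2
  }
  phi <- phi / 2
  phi[!mask] <- 0
  phi
}

#' Viscous energy-loss maps
#'
#' The dissipation function phi_v is evaluated per voxel and frame from
#' mask-aware velocity gradients; the energy-loss rate is
#' `mu * V_voxel * phi_v` (W). `el_tot` integrates the rate over the covered
#' cycle (trapezoidal rule over the frame times; a single frame counts one
#' frame duration) and `el_mean` is the arithmetic frame average of the
#' rate. The retained `-2/3 div` term makes phi_v insensitive to the small
#' nonzero divergence of measured fields.
#'
#' @param series a [velocity_series()].
#' @param fluid a [fluid_properties()].
#' @return list: `el_rate` (nx, ny, nz, n_frames array, W), `el_tot` (J
#'   volume), `el_mean` (W volume), `covered_duration_s`.
#' @export
energy_loss_maps <- function(series, fluid = fluid_properties()) {
  g <- series$grid
  if (sum(series$mask) < 2L) stop("degenerate lumen mask")
  vvox <- voxel_volume_m3(g)
  nt <- g$n_frames
  rate <- array(0, c(g$shape, nt))
  for (k in seq_len(nt)) {
    vframe <- array(series$velocity[, , , k, ], c(g$shape, 3L))
    phi <- dissipation_function(vframe, series$mask, g$spacing)
    rate[, , , k] <- fluid$viscosity * vvox * phi
  }
  fd_s <- g$frame_duration * 1e-3
  if (nt == 1L) {
    el_tot <- rate[, , , 1] * fd_s
    el_mean <- rate[, , , 1]
    dur <- fd_s
  } else {
    # trapezoid over frame onset times
    w <- c(0.5, rep(1, nt - 2L), 0.5) * fd_s
    el_tot <- array(0, g$shape)
    for (k in seq_len(nt)) el_tot <- el_tot + w[k] * rate[, , , k]
    el_mean <- apply(rate, 1:3, mean)
    dur <- (nt - 1L) * fd_s
  }
  list(el_rate = rate, el_tot = el_tot, el_mean = el_mean,
       covered_duration_s = dur)
}

#' Compute all five voxel-wise hemodynamic maps
#'
#' Peak velocity, stasis, time-summed kinetic energy, total energy loss and
#' mean energy-loss rate on the series' grid.
#'
#' @param series a [velocity_series()] (typically already resampled to 1 mm
#'   isotropic via [resample_isotropic()]).
#' @param fluid a [fluid_properties()].
#' @param stasis_threshold m/s (default 0.1).
#' @return object of class `hemodynamic_maps`.
#' @export
hemodynamic_maps <- function(series, fluid = fluid_properties(),
                             stasis_threshold = 0.1) {
  el <- energy_loss_maps(series, fluid)
  structure(list(
    peak_velocity = peak_velocity_map(series),
    stasis = stasis_map(series, stasis_threshold),
    kinetic_energy = kinetic_energy_map(series, fluid),
    el_tot = el$el_tot,
    el_mean = el$el_mean,
    covered_duration_s = el$covered_duration_s,
    voxel_volume_m3 = voxel_volume_m3(series$grid),
    mask = series$mask,
    grid = series$grid),
    class = "hemodynamic_maps")
}

#' Regional summaries of the hemodynamic maps
#'
#' One row per region: the 98th percentile of peak velocity and the mean of
#' stasis, kinetic energy, total energy loss and mean energy-loss rate over
#' the region's voxels.
#'
#' @param maps a [hemodynamic_maps()].
#' @param regions a [region_model()] on the same grid.
#' @return data.frame with columns `region`, `n_voxels`,
#'   `peak_velocity_p98`, `stasis_mean`, `ke_mean`, `el_tot_mean`,
#'   `el_mean_mean`.
#' @export
regional_summary <- function(maps, regions) {
  if (!identical(dim(maps$peak_velocity), dim(regions$labels)))
    stop("maps and region labels are on different grids")
  rn <- region_names()
  rows <- lapply(names(rn), function(nm) {
    sel <- regions$labels == rn[[nm]]
    if (!any(sel)) stop(sprintf("region %s is empty", nm))
    data.frame(
      region = nm,
      n_voxels = sum(sel),
      peak_velocity_p98 = quantile(maps$peak_velocity[sel], 0.98,
                                   names = FALSE, type = 7),
      stasis_mean = mean(maps$stasis[sel]),
      ke_mean = mean(maps$kinetic_energy[sel]),
      el_tot_mean = mean(maps$el_tot[sel]),
      el_mean_mean = mean(maps$el_mean[sel]))
  })
  do.call(rbind, rows)
}
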