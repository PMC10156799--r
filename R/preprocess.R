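#' Detect static tissue voxels
#'
#' A voxel is flagged static when the temporal standard deviation of every
#' velocity component falls below `std_threshold` and its time-averaged
#' magnitude lies above the noise floor (so air/background is excluded).
#' Static tissue is where eddy-current phase offsets can be estimated,
#' since its true velocity is zero.
#'
#' @param series a [velocity_series()] with at least 2 frames.
#' @param std_threshold m/s; default 0.01.
#' @param mag_floor_quantile quantile of the positive time-mean magnitude
#'   used as the noise floor; default 0.05.
#' @return logical volume `(nx, ny, nz)`.
#' @export
detect_static_tissue <- function(series, std_threshold = 0.01,
                                 mag_floor_quantile = 0.05) {
  g <- series$grid
  if (g$n_frames < 2L)
    stop("static-tissue detection needs at least 2 frames")
  d4 <- c(g$shape, g$n_frames)
  ok <- array(TRUE, g$shape)
  for (comp in 1:3) {
    vc <- array(series$velocity[, , , , comp], d4)
    mu <- apply(vc, 1:3, mean)
    s2 <- apply(vc^2, 1:3, mean) - mu^2
    s2[s2 < 0] <- 0
    ok <- ok & sqrt(s2 * g$n_frames / (g$n_frames - 1)) < std_threshold
  }
  mmean <- apply(array(series$magnitude, d4), 1:3, mean)
  pos <- mmean[mmean > 0]
  floor_val <- if (length(pos)) quantile(pos, mag_floor_quantile, names = FALSE) else 0
  ok & mmean >= floor_val
}

#' Correct spatial phase-offset errors
#'
#' Fits, per velocity component, a least-squares spatial polynomial (order 1
#' or 2, world mm coordinates) to the time-averaged velocity over the static
#' tissue voxels, and subtracts the fitted polynomial from every voxel of
#' every frame. Eddy-current offsets are temporally static, hence the fit on
#' the time average.
#'
#' @param series a [velocity_series()].
#' @param static_mask logical volume from [detect_static_tissue()].
#' @param poly_order 1 or 2.
#' @return list: `series` (corrected), `report` with per-component
#'   `offset_coefficients` (basis `1, x, y, z[, x^2, ...]`).
#' @export
correct_phase_offsets <- function(series, static_mask, poly_order = 1L) {
  stopifnot(poly_order %in% c(1L, 2L))
  g <- series$grid
  if (!any(static_mask)) {
    warning("empty static mask; phase-offset correction skipped")
    return(list(series = series,
                report = list(offset_coefficients = NULL,
                              n_static_voxels = 0L)))
  }
  co <- coord_arrays(g)
  sel <- which(static_mask)
  B_fit <- poly_basis(cbind(co$x[sel], co$y[sel], co$z[sel]), poly_order)
  B_all <- poly_basis(cbind(as.vector(co$x), as.vector(co$y),
                            as.vector(co$z)), poly_order)
  d4 <- c(g$shape, g$n_frames)
  out <- series
  coefs <- vector("list", 3L)
  for (comp in 1:3) {
    vc <- array(series$velocity[, , , , comp], d4)
    vbar <- apply(vc, 1:3, mean)
    fit <- stats::lm.fit(B_fit, vbar[sel])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coefs[[comp]] <- unname(cf)
    off <- array(as.vector(B_all %*% cf), g$shape)
    for (k in seq_len(g$n_frames))
      out$velocity[, , , k, comp] <- out$velocity[, , , k, comp] - off
  }
  list(series = out,
       report = list(offset_coefficients = coefs,
                     n_static_voxels = length(sel),
                     poly_order = poly_order))
}

#' Velocity anti-aliasing (phase unwrapping)
#'
#' Venc wrap-around shifts a velocity value by multiples of `2 venc`. The
#' corrector compares each voxel value, per component and frame, with the
#' median of its 6-neighbourhood; values differing from that median by more
#' than the venc are shifted by the multiple of `2 venc` that brings them
#' closest to it. Sweeps repeat to a fixed point (at most `max_iter`), so
#' wrapped patches are peeled from their rim inwards.
#'
#' @param series a [velocity_series()].
#' @param max_iter sweep cap, default 10.
#' @return list: `series` (unwrapped), `n_fixed` (total voxel values moved).
#' @export
unalias <- function(series, max_iter = 10L) {
  g <- series$grid
  venc_ms <- series$venc / 100
  v <- series$velocity
  d4 <- c(g$shape, g$n_frames)
  n_fixed <- 0L
  for (comp in 1:3) for (k in seq_len(g$n_frames)) {
    vol <- array(v[, , , k, comp], g$shape)
    for (it in seq_len(max_iter)) {
      nb <- cbind(as.vector(shift_array(vol, 1, 1L)),
                  as.vector(shift_array(vol, 1, -1L)),
                  as.vector(shift_array(vol, 2, 1L)),
                  as.vector(shift_array(vol, 2, -1L)),
                  as.vector(shift_array(vol, 3, 1L)),
                  as.vector(shift_array(vol, 3, -1L)))
      med <- median6(nb)
      dev <- as.vector(vol) - med
      wrap <- abs(dev) > venc_ms
      if (!any(wrap)) break
      shift_n <- round(dev[wrap] / (2 * venc_ms))
      moved <- shift_n != 0
      if (!any(moved)) break
      vol[which(wrap)[moved]] <- vol[which(wrap)[moved]] -
        2 * venc_ms * shift_n[moved]
      n_fixed <- n_fixed + sum(moved)
    }
    v[, , , k, comp] <- vol
  }
  out <- series
  out$velocity <- v
  list(series = out, n_fixed = n_fixed)
}

#' Phase-contrast MR angiogram (PC-MRA)
#'
#' The time-mean of the magnitude-weighted speed,
#' `PCMRA(x) = (1/T) sum_t mag_t(x) * |v_t(x)|`. Bright where blood moves,
#' dark in static tissue and air; thresholding it segments the lumen.
#'
#' @param series a [velocity_series()].
#' @return nonnegative volume `(nx, ny, nz)`.
#' @export
compute_pcmra <- function(series) {
  sp <- speed_map(series)
  d4 <- dim(sp)
  apply(array(series$magnitude, d4) * sp, 1:3, mean)
}

#' Zero velocities where the magnitude is at noise level
#'
#' Voxels whose time-mean magnitude falls below the given quantile of the
#' in-mask magnitude distribution carry no reliable phase; their velocity is
#' zeroed.
#'
#' @param series a [velocity_series()].
#' @param quantile_floor quantile (default 0.05) of in-mask magnitude.
#' @return list: `series`, `noise_mask` (logical volume of zeroed voxels).
#' @export
apply_noise_mask <- function(series, quantile_floor = 0.05) {
  g <- series$grid
  mmean <- apply(array(series$magnitude, c(g$shape, g$n_frames)), 1:3, mean)
  floor_val <- quantile(mmean[series$mask], quantile_floor, names = FALSE)
  noise_mask <- mmean < floor_val
  out <- series
  for (k in seq_len(g$n_frames)) for (comp in 1:3) {
    vol <- out$velocity[, , , k, comp]
    vol[noise_mask] <- 0
    out$velocity[, , , k, comp] <- vol
  }
  list(series = out, noise_mask = noise_mask)
}

#' Otsu threshold of a numeric sample
#'
#' Maximises between-class variance over a histogram; used to turn the
#' PC-MRA into a lumen segmentation on phantoms.
#'
#' @param x numeric vector.
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}
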