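#' Time-resolved 3-component velocity field
#'
#' The central data container: velocity in m/s on a regular grid, one 3-D
#' volume per cardiac frame and component, plus the magnitude (modulus)
#' image, the lumen mask, the velocity-encoding limit (venc) and the
#' fraction of the cardiac cycle covered by the acquisition.
#'
#' @param grid a [grid_spec()].
#' @param velocity numeric array `(nx, ny, nz, n_frames, 3)`, m/s.
#' @param magnitude numeric array `(nx, ny, nz, n_frames)`, arbitrary units,
#'   nonnegative. Defaults to 1 inside the mask, 0 outside.
#' @param mask logical array `(nx, ny, nz)`: the lumen. Out-of-mask voxels
#'   carry zero velocity by convention.
#' @param venc velocity-encoding limit in cm/s.
#' @param cycle_fraction fraction of the cardiac cycle covered, in (0, 1].
#' @return an object of class `velocity_series`.
#' @export
velocity_series <- function(grid, velocity, magnitude = NULL, mask = NULL,
                            venc = 150, cycle_fraction = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  dv <- c(grid$shape, grid$n_frames, 3L)
  if (!identical(as.integer(unname(dim(velocity))), as.integer(dv)))
    stop("velocity must have dim (nx, ny, nz, n_frames, 3)")
  if (!all(is.finite(velocity))) stop("velocity must be finite everywhere")
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  storage.mode(mask) <- "logical"
  if (is.null(magnitude)) {
    magnitude <- array(rep(as.numeric(mask), grid$n_frames),
                       c(grid$shape, grid$n_frames))
  }
  if (!identical(as.integer(unname(dim(magnitude))),
                 as.integer(c(grid$shape, grid$n_frames))))
    stop("magnitude must have dim (nx, ny, nz, n_frames)")
  if (any(magnitude < 0)) stop("magnitude must be nonnegative")
  if (!(cycle_fraction > 0 && cycle_fraction <= 1))
    stop("cycle_fraction must be in (0, 1]")
  structure(list(grid = grid, velocity = velocity, magnitude = magnitude,
                 mask = mask, venc = as.numeric(venc),
                 cycle_fraction = as.numeric(cycle_fraction)),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat("velocity_series\n")
  print(x$grid)
  cat(sprintf("  lumen voxels: %d | venc: %.3g cm/s | cycle fraction: %.3g\n",
              sum(x$mask), x$venc, x$cycle_fraction))
  cat(sprintf("  speed range in lumen: %.4g .. %.4g m/s\n",
              suppressWarnings(min(speed_map(x))),
              suppressWarnings(max(speed_map(x)))))
  invisible(x)
}

#' Voxel-wise speed (velocity magnitude) per frame
#'
#' @param series a [velocity_series()].
#' @return numeric array `(nx, ny, nz, n_frames)`, m/s.
#' @export
speed_map <- function(series) {
  d4 <- c(series$grid$shape, series$grid$n_frames)
  v <- series$velocity
  s <- sqrt(array(v[, , , , 1], d4)^2 + array(v[, , , , 2], d4)^2 +
            array(v[, , , , 3], d4)^2)
  dim(s) <- d4
  s
}

# Sample the velocity field (m/s) at world points and a time (s), with
# trilinear spatial interpolation and linear temporal interpolation between
# frames. Time wraps periodically over the cardiac cycle. Returns n x 3.
velocity_at <- function(series, pts_mm, t_s) {
  g <- series$grid
  idx <- world_to_index(g, pts_mm)
  nt <- g$n_frames
  if (nt == 1L) {
    k0 <- 1L; k1 <- 1L; w <- 0
  } else {
    total <- cycle_duration_s(g)
    tau <- t_s %% total
    fk <- tau / (g$frame_duration * 1e-3)
    k0 <- (floor(fk) %% nt) + 1L
    k1 <- (k0 %% nt) + 1L
    w <- fk - floor(fk)
  }
  out <- matrix(0, nrow(idx), 3)
  for (comp in 1:3) {
    v0 <- interp_trilinear(series$velocity[, , , k0, comp], idx)
    if (w > 0) {
      v1 <- interp_trilinear(series$velocity[, , , k1, comp], idx)
      out[, comp] <- (1 - w) * v0 + w * v1
    } else out[, comp] <- v0
  }
  out
}

# TRUE where the nearest voxel of each point is inside the lumen (and grid)
inside_lumen <- function(series, pts_mm) {
  g <- series$grid
  idx <- round(world_to_index(g, pts_mm))
  ok <- idx[, 1] >= 1 & idx[, 1] <= g$shape[1] &
        idx[, 2] >= 1 & idx[, 2] <= g$shape[2] &
        idx[, 3] >= 1 & idx[, 3] <= g$shape[3]
  res <- rep(FALSE, nrow(idx))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * g$shape[1] * g$shape[2] +
           (idx[ok, 2] - 1) * g$shape[1] + idx[ok, 1]
    res[ok] <- series$mask[lin]
  }
  res
}
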