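#' Regular acquisition grid
#'
#' Describes the spatial and temporal sampling of a 4D flow dataset: voxel
#' counts, voxel spacing in mm, number of cardiac frames and the frame
#' duration in ms. World coordinates are in mm; the centre of voxel
#' `(i, j, k)` (1-based) sits at `origin + (i - 1, j - 1, k - 1) * spacing`.
#'
#' @param shape integer vector `(nx, ny, nz)`.
#' @param spacing voxel edge lengths in mm, length 3.
#' @param n_frames number of cardiac frames (>= 1).
#' @param frame_duration duration of one frame in ms.
#' @param origin world coordinate (mm) of the centre of voxel (1, 1, 1).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, n_frames = 1L, frame_duration = 50,
                      origin = c(0, 0, 0)) {
  shape <- as.integer(unname(shape))
  spacing <- unname(spacing)
  origin <- unname(origin)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            n_frames >= 1L, frame_duration > 0,
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 n_frames = as.integer(n_frames),
                 frame_duration = as.numeric(frame_duration),
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d frame(s) x %.3g ms\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$n_frames, x$frame_duration))
  invisible(x)
}

#' World-coordinate axes of a grid
#'
#' @param grid a [grid_spec()].
#' @return list with numeric vectors `x`, `y`, `z` (mm, voxel centres).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

#' Voxel volume in cubic metres
#' @param grid a [grid_spec()].
#' @export
voxel_volume_m3 <- function(grid) prod(grid$spacing * 1e-3)

#' Frame onset times in seconds
#' @param grid a [grid_spec()].
#' @export
frame_times_s <- function(grid) {
  (seq_len(grid$n_frames) - 1) * grid$frame_duration * 1e-3
}

#' Cardiac cycle duration implied by the grid, in seconds
#' @param grid a [grid_spec()].
#' @export
cycle_duration_s <- function(grid) grid$n_frames * grid$frame_duration * 1e-3

# mm world coordinates -> continuous 1-based voxel indices
world_to_index <- function(grid, pts) {
  pts <- rbind(pts)
  cbind((pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1,
        (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1,
        (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1)
}

index_to_world <- function(grid, idx) {
  idx <- rbind(idx)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}

# full 3-D arrays of world coordinates (used by offset models and phantoms)
coord_arrays <- function(grid) {
  ax <- grid_axes(grid)
  d <- grid$shape
  list(x = array(rep(ax$x, times = d[2] * d[3]), d),
       y = array(rep(rep(ax$y, each = d[1]), times = d[3]), d),
       z = array(rep(ax$z, each = d[1] * d[2]), d))
}
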