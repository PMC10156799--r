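#' Write a velocity series as NIfTI volumes plus a JSON sidecar
#'
#' Layout: `<prefix>_velocity.nii.gz` (5-D: x, y, z, frame, component, m/s),
#' `<prefix>_magnitude.nii.gz` (4-D), `<prefix>_mask.nii.gz` (3-D labels or
#' lumen), and `<prefix>.json` holding the acquisition metadata (venc,
#' frame duration, cycle fraction, origin).
#'
#' @param series a [velocity_series()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"flow"`).
#' @param labels optional integer label volume written instead of the
#'   logical mask.
#' @return the sidecar path, invisibly.
#' @export
write_flow_series <- function(series, dir, prefix = "flow", labels = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- series$grid
  pd <- g$spacing
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, c(pd, rep(1, length(dim(arr)) - 3L)))
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz",
                                                   prefix, name)))
  }
  wr(series$velocity, "velocity")
  wr(series$magnitude, "magnitude")
  wr(if (is.null(labels)) array(as.integer(series$mask), g$shape)
     else labels, "mask")
  meta <- list(venc_cms = series$venc,
               frame_duration_ms = g$frame_duration,
               n_frames = g$n_frames,
               cycle_fraction = series$cycle_fraction,
               spacing_mm = g$spacing,
               origin_mm = g$origin)
  side <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a velocity series written by [write_flow_series()]
#'
#' @param dir directory containing the files.
#' @param prefix file name prefix.
#' @return list: `series` (a [velocity_series()]), `labels` (the stored
#'   mask volume as integers).
#' @export
read_flow_series <- function(dir, prefix = "flow") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz",
                                                    prefix, name)))
    a <- as.array(img)
    array(as.vector(a), dim(a))   # drop NIfTI attributes
  }
  vel <- rd("velocity")
  mag <- rd("magnitude")
  lab <- rd("mask")
  storage.mode(lab) <- "integer"
  grid <- grid_spec(dim(vel)[1:3], meta$spacing_mm, meta$n_frames,
                    meta$frame_duration_ms, meta$origin_mm)
  series <- velocity_series(grid, vel, magnitude = mag, mask = lab > 0L,
                            venc = meta$venc_cms,
                            cycle_fraction = meta$cycle_fraction)
  list(series = series, labels = lab)
}

#' Export pathlines as CSV
#'
#' Long format: one row per trajectory point with columns
#' `trajectory`, `t`, `x`, `y`, `z`.
#'
#' @param pathlines a `pathline_set`.
#' @param path output CSV path.
#' @export
write_pathlines_csv <- function(pathlines, path) {
  traj <- pathlines$trajectories
  n <- dim(traj)[1]; ns <- dim(traj)[2]
  id <- rep(seq_len(n), ns)
  tt <- rep(pathlines$times, each = n)
  df <- data.frame(trajectory = id, t = tt,
                   x = as.vector(traj[, , 1]),
                   y = as.vector(traj[, , 2]),
                   z = as.vector(traj[, , 3]))
  df <- df[complete.cases(df), ]
  df <- df[order(df$trajectory, df$t), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export pathlines as legacy VTK polydata
#'
#' ASCII VTK with one polyline per trajectory and the per-point time as a
#' scalar field, loadable in ParaView and similar viewers.
#'
#' @param pathlines a `pathline_set`.
#' @param path output `.vtk` path.
#' @export
write_pathlines_vtk <- function(pathlines, path) {
  traj <- pathlines$trajectories
  n <- dim(traj)[1]
  pts <- list(); times <- list(); lines <- list()
  offset <- 0L
  for (i in seq_len(n)) {
    np <- pathlines$n_points[i]
    pts[[i]] <- cbind(traj[i, seq_len(np), 1],
                      traj[i, seq_len(np), 2],
                      traj[i, seq_len(np), 3])
    times[[i]] <- pathlines$times[seq_len(np)]
    lines[[i]] <- c(np, offset + seq_len(np) - 1L)
    offset <- offset + np
  }
  allp <- do.call(rbind, pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pathlines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(allp))), con)
  utils::write.table(format(allp, scientific = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  sizes <- vapply(lines, length, 0L)
  writeLines(sprintf("LINES %d %d", n, sum(sizes)), con)
  for (l in lines) writeLines(paste(l, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(allp)),
               "SCALARS time float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(unlist(times), scientific = TRUE, digits = 7),
                   collapse = " "), con)
  invisible(path)
}

#' Serialize a flow-distribution result to JSON
#' @param result a `flow_distribution_result`.
#' @param path output path.
#' @export
write_flow_distribution_json <- function(result, path) {
  jsonlite::write_json(
    list(n_lpa = result$n_lpa, n_rpa = result$n_rpa,
         fraction_lpa = result$fraction_lpa,
         fraction_rpa = result$fraction_rpa,
         classification = result$classification,
         validity_fraction = result$validity_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
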