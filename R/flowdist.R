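#' Seed pathline emitters in a caval region
#'
#' Quasi-uniform jittered-grid sampling of the chosen source region (IVC or
#' SVC) at the requested volumetric density. A regular lattice with pitch
#' `(1000 / density)^(1/3)` mm is jittered uniformly by up to half a pitch
#' per axis and points falling outside the source label are discarded, so
#' the achieved density matches the request up to boundary effects.
#'
#' @param regions a [region_model()].
#' @param source `"IVC"` or `"SVC"`.
#' @param density emitters per cm^3 (default 30).
#' @param seed integer seed for the jitter.
#' @return list of class `emitter_set`: `positions` (n x 3 mm),
#'   `source_label`, `density_requested`, `density_achieved`.
#' @export
seed_emitters <- function(regions, source = c("IVC", "SVC"), density = 30,
                          seed = 1L) {
  source <- match.arg(source)
  lab <- region_names()[[source]]
  sel <- regions$labels == lab
  if (!any(sel)) stop(sprintf("source region %s is empty", source))
  if (density <= 0) {
    return(structure(list(positions = matrix(numeric(0), 0, 3),
                          source_label = source,
                          density_requested = density,
                          density_achieved = 0),
                     class = "emitter_set"))
  }
  g <- regions$grid
  vox <- which(sel)
  pts <- index_to_world(g, arrayInd(vox, dim(sel)))
  lo <- apply(pts, 2, min) - g$spacing / 2
  hi <- apply(pts, 2, max) + g$spacing / 2
  pitch <- (1000 / density)^(1 / 3)
  pos <- with_private_seed(seed, function() {
    ax <- lapply(1:3, function(a) {
      n <- max(1L, ceiling((hi[a] - lo[a]) / pitch))
      # lattice centred on the region bounding box, so a symmetric region
      # is sampled symmetrically
      (lo[a] + hi[a]) / 2 + (seq_len(n) - (n + 1) / 2) * pitch
    })
    lattice <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    lattice + matrix(runif(length(lattice), -pitch / 2, pitch / 2),
                     ncol = 3)
  })
  idx <- round(world_to_index(g, pos))
  ok <- idx[, 1] >= 1 & idx[, 1] <= dim(sel)[1] &
        idx[, 2] >= 1 & idx[, 2] <= dim(sel)[2] &
        idx[, 3] >= 1 & idx[, 3] <= dim(sel)[3]
  keep <- rep(FALSE, nrow(pos))
  lin <- (idx[ok, 3] - 1) * prod(dim(sel)[1:2]) +
    (idx[ok, 2] - 1) * dim(sel)[1] + idx[ok, 1]
  keep[ok] <- sel[lin]
  pos <- pos[keep, , drop = FALSE]
  vol_cm3 <- sum(sel) * prod(g$spacing) / 1000
  structure(list(positions = pos, source_label = source,
                 density_requested = density,
                 density_achieved = nrow(pos) / vol_cm3),
            class = "emitter_set")
}

#' Trace pathlines through a time-resolved velocity field
#'
#' Integrates `dx/dt = V(x, t)` with classical 4th-order Runge-Kutta,
#' trilinear spatial interpolation and linear temporal interpolation between
#' frames; time wraps periodically over the cardiac cycle. All emitters are
#' released at `t = 0`. A trajectory terminates when it leaves the lumen,
#' when its local speed stays below 1e-3 m/s for 5 consecutive steps, when
#' it crosses one of the supplied entrance planes, or after `max_cycles`
#' cardiac cycles.
#'
#' @param series a [velocity_series()].
#' @param emitters an `emitter_set` from [seed_emitters()], or an n x 3
#'   matrix of mm seed points.
#' @param dt integration step in ms; default `frame_duration / 5`.
#' @param max_cycles integration horizon in cardiac cycles (default 3).
#' @param entrance_planes optional list of [analysis_plane()]s with roles
#'   `LPA_entrance` / `RPA_entrance`; crossing one terminates a trajectory.
#' @return list of class `pathline_set`: `trajectories` (n x steps x 3 array
#'   with NA after termination), `times` (s), `n_points` per trajectory,
#'   `termination` (factor: left_mask / low_velocity / crossed_plane /
#'   max_time), `first_plane` (LPA / RPA / none), `source_label`.
#' @export
trace_pathlines <- function(series, emitters, dt = NULL, max_cycles = 3L,
                            entrance_planes = NULL) {
  g <- series$grid
  if (inherits(emitters, "emitter_set")) {
    pos <- emitters$positions
    src <- emitters$source_label
  } else {
    pos <- rbind(emitters)
    src <- NA_character_
  }
  if (!nrow(pos)) stop("no emitters to trace")
  if (is.null(dt)) dt <- g$frame_duration / 5
  stopifnot(dt > 0, dt <= g$frame_duration, max_cycles >= 1)
  if (!all(inside_lumen(series, pos)))
    stop("an emitter lies outside the lumen at t = 0")
  dt_s <- dt * 1e-3
  n_steps <- ceiling(max_cycles * cycle_duration_s(g) / dt_s)
  n <- nrow(pos)

  # cache per-frame component volumes once (5-D slicing is costly in-loop)
  vols <- vector("list", g$n_frames)
  for (k in seq_len(g$n_frames)) {
    vols[[k]] <- lapply(1:3, function(comp)
      array(series$velocity[, , , k, comp], g$shape))
  }
  vel_at <- function(p, t_s) {
    idx <- world_to_index(g, p)
    nt <- g$n_frames
    if (nt == 1L) { k0 <- 1L; k1 <- 1L; w <- 0 } else {
      fk <- (t_s %% cycle_duration_s(g)) / (g$frame_duration * 1e-3)
      k0 <- (floor(fk) %% nt) + 1L
      k1 <- (k0 %% nt) + 1L
      w <- fk - floor(fk)
    }
    out <- matrix(0, nrow(p), 3)
    for (comp in 1:3) {
      v0 <- interp_trilinear(vols[[k0]][[comp]], idx)
      out[, comp] <- if (w > 0)
        (1 - w) * v0 + w * interp_trilinear(vols[[k1]][[comp]], idx)
      else v0
    }
    out
  }

  traj <- array(NA_real_, c(n, n_steps + 1L, 3L))
  traj[, 1, ] <- pos
  alive <- rep(TRUE, n)
  slow_run <- integer(n)
  term <- rep(NA_character_, n)
  first_plane <- rep("none", n)
  n_points <- rep(1L, n)

  plane_sd <- function(pl, p) plane_coords(pl, p)$signed
  if (!is.null(entrance_planes)) {
    sd_prev <- lapply(entrance_planes, function(pl) plane_sd(pl, pos))
  }

  p_cur <- pos
  for (step in seq_len(n_steps)) {
    if (!any(alive)) break
    t0 <- (step - 1L) * dt_s
    ia <- which(alive)
    p <- p_cur[ia, , drop = FALSE]
    k1 <- vel_at(p, t0) * 1e3                     # m/s -> mm/s
    k2 <- vel_at(p + dt_s / 2 * k1, t0 + dt_s / 2) * 1e3
    k3 <- vel_at(p + dt_s / 2 * k2, t0 + dt_s / 2) * 1e3
    k4 <- vel_at(p + dt_s * k3, t0 + dt_s) * 1e3
    p_new <- p + dt_s / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

    speed0 <- sqrt(rowSums((k1 * 1e-3)^2))
    slow_run[ia] <- ifelse(speed0 < 1e-3, slow_run[ia] + 1L, 0L)

    inl <- inside_lumen(series, p_new)
    # plane crossings between p and p_new (only within the plane radius)
    crossed <- rep(NA_character_, length(ia))
    if (!is.null(entrance_planes)) {
      for (pi in seq_along(entrance_planes)) {
        pl <- entrance_planes[[pi]]
        sd0 <- sd_prev[[pi]][ia]
        sd1 <- plane_sd(pl, p_new)
        hit <- is.na(crossed) & (sign(sd0) != sign(sd1)) & sd0 != sd1
        if (any(hit)) {
          f <- sd0[hit] / (sd0[hit] - sd1[hit])
          xing <- p[hit, , drop = FALSE] +
            f * (p_new[hit, , drop = FALSE] - p[hit, , drop = FALSE])
          lat <- plane_coords(pl, xing)$lateral
          ok <- lat <= pl$in_plane_radius
          which_hit <- which(hit)[ok]
          crossed[which_hit] <-
            if (pl$role == "LPA_entrance") "LPA"
            else if (pl$role == "RPA_entrance") "RPA" else "boundary"
        }
        sd_prev[[pi]][ia] <- sd1
      }
    }

    traj[cbind(rep(ia, 3), step + 1L, rep(1:3, each = length(ia)))] <-
      as.vector(p_new)
    n_points[ia] <- step + 1L
    p_cur[ia, ] <- p_new

    done_plane <- !is.na(crossed) & crossed %in% c("LPA", "RPA")
    done_mask <- !inl & !done_plane
    done_slow <- slow_run[ia] >= 5L & !done_plane & !done_mask
    term[ia[done_plane]] <- "crossed_plane"
    first_plane[ia[done_plane]] <- crossed[done_plane]
    term[ia[done_mask]] <- "left_mask"
    term[ia[done_slow]] <- "low_velocity"
    alive[ia[done_plane | done_mask | done_slow]] <- FALSE
  }
  term[is.na(term)] <- "max_time"
  structure(list(
    trajectories = traj[, seq_len(max(n_points)), , drop = FALSE],
    times = (seq_len(max(n_points)) - 1L) * dt_s,
    n_points = n_points,
    termination = factor(term, levels = c("left_mask", "low_velocity",
                                          "crossed_plane", "max_time")),
    first_plane = factor(first_plane, levels = c("LPA", "RPA", "none")),
    source_label = src),
    class = "pathline_set")
}

#' Count pathline entries into the pulmonary arteries
#'
#' Scans each trajectory for sign changes of the signed distance to the LPA
#' and RPA entrance planes, with the interpolated crossing point required to
#' fall within the plane radius. Only the first plane crossed counts per
#' pathline. The validity fraction is the share of pathlines with more than
#' 3 time points that reach either plane.
#'
#' @param pathlines a `pathline_set`.
#' @param lpa_plane,rpa_plane [analysis_plane()]s with matching roles.
#' @return list of class `flow_distribution_result` with counts `n_lpa`,
#'   `n_rpa`, `validity_fraction` (fractions filled by
#'   [flow_distribution()]).
#' @export
count_crossings <- function(pathlines, lpa_plane, rpa_plane) {
  stopifnot(lpa_plane$role == "LPA_entrance",
            rpa_plane$role == "RPA_entrance")
  traj <- pathlines$trajectories
  n <- dim(traj)[1]
  first <- rep("none", n)
  first_step <- rep(Inf, n)
  for (which_pl in 1:2) {
    pl <- if (which_pl == 1L) lpa_plane else rpa_plane
    nm <- if (which_pl == 1L) "LPA" else "RPA"
    # signed distance for all points of all trajectories at once
    ns_all <- dim(traj)[2]
    rel1 <- matrix(traj[, , 1], n, ns_all) - pl$origin[1]
    rel2 <- matrix(traj[, , 2], n, ns_all) - pl$origin[2]
    rel3 <- matrix(traj[, , 3], n, ns_all) - pl$origin[3]
    sd <- rel1 * pl$normal[1] + rel2 * pl$normal[2] + rel3 * pl$normal[3]
    ns <- ncol(sd)
    s0 <- sd[, -ns, drop = FALSE]
    s1 <- sd[, -1, drop = FALSE]
    flip <- !is.na(s0) & !is.na(s1) & (sign(s0) != sign(s1)) & (s0 != s1)
    if (!any(flip)) next
    hits <- which(flip, arr.ind = TRUE)
    f <- s0[flip] / (s0[flip] - s1[flip])
    p0 <- cbind(traj[cbind(hits[, 1], hits[, 2], 1)],
                traj[cbind(hits[, 1], hits[, 2], 2)],
                traj[cbind(hits[, 1], hits[, 2], 3)])
    p1 <- cbind(traj[cbind(hits[, 1], hits[, 2] + 1L, 1)],
                traj[cbind(hits[, 1], hits[, 2] + 1L, 2)],
                traj[cbind(hits[, 1], hits[, 2] + 1L, 3)])
    xing <- p0 + f * (p1 - p0)
    lat <- plane_coords(pl, xing)$lateral
    ok <- lat <= pl$in_plane_radius
    if (!any(ok)) next
    hi <- hits[ok, , drop = FALSE]
    # earliest in-radius crossing per trajectory for this plane
    ord <- order(hi[, 1], hi[, 2])
    hi <- hi[ord, , drop = FALSE]
    first_of <- !duplicated(hi[, 1])
    for (r in which(first_of)) {
      id <- hi[r, 1]; st <- hi[r, 2]
      if (st < first_step[id]) {
        first_step[id] <- st
        first[id] <- nm
      }
    }
  }
  many <- pathlines$n_points > 3L
  validity <- if (any(many)) mean(first[many] != "none") else NA_real_
  structure(list(n_lpa = sum(first == "LPA"), n_rpa = sum(first == "RPA"),
                 first_plane = factor(first, levels = c("LPA", "RPA", "none")),
                 fraction_lpa = NA_real_, fraction_rpa = NA_real_,
                 classification = NA_character_,
                 validity_fraction = validity),
            class = "flow_distribution_result")
}

#' Caval flow distribution from crossing counts
#'
#' `fraction_lpa = n_lpa / (n_lpa + n_rpa)` and its complement. Unequal
#' flow distribution is defined as strictly less than 30% or strictly more
#' than 70% of flow to the LPA; the boundary values classify as equal.
#'
#' @param counts a `flow_distribution_result` from [count_crossings()].
#' @return the input with `fraction_lpa`, `fraction_rpa` and
#'   `classification` (`"equal"` / `"unequal"`) filled in.
#' @export
flow_distribution <- function(counts) {
  tot <- counts$n_lpa + counts$n_rpa
  if (tot == 0) {
    warning("no pathline reached either plane; fractions undefined")
    counts$classification <- NA_character_
    return(counts)
  }
  counts$fraction_lpa <- counts$n_lpa / tot
  counts$fraction_rpa <- counts$n_rpa / tot
  counts$classification <-
    if (counts$fraction_lpa < 0.30 || counts$fraction_lpa > 0.70)
      "unequal" else "equal"
  counts
}

#' @export
print.flow_distribution_result <- function(x, ...) {
  cat(sprintf(
    "flow distribution: LPA %d / RPA %d  (LPA fraction %.3f, %s; validity %.2f)\n",
    x$n_lpa, x$n_rpa, x$fraction_lpa, x$classification %||% "n/a",
    x$validity_fraction))
  invisible(x)
}
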