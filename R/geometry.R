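#' Analysis plane
#'
#' An oriented 2-D plane with a finite in-plane radius, used both to bound
#' 3-D regions of interest along vessel centerlines and to count pathline
#' entries into the pulmonary arteries.
#'
#' @param origin mm point on the plane.
#' @param normal direction vector (normalised internally).
#' @param in_plane_radius mm; crossings and cuts are only counted within
#'   this radius of the origin.
#' @param role one of `"LPA_entrance"`, `"RPA_entrance"`, `"region_boundary"`.
#' @export
analysis_plane <- function(origin, normal, in_plane_radius,
                           role = c("region_boundary", "LPA_entrance",
                                    "RPA_entrance")) {
  role <- match.arg(role)
  nrm <- sqrt(sum(normal^2))
  stopifnot(nrm > 0, in_plane_radius > 0, length(origin) == 3)
  structure(list(origin = as.numeric(origin),
                 normal = as.numeric(normal) / nrm,
                 in_plane_radius = as.numeric(in_plane_radius),
                 role = role),
            class = "analysis_plane")
}

# signed distance (mm) of points to a plane, and lateral in-plane offset
plane_coords <- function(plane, pts) {
  pts <- rbind(pts)
  rel <- sweep(pts, 2, plane$origin)
  sd <- as.vector(rel %*% plane$normal)
  lat2 <- rowSums(rel^2) - sd^2
  lat2[lat2 < 0] <- 0
  list(signed = sd, lateral = sqrt(lat2))
}

#' Region model of the total cavopulmonary connection
#'
#' A labelled partition of the lumen into the five regions
#' (1 = IVC, 2 = SVC, 3 = connection, 4 = LPA, 5 = RPA), together with the
#' limb centerlines and the boundary planes that delimit them.
#'
#' @param labels integer volume, 0 = background.
#' @param grid the [grid_spec()] the labels live on.
#' @param centerlines named list of centerlines (see [extract_centerline()]).
#' @param boundary_planes named list of [analysis_plane()]s.
#' @export
region_model <- function(labels, grid, centerlines = list(),
                         boundary_planes = list()) {
  stopifnot(identical(dim(labels), as.integer(grid$shape)))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 5L)) stop("labels must be in 0..5")
  structure(list(labels = labels, grid = grid, centerlines = centerlines,
                 boundary_planes = boundary_planes),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  nm <- region_names()
  cnt <- tabulate(x$labels[x$labels > 0], 5L)
  cat("region_model:",
      paste(sprintf("%s=%d", nm, cnt), collapse = " "), "voxels\n")
  invisible(x)
}

#' Region label dictionary
#' @return named integer vector mapping region names to label values.
#' @export
region_names <- function() {
  c(IVC = 1L, SVC = 2L, connection = 3L, LPA = 4L, RPA = 5L)
}

#' Region volumes in cm^3
#' @param regions a [region_model()].
#' @export
region_volumes_cm3 <- function(regions) {
  vvox_cm3 <- prod(regions$grid$spacing) / 1000
  cnt <- tabulate(regions$labels[regions$labels > 0], 5L)
  stats::setNames(cnt * vvox_cm3, names(region_names()))
}

# City-block distance (mm) to the mask boundary by iterative min-plus
# propagation; out-of-mask voxels are 0. Used as a medial-ridge weight.
distance_to_wall <- function(mask, spacing) {
  d <- array(ifelse(mask, Inf, 0), dim(mask))
  repeat {
    d_old <- d
    for (axis in 1:3) {
      d <- pmin(d, shift_array(d, axis, 1L) + spacing[axis])
      d <- pmin(d, shift_array(d, axis, -1L) + spacing[axis])
    }
    if (all(d == d_old)) break
  }
  array(d, dim(mask))
}

# compact voxel graph over a logical mask; 26-connectivity when weighted
# (centerlines), 6-connectivity otherwise (components). Returns igraph plus
# the voxel linear indices in graph-vertex order.
mask_graph <- function(mask, spacing, weighted = FALSE, dist = NULL) {
  d <- dim(mask)
  ids <- array(0L, d)
  vox <- which(mask)
  ids[vox] <- seq_along(vox)
  offs <- if (weighted) {
    o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
    # half of the 26 neighbours (undirected edges once)
    o[o$dz > 0 | (o$dz == 0 & (o$dy > 0 | (o$dy == 0 & o$dx > 0))), ]
  } else {
    data.frame(dx = c(1, 0, 0), dy = c(0, 1, 0), dz = c(0, 0, 1))
  }
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    off <- as.integer(offs[r, ])
    nb <- ids
    for (axis in 1:3) if (off[axis] != 0) nb <- shift_array(nb, axis, off[axis])
    # shift_array replicates edges; suppress wrapped pairs at grid borders
    for (axis in 1:3) {
      if (off[axis] > 0) {
        idx <- lapply(d, seq_len); idx[[axis]] <- d[axis]
        eval_border <- do.call(`[<-`, c(list(array(FALSE, d)), idx, list(TRUE)))
        nb[eval_border] <- 0L
      } else if (off[axis] < 0) {
        idx <- lapply(d, seq_len); idx[[axis]] <- 1L
        eval_border <- do.call(`[<-`, c(list(array(FALSE, d)), idx, list(TRUE)))
        nb[eval_border] <- 0L
      }
    }
    sel <- ids > 0L & nb > 0L
    if (!any(sel)) next
    f <- ids[sel]; t2 <- nb[sel]
    from <- c(from, f); to <- c(to, t2)
    if (weighted) {
      step_len <- sqrt(sum((off * spacing)^2))
      dd <- (dist[vox[f]] + dist[vox[t2]]) / 2
      w <- c(w, step_len / (0.25 + dd)^2)
    }
  }
  gph <- igraph::make_undirected_graph(as.vector(rbind(from, to)),
                                       n = length(vox))
  if (weighted) igraph::E(gph)$weight <- w
  list(graph = gph, voxels = vox)
}

#' Extract a vessel centerline between two endpoints
#'
#' Finds the medial path through a tubular mask: a shortest path on the
#' voxel adjacency graph whose edge costs divide step length by the squared
#' distance-to-wall, so the optimum runs along the medial (skeleton) ridge.
#' The raw voxel path is smoothed with a moving average (window 5) and
#' resampled at 1 mm arclength.
#'
#' @param mask logical lumen volume.
#' @param grid the [grid_spec()].
#' @param endpoints 2 x 3 matrix of mm points inside the mask.
#' @return list of class `centerline`: `points` (n x 3 mm), `arclength`
#'   (mm, strictly increasing), `tangents` (n x 3 unit vectors).
#' @export
extract_centerline <- function(mask, grid, endpoints) {
  endpoints <- rbind(endpoints)
  stopifnot(nrow(endpoints) == 2L)
  dtw <- distance_to_wall(mask, grid$spacing)
  mg <- mask_graph(mask, grid$spacing, weighted = TRUE, dist = dtw)
  # snap each endpoint to its nearest in-mask voxel; among near-ties
  # (within half a voxel) prefer the deeper, more medial one. Endpoints at
  # open vessel ends must not drift inward, so proximity dominates.
  snap <- function(p) {
    idx <- round(world_to_index(grid, p))
    if (any(idx < 1) || any(idx > grid$shape) ||
        !mask[idx[1], idx[2], idx[3]])
      stop("centerline endpoint lies outside the mask")
    rng <- lapply(1:3, function(a) {
      pmax(1L, idx[a] - 2L):pmin(grid$shape[a], idx[a] + 2L)
    })
    sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    lin <- (sub[, 3] - 1) * prod(grid$shape[1:2]) +
      (sub[, 2] - 1) * grid$shape[1] + sub[, 1]
    keep <- mask[lin]
    lin <- lin[keep]; sub <- sub[keep, , drop = FALSE]
    dist <- sqrt(rowSums(sweep(index_to_world(grid, sub), 2, p)^2))
    cand <- dist <= min(dist) + max(grid$spacing) / 2
    lin[cand][which.max(dtw[lin[cand]])]
  }
  v_from <- match(snap(endpoints[1, ]), mg$voxels)
  v_to <- match(snap(endpoints[2, ]), mg$voxels)
  sp <- igraph::shortest_paths(mg$graph, v_from, v_to, output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  if (!length(vp)) stop("mask is disconnected between the endpoints")
  lin <- mg$voxels[vp]
  d <- grid$shape
  k <- (lin - 1) %/% (d[1] * d[2]) + 1
  rem <- (lin - 1) %% (d[1] * d[2])
  j <- rem %/% d[1] + 1
  i <- rem %% d[1] + 1
  pts <- index_to_world(grid, cbind(i, j, k))
  centerline_from_points(pts)
}

# smooth (moving average, window 5) and resample a polyline at 1 mm
centerline_from_points <- function(pts, window = 5L, step = 1) {
  if (nrow(pts) >= window) {
    kern <- rep(1 / window, window)
    sm <- apply(pts, 2, function(col) {
      f <- stats::filter(col, kern, sides = 2)
      f[is.na(f)] <- col[is.na(f)]  # keep endpoints
      as.numeric(f)
    })
  } else sm <- pts
  seglen <- sqrt(rowSums(diff(sm)^2))
  keep <- c(TRUE, seglen > 1e-9)
  sm <- sm[keep, , drop = FALSE]
  if (nrow(sm) < 2L) stop("degenerate centerline")
  arc <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
  s_new <- seq(0, max(arc), by = step)
  if (max(s_new) < max(arc)) s_new <- c(s_new, max(arc))
  res <- sapply(1:3, function(a) stats::approx(arc, sm[, a], xout = s_new)$y)
  tans <- rbind(res[2, ] - res[1, ],
                (res[-(1:2), , drop = FALSE] -
                   res[seq_len(nrow(res) - 2), , drop = FALSE]) / 2,
                res[nrow(res), ] - res[nrow(res) - 1, ])
  tans <- tans / sqrt(rowSums(tans^2))
  structure(list(points = res, arclength = s_new, tangents = tans),
            class = "centerline")
}

#' Place an analysis plane on a centerline
#'
#' The plane origin is the centerline point at the requested arclength, the
#' normal is the local tangent, and the in-plane radius covers the lumen
#' cross-section with a 2 mm margin.
#'
#' @param centerline a `centerline` from [extract_centerline()].
#' @param arclength mm position along the centerline.
#' @param mask logical lumen volume.
#' @param grid the [grid_spec()].
#' @param role passed to [analysis_plane()].
#' @export
place_plane <- function(centerline, arclength, mask, grid,
                        role = "region_boundary") {
  rng <- range(centerline$arclength)
  if (arclength < rng[1] || arclength > rng[2])
    stop("arclength outside the centerline range")
  origin <- sapply(1:3, function(a)
    stats::approx(centerline$arclength, centerline$points[, a],
                  xout = arclength)$y)
  i <- which.min(abs(centerline$arclength - arclength))
  normal <- centerline$tangents[i, ]
  vox <- which(mask)
  pts <- index_to_world(grid, arrayInd(vox, dim(mask)))
  pc <- plane_coords(analysis_plane(origin, normal, 1e6, role), pts)
  in_plane <- abs(pc$signed) <= max(grid$spacing) / 2
  radius <- if (any(in_plane)) max(pc$lateral[in_plane]) + 2 else
    max(grid$spacing) + 2
  analysis_plane(origin, normal, radius, role)
}

#' Partition a lumen mask into labelled regions
#'
#' Cuts the mask along each boundary plane (a one-voxel-thick slab on the
#' far side of the plane, within its in-plane radius, so distant limbs are
#' not severed), labels the resulting connected components by the region
#' seed each contains, and finally assigns the cut-band voxels to the
#' nearest labelled neighbour with ties resolved towards the connection
#' region. Every lumen voxel receives exactly one label.
#'
#' @param mask logical lumen volume.
#' @param grid the [grid_spec()].
#' @param boundary_planes list of [analysis_plane()]s whose normals point
#'   away from the connection.
#' @param seeds named list of mm points, names from
#'   `names(region_names())`.
#' @param centerlines optional named centerline list stored in the result.
#' @return a [region_model()].
#' @export
partition_regions <- function(mask, grid, boundary_planes, seeds,
                              centerlines = list()) {
  if (!length(boundary_planes)) stop("at least one boundary plane required")
  rn <- region_names()
  if (!all(names(seeds) %in% names(rn))) stop("unknown region seed name")
  d <- dim(mask)
  vox <- which(mask)
  pts <- index_to_world(grid, arrayInd(vox, d))
  cut <- rep(FALSE, length(vox))
  thick <- max(grid$spacing) * 1.01
  for (pl in boundary_planes) {
    pc <- plane_coords(pl, pts)
    cut <- cut | (pc$signed > 0 & pc$signed <= thick &
                    pc$lateral <= pl$in_plane_radius)
  }
  keep <- array(FALSE, d)
  keep[vox[!cut]] <- TRUE
  mg <- mask_graph(keep, grid$spacing, weighted = FALSE)
  comp <- igraph::components(mg$graph)$membership
  comp_of <- array(0L, d)
  comp_of[mg$voxels] <- comp
  labels <- array(0L, d)
  for (nm in names(seeds)) {
    idx <- round(world_to_index(grid, seeds[[nm]]))
    if (any(idx < 1) || any(idx > d)) stop("seed outside the grid")
    cid <- comp_of[idx[1], idx[2], idx[3]]
    if (cid == 0L)
      stop(sprintf("seed '%s' falls in a cut or background voxel", nm))
    if (any(labels[mg$voxels][comp == cid] != 0L))
      stop("two seeds fall in the same component; a plane may be missing")
    labels[mg$voxels[comp == cid]] <- rn[[nm]]
  }
  # propagate labels into the cut bands (and any unreached lumen voxels),
  # preferring the connection label on ties
  repeat {
    todo <- mask & labels == 0L
    if (!any(todo)) break
    cand <- array(0L, d)
    for (axis in 1:3) for (s in c(1L, -1L)) {
      nb <- shift_array(labels, axis, s)
      take <- todo & nb > 0L & (cand == 0L | nb == 3L)
      cand[take] <- nb[take]
    }
    hit <- todo & cand > 0L
    if (!any(hit)) stop("unlabelled lumen voxels are unreachable")
    labels[hit] <- cand[hit]
  }
  region_model(labels, grid, centerlines = centerlines,
               boundary_planes = boundary_planes)
}
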