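#' Shift an array along one axis with edge replication
#'
#' Used by the finite-difference and neighbourhood operators. Values shifted
#' in from outside the grid replicate the edge plane, so callers must combine
#' the result with a shifted validity mask when out-of-grid neighbours should
#' not contribute.
#'
#' @param a numeric or logical array.
#' @param axis axis index (1-based).
#' @param by integer shift; `by = 1` brings the neighbour at `i + 1` to `i`.
#' @return array of the same shape as `a`.
#' @keywords internal
shift_array <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + by
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Evaluate a function with a private RNG state; the caller's RNG stream is
# left untouched. All stochastic operations in the package funnel through
# this so a single integer seed makes a whole pipeline reproducible.
with_private_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Trilinear interpolation of a 3-D volume at fractional voxel indices
#'
#' @param vol 3-D numeric array.
#' @param idx n x 3 matrix of continuous 1-based voxel indices. Indices are
#'   clamped to the valid range, i.e. the volume is edge-extended.
#' @return numeric vector of length n.
#' @keywords internal
interp_trilinear <- function(vol, idx) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(idx[, 1], d[1]); y <- cl(idx[, 2], d[2]); z <- cl(idx[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  nx <- d[1]; nxy <- d[1] * d[2]
  lin <- function(i, j, k) (k - 1) * nxy + (j - 1) * nx + i
  v000 <- vol[lin(x0, y0, z0)]; v100 <- vol[lin(x1, y0, z0)]
  v010 <- vol[lin(x0, y1, z0)]; v110 <- vol[lin(x1, y1, z0)]
  v001 <- vol[lin(x0, y0, z1)]; v101 <- vol[lin(x1, y0, z1)]
  v011 <- vol[lin(x0, y1, z1)]; v111 <- vol[lin(x1, y1, z1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Row-wise median of a 6-column matrix via a sorting network (no loops over
# rows). For an even count the median is the mean of the 3rd and 4th order
# statistics.
median6 <- function(m) {
  stopifnot(ncol(m) == 6L)
  cmp <- function(i, j) {
    lo <- pmin(m[, i], m[, j]); hi <- pmax(m[, i], m[, j])
    m[, i] <<- lo; m[, j] <<- hi
  }
  # Batcher network for 6 elements
  cmp(1, 2); cmp(3, 4); cmp(5, 6)
  cmp(1, 3); cmp(2, 4)
  cmp(1, 5); cmp(2, 6)
  cmp(3, 5); cmp(4, 6)
  cmp(2, 3); cmp(4, 5)
  cmp(3, 4)
  (m[, 3] + m[, 4]) / 2
}

# Spatial polynomial design matrix over world coordinates (mm), order 1 or 2.
poly_basis <- function(xyz, order) {
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  if (order == 1L) {
    cbind(1, x, y, z)
  } else if (order == 2L) {
    cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
  } else {
    stop("polynomial order must be 1 or 2")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a logical mask with FALSE padding: out-of-grid neighbours are not
# in the mask (unlike shift_array, which replicates the edge plane).
shift_mask <- function(mask, axis, by) {
  out <- shift_array(mask, axis, by)
  d <- dim(mask)
  idx <- lapply(d, seq_len)
  if (by > 0) {
    idx[[axis]] <- (d[axis] - by + 1L):d[axis]
  } else {
    idx[[axis]] <- seq_len(-by)
  }
  do.call(`[<-`, c(list(out), idx, list(FALSE)))
}
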