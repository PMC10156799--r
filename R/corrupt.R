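#' Apply MRI-style corruptions to a velocity series
#'
#' Models the artifacts that phase-contrast preprocessing must remove:
#' additive Gaussian velocity noise, smooth spatial phase-offset errors
#' (eddy currents / Maxwell terms, modelled as a per-component polynomial in
#' world coordinates), and venc wrap-around (aliasing). Corruptions are
#' applied in that order; the wrap maps a true value `v` to
#' `v - 2 venc round(v / (2 venc))`, so stored values always lie in
#' `[-venc, venc]`.
#'
#' @param series a [velocity_series()].
#' @param noise_sd standard deviation of i.i.d. Gaussian velocity noise, m/s.
#' @param offset_coeffs `NULL`, or a list of up to 3 numeric vectors (one per
#'   component) of polynomial coefficients over the basis
#'   `1, x, y, z` (order 1) or `1, x, y, z, x^2, y^2, z^2, xy, xz, yz`
#'   (order 2), coordinates in mm, offsets in m/s.
#' @param alias logical; wrap values beyond the venc.
#' @param seed integer seed for the noise (default 1).
#' @return a list: `series` (corrupted), `n_aliased` (count of voxel values
#'   wrapped).
#' @export
corrupt <- function(series, noise_sd = 0, offset_coeffs = NULL,
                    alias = FALSE, seed = 1L) {
  stopifnot(noise_sd >= 0)
  v <- series$velocity
  d <- dim(v)
  if (noise_sd > 0) {
    noise <- with_private_seed(seed, function() rnorm(length(v), 0, noise_sd))
    v <- v + array(noise, d)
  }
  if (!is.null(offset_coeffs)) {
    co <- coord_arrays(series$grid)
    xyz <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
    for (comp in seq_along(offset_coeffs)) {
      cf <- offset_coeffs[[comp]]
      if (is.null(cf) || !length(cf)) next
      order <- if (length(cf) > 4) 2L else 1L
      B <- poly_basis(xyz, order)
      cf_full <- c(cf, rep(0, ncol(B) - length(cf)))
      off <- array(as.vector(B %*% cf_full), series$grid$shape)
      for (k in seq_len(d[4])) v[, , , k, comp] <- v[, , , k, comp] + off
    }
  }
  n_aliased <- 0L
  if (alias) {
    venc_ms <- series$venc / 100  # cm/s -> m/s
    wrapped <- v - 2 * venc_ms * round(v / (2 * venc_ms))
    n_aliased <- sum(wrapped != v)
    v <- wrapped
  }
  out <- series
  out$velocity <- v
  list(series = out, n_aliased = n_aliased)
}
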