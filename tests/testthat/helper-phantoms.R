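# Shared fixtures, built once per test run and cached by key.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fix_poiseuille <- function(h, radius = 8, length = 60, vbar = 0.3) {
  cached(sprintf("pois_%g_%g_%g_%g", h, radius, length, vbar), function() {
    suppressWarnings(
      make_poiseuille_tube(h, radius = radius, length = length,
                           mean_velocity = vbar))
  })
}

fix_tcpc <- function(split, pulsatility = 0, n_frames = 2L) {
  cached(sprintf("tcpc_%g_%g_%d", split, pulsatility, n_frames), function() {
    make_tcpc_phantom(split_ivc_to_lpa = split, pulsatility = pulsatility,
                      n_frames = n_frames)
  })
}

# pathline-counting split estimate for a phantom, default study settings
estimate_split <- function(phantom, density = 30, seed = 11L, dt = NULL) {
  em <- seed_emitters(phantom$regions, "IVC", density = density, seed = seed)
  pl <- trace_pathlines(phantom$series, em, dt = dt,
                        entrance_planes =
                          phantom$regions$boundary_planes[c("lpa", "rpa")])
  flow_distribution(count_crossings(pl,
                                    phantom$regions$boundary_planes$lpa,
                                    phantom$regions$boundary_planes$rpa))
}

# narrow fast jet on a uniform base flow whose wrapped core is a one-voxel
# column: the aliasing round-trip scenario (truth 1.2 venc at the axis)
fix_jet_series <- function(venc = 40) {
  cached(sprintf("jet_%g", venc), function() {
    g <- grid_spec(c(21, 21, 20), c(1, 1, 1), 2L, 50)
    ax <- grid_axes(g)
    co <- fontanflow:::coord_arrays(g)
    r2 <- (co$x - ax$x[11])^2 + (co$y - ax$y[11])^2
    vz <- (0.3 + 0.9 * exp(-r2 / 1.5^2)) * venc / 100
    vel <- array(0, c(g$shape, 2L, 3L))
    for (k in 1:2) vel[, , , k, 3] <- vz
    velocity_series(g, vel, venc = venc)
  })
}

# independent continuous-field streamline tracer over the analytic
# streamfunction (numeric gradient + fine RK4 in arclength); the oracle for
# the phantom's split ground truth, sharing no code with trace_pathlines
trace_streamfunction_exit <- function(sf, x0, y0, limb_length = 24,
                                      ds = 0.15) {
  a <- sf$half_width
  eps <- 1e-4
  vel <- function(x, y) {
    c(u = (sf$psi(x, y + eps) - sf$psi(x, y - eps)) / (2 * eps),
      v = -(sf$psi(x + eps, y) - sf$psi(x - eps, y)) / (2 * eps))
  }
  p <- c(x0, y0)
  for (i in 1:8000) {
    k1 <- vel(p[1], p[2])
    sp <- sqrt(sum(k1^2))
    if (!is.finite(sp) || sp < 1e-9) return("stuck")
    h <- ds / sp
    k2 <- vel(p[1] + h / 2 * k1[1], p[2] + h / 2 * k1[2])
    k3 <- vel(p[1] + h / 2 * k2[1], p[2] + h / 2 * k2[2])
    k4 <- vel(p[1] + h * k3[1], p[2] + h * k3[2])
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (p[1] < -a - limb_length / 2) return("LPA")
    if (p[1] > a + limb_length / 2) return("RPA")
  }
  "maxiter"
}
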