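test_that("uniform flow phantom is constant and masks the full grid", {
  g <- grid_spec(c(8, 8, 8), c(2, 2, 2), 3L, 40)
  s <- make_uniform_flow(g, c(0, 0, 0.2))
  expect_true(all(s$velocity[, , , , 3] == 0.2))
  expect_true(all(s$velocity[, , , , 1:2] == 0))
  expect_true(all(s$mask))
  expect_error(make_uniform_flow(g, c(0, NA, 1)))
})

test_that("Poiseuille truth matches an independent radial integral", {
  # oracle: numeric 1-D integral of mu (dv/dr)^2 and of 1/2 rho v^2 over the
  # tube cross-section, independent of the closed forms stored in truth
  mu <- 3.2e-3; rho <- 1060
  R <- 8e-3; L <- 60e-3; vbar <- 0.3
  r <- seq(0, R, length.out = 20001)
  dvdr <- -4 * vbar * r / R^2
  el_num <- mu * L * sum(dvdr^2 * 2 * pi * r) * (r[2] - r[1])
  ke_num <- 0.5 * rho * L *
    sum((2 * vbar * (1 - r^2 / R^2))^2 * 2 * pi * r) * (r[2] - r[1])
  pz <- fix_poiseuille(2)
  expect_equal(pz$truth$analytic_el_rate, el_num, tolerance = 1e-4)
  expect_equal(pz$truth$analytic_ke, ke_num, tolerance = 1e-4)
  expect_equal(pz$truth$peak_velocity, 0.6)
  # centreline voxel velocity approaches 2 vbar
  expect_equal(max(pz$series$velocity), 2 * 0.3, tolerance = 0.01)
})

test_that("Poiseuille with zero mean velocity is a zero field", {
  pz <- suppressWarnings(
    make_poiseuille_tube(2, radius = 8, length = 20, mean_velocity = 0))
  expect_true(all(pz$series$velocity == 0))
  expect_equal(pz$truth$analytic_el_rate, 0)
})

test_that("under-resolved tube radius triggers a warning", {
  expect_warning(make_poiseuille_tube(4, radius = 8, length = 20,
                                      mean_velocity = 0.2),
                 "poorly resolved")
})

test_that("Poiseuille truth converges first order against the discrete quadrature", {
  # numeric volume integral of mu (dv/dr)^2 evaluated with the analytic
  # gradient on each grid's lumen voxels
  # cross-sectional quadrature (per unit tube length) of the analytic
  # integrand over the discrete lumen, compared with the closed form
  mu <- 3.2e-3
  errs <- sapply(c(4, 2, 1), function(h) {
    pz <- fix_poiseuille(h)
    g <- pz$series$grid
    co <- fontanflow:::coord_arrays(g)
    r2 <- (co$x^2 + co$y^2)[, , 1]    # tube axis along z through (0, 0)
    sel <- pz$series$mask[, , 1]
    integ <- sum(mu * (4 * 0.3 * sqrt(r2[sel]) * 1e-3 / (8e-3)^2)^2) *
      (h * 1e-3)^2
    abs(integ / (pz$truth$analytic_el_rate / 60e-3) - 1)
  })
  expect_gt(errs[1] / errs[2], 2)
  expect_gt(errs[2] / errs[3], 2)
})

test_that("solid-body rotation has zero strain rate and circular orbits", {
  g <- grid_spec(c(24, 24, 12), c(1, 1, 1), 1L, 50)
  s <- make_solid_body_rotation(g, omega = 5)
  el <- energy_loss_maps(s)
  # reference: shear flow of comparable gradient magnitude (k = 5 1/s)
  ref <- 3.2e-3 * voxel_volume_m3(g) * 5^2
  interior <- s$mask
  for (axis in 1:3) {
    interior <- interior & fontanflow:::shift_array(s$mask, axis, 1L) &
      fontanflow:::shift_array(s$mask, axis, -1L)
  }
  expect_lt(max(el$el_rate[, , , 1][interior]) / ref, 1e-6)
  s0 <- make_solid_body_rotation(g, omega = 0)
  expect_true(all(s0$velocity == 0))
})

test_that("TCPC phantom discrete in-plane divergence vanishes at interior voxels", {
  ph <- fix_tcpc(0.65)
  s <- ph$series
  g <- s$grid
  kz <- round(mean(ph$truth$slab))
  u <- s$velocity[, , kz, 1, 1]
  v <- s$velocity[, , kz, 1, 2]
  h <- g$spacing[1]
  div <- (u[3:nrow(u), 2:(ncol(u) - 1)] - u[1:(nrow(u) - 2), 2:(ncol(u) - 1)] +
          v[2:(nrow(v) - 1), 3:ncol(v)] - v[2:(nrow(v) - 1), 1:(ncol(v) - 2)]) /
    (2 * h)
  m2 <- s$mask[, , kz]
  inner <- m2
  for (axis in 1:2) {
    inner <- inner & fontanflow:::shift_array(m2, axis, 1L) &
      fontanflow:::shift_array(m2, axis, -1L) &
      fontanflow:::shift_array(m2, axis, 2L) &
      fontanflow:::shift_array(m2, axis, -2L)
  }
  inner <- inner[2:(nrow(u) - 1), 2:(ncol(u) - 1)]
  grad_scale <- max(abs(u), abs(v)) / h   # peak velocity gradient scale, 1/s
  expect_lt(max(abs(div[inner])) / grad_scale, 1e-3)
})

test_that("streamfunction split ground truth is confirmed by continuous streamline tracing", {
  for (split in c(0.35, 0.8)) {
    ph <- fix_tcpc(split)
    sf <- ph$truth$streamfunction
    a <- sf$half_width
    xs <- seq(-a + 0.05, a - 0.05, length.out = 41)
    exits <- vapply(xs, function(x)
      trace_streamfunction_exit(sf, x, -a - 10), "")
    est <- mean(exits == "LPA") / mean(exits %in% c("LPA", "RPA"))
    expect_equal(est, split, tolerance = 0.03)
  }
})

test_that("pulsatility modulates frames sinusoidally; zero pulsatility is steady", {
  ph0 <- fix_tcpc(0.5)
  expect_equal(ph0$series$velocity[, , , 1, ], ph0$series$velocity[, , , 2, ])
  ph <- make_tcpc_phantom(0.5, pulsatility = 0.3, n_frames = 8L)
  tt <- frame_times_s(ph$series$grid)
  Tc <- cycle_duration_s(ph$series$grid)
  expected <- 1 + 0.3 * sin(2 * pi * tt / Tc)
  kz <- round(mean(ph$truth$slab))
  base <- ph$series$velocity[, , kz, 1, 2] / expected[1]
  probe <- which(abs(base) == max(abs(base)), arr.ind = TRUE)[1, ]
  v_t <- ph$series$velocity[probe[1], probe[2], kz, , 2]
  expect_equal(v_t / base[probe[1], probe[2]], expected, tolerance = 1e-12)
})

test_that("corrupt is an identity when disabled and bit-reproducible under a seed", {
  ph <- fix_tcpc(0.5)
  same <- corrupt(ph$series, noise_sd = 0, offset_coeffs = NULL, alias = FALSE)
  expect_identical(same$series$velocity, ph$series$velocity)
  a <- corrupt(ph$series, noise_sd = 0.02, seed = 7L)
  b <- corrupt(ph$series, noise_sd = 0.02, seed = 7L)
  expect_identical(a$series$velocity, b$series$velocity)
  c2 <- corrupt(ph$series, noise_sd = 0.02, seed = 8L)
  expect_false(identical(a$series$velocity, c2$series$velocity))
})

test_that("alias wrap follows the wrap formula and stays within the venc", {
  g <- grid_spec(c(4, 4, 4), c(1, 1, 1), 1L, 50)
  venc <- 50
  vel <- array(0, c(g$shape, 1L, 3L))
  vel[, , , 1, 3] <- 1.2 * venc / 100
  s <- velocity_series(g, vel, venc = venc)
  cr <- corrupt(s, alias = TRUE)
  expect_equal(unique(as.vector(cr$series$velocity[, , , 1, 3])),
               -0.8 * venc / 100, tolerance = 1e-12)
  ph <- fix_tcpc(0.5)
  s2 <- ph$series
  s2$venc <- 15
  w <- corrupt(s2, alias = TRUE)$series$velocity
  expect_true(all(w >= -0.15 - 1e-12 & w <= 0.15 + 1e-12))
})
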