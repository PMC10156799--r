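test_that("series are truncated to the minimum covered cycle fraction", {
  g <- function(nt) grid_spec(c(4, 4, 4), c(1, 1, 1), nt, 50)
  s_full <- make_uniform_flow(g(20L), c(0, 0, 0.1))       # covers 1.00
  s_part <- make_uniform_flow(g(17L), c(0, 0, 0.1))
  s_part$cycle_fraction <- 0.85
  out <- truncate_to_common_fraction(list(s_full, s_part))
  expect_equal(out[[1]]$grid$n_frames, 17L)                # 0.85 of 20
  expect_equal(out[[1]]$cycle_fraction, 0.85)
  expect_equal(out[[2]]$grid$n_frames, 17L)                # unchanged
  expect_equal(out[[2]]$cycle_fraction, 0.85)
  same <- truncate_to_common_fraction(list(s_full))
  expect_identical(same[[1]]$velocity, s_full$velocity)
  expect_error(truncate_to_common_fraction(list()), "empty")
})

test_that("isotropic resampling is exact on coincident points and linear fields", {
  g <- grid_spec(c(9, 9, 9), c(1, 1, 1), 2L, 50)
  s <- make_uniform_flow(g, c(0.05, 0, 0.2))
  r <- resample_isotropic(s, 1)
  expect_equal(r$velocity, s$velocity, tolerance = 1e-12)
  # v_z = k y reproduced exactly at any resolution (trilinear exactness)
  co <- fontanflow:::coord_arrays(g)
  s2 <- s
  for (k in 1:2) s2$velocity[, , , k, 3] <- 0.01 * co$y
  r2 <- resample_isotropic(s2, 0.6)
  co2 <- fontanflow:::coord_arrays(r2$grid)
  expect_equal(array(r2$velocity[, , , 1, 3], r2$grid$shape), 0.01 * co2$y,
               tolerance = 1e-12)
})

test_that("resampling a coarse Poiseuille tube to 1 mm sharpens the peak", {
  pz2 <- fix_poiseuille(2)
  r1 <- resample_isotropic(pz2$series, 1)
  peak2 <- max(speed_map(pz2$series))
  peak1 <- max(speed_map(r1))
  expect_gte(peak1, peak2 - 1e-12)
  expect_lte(peak1, 0.6 + 1e-9)   # never overshoots the analytic maximum
})

test_that("peak-velocity map and regional 98th percentile match a sorted oracle", {
  g <- grid_spec(c(10, 10, 5), c(1, 1, 1), 3L, 50)
  vel <- array(0, c(g$shape, 3L, 3L))
  vel[, , , 1, 3] <- 0.2
  vel[, , , 2, 3] <- 0.5
  vel[, , , 3, 3] <- 0.3
  s <- velocity_series(g, vel)
  pk <- peak_velocity_map(s)
  expect_true(all(pk == 0.5))
  # region = one z slab of 100 voxels: 99 peak at 0.5, one at 1.0;
  # oracle: brute-force linear-interpolation percentile over sorted values
  vel[10, 10, 3, 2, 3] <- 1.0
  s2 <- velocity_series(g, vel)
  labels <- array(0L, g$shape)
  for (kz in 1:5) labels[, , kz] <- kz
  maps <- hemodynamic_maps(s2)
  rs <- regional_summary(maps, region_model(labels, g))
  vals <- sort(as.vector(peak_velocity_map(s2)[, , 3]))
  h <- 1 + 0.98 * (length(vals) - 1)
  oracle <- vals[floor(h)] +
    (h - floor(h)) * (vals[floor(h) + 1] - vals[floor(h)])
  expect_equal(rs$peak_velocity_p98[rs$region == "connection"], oracle)
  # a single-voxel region reduces to that voxel's values
  one <- array(0L, g$shape)
  one[1, 1, 1] <- 1L; one[2, 1, 1] <- 2L; one[3, 1, 1] <- 3L
  one[4, 1, 1] <- 4L; one[5, 1, 1] <- 5L
  rs1 <- regional_summary(maps, region_model(one, g))
  expect_equal(rs1$peak_velocity_p98[rs1$region == "IVC"],
               maps$peak_velocity[1, 1, 1])
  expect_equal(rs1$ke_mean[rs1$region == "IVC"],
               maps$kinetic_energy[1, 1, 1])
})

test_that("stasis percentages cover the trivial and alternating cases", {
  g <- grid_spec(c(4, 4, 4), c(1, 1, 1), 4L, 50)
  slow <- make_uniform_flow(g, c(0, 0, 0.05))
  fast <- make_uniform_flow(g, c(0, 0, 0.2))
  expect_true(all(stasis_map(slow) == 100))
  expect_true(all(stasis_map(fast) == 0))
  alt <- slow
  alt$velocity[, , , c(2, 4), 3] <- 0.2
  expect_true(all(stasis_map(alt) == 50))
})

test_that("kinetic energy evaluates the defining formula and its closed form", {
  g <- grid_spec(c(3, 3, 3), c(1, 1, 1), 1L, 50)
  s <- make_uniform_flow(g, c(0, 0, 1))
  ke <- kinetic_energy_map(s)
  expect_equal(unique(as.vector(ke)), 0.5 * 1060 * 1e-9, tolerance = 1e-12)
  expect_true(all(kinetic_energy_map(make_uniform_flow(g, c(0, 0, 0))) == 0))
  pz <- fix_poiseuille(1)
  ke_tot <- sum(kinetic_energy_map(pz$series))
  expect_lt(abs(ke_tot / pz$truth$analytic_ke - 1), 0.03)
})

test_that("dissipation is exact on simple shear and zero on gradient-free fields", {
  g <- grid_spec(c(12, 12, 12), c(1, 1, 1), 1L, 50)
  co <- fontanflow:::coord_arrays(g)
  k <- 4
  vel <- array(0, c(g$shape, 1L, 3L))
  vel[, , , 1, 3] <- k * co$y * 1e-3      # v_z = k y, k in 1/s
  s <- velocity_series(g, vel)
  el <- energy_loss_maps(s)
  expected <- 3.2e-3 * voxel_volume_m3(g) * k^2
  expect_equal(as.vector(el$el_rate[, , , 1]),
               rep(expected, prod(g$shape)), tolerance = 1e-12)
  u <- make_uniform_flow(g, c(0.1, -0.2, 0.3))
  expect_lt(max(abs(energy_loss_maps(u)$el_rate)), 1e-20)
})

test_that("Poiseuille energetics converge onto the closed forms through 1 mm", {
  el_err <- ke_err <- numeric(3)
  hs <- c(4, 2, 1)
  for (i in seq_along(hs)) {
    pz <- fix_poiseuille(hs[i])
    maps <- hemodynamic_maps(pz$series)
    el_err[i] <- abs(sum(maps$el_mean) / pz$truth$analytic_el_rate - 1)
    ke_err[i] <- abs(sum(maps$kinetic_energy) / pz$truth$analytic_ke - 1)
  }
  expect_lt(el_err[3], 0.05)
  expect_lt(ke_err[3], 0.03)
  expect_true(all(diff(el_err) < 0))
  expect_true(all(diff(ke_err) < 0))
})

test_that("KE and dissipation scale quadratically with velocity", {
  ph <- fix_tcpc(0.65)
  s <- ph$series
  s2 <- s
  s2$velocity <- 2 * s2$velocity
  m1 <- hemodynamic_maps(s)
  m2 <- hemodynamic_maps(s2)
  expect_equal(m2$kinetic_energy, 4 * m1$kinetic_energy, tolerance = 1e-12)
  expect_equal(m2$el_tot, 4 * m1$el_tot, tolerance = 1e-12)
})

test_that("el_mean times covered duration equals el_tot for steady fields", {
  ph <- fix_tcpc(0.5)   # steady: identical frames
  maps <- hemodynamic_maps(ph$series)
  expect_equal(maps$el_mean * maps$covered_duration_s, maps$el_tot,
               tolerance = 1e-12)
})

test_that("the dissipation map commutes with a 90-degree rotation", {
  ph <- fix_tcpc(0.65)
  s <- ph$series
  el <- energy_loss_maps(s)$el_rate[, , , 1]
  # rotate 90 degrees about z: (x, y) -> (y, -x); components swap as well
  g <- s$grid
  rot_vol <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  g2 <- grid_spec(g$shape[c(2, 1, 3)], g$spacing[c(2, 1, 3)], g$n_frames,
                  g$frame_duration, g$origin[c(2, 1, 3)])
  vel2 <- array(0, c(g2$shape, g$n_frames, 3L))
  for (k in seq_len(g$n_frames)) {
    vx <- array(s$velocity[, , , k, 1], g$shape)
    vy <- array(s$velocity[, , , k, 2], g$shape)
    vz <- array(s$velocity[, , , k, 3], g$shape)
    vel2[, , , k, 1] <- -rot_vol(vy)
    vel2[, , , k, 2] <- rot_vol(vx)
    vel2[, , , k, 3] <- rot_vol(vz)
  }
  s2 <- velocity_series(g2, vel2, mask = array(rot_vol(s$mask), g2$shape),
                        venc = s$venc)
  el2 <- energy_loss_maps(s2)$el_rate[, , , 1]
  expect_equal(el2, rot_vol(el), tolerance = 1e-10)
})

test_that("regional summaries reduce uniform maps to the uniform value", {
  ph <- fix_tcpc(0.5)
  maps <- hemodynamic_maps(ph$series)
  maps$stasis[ph$series$mask] <- 42
  maps$kinetic_energy[ph$series$mask] <- 7e-7
  rs <- regional_summary(maps, ph$regions)
  expect_equal(nrow(rs), 5L)
  expect_true(all(rs$stasis_mean == 42))
  expect_true(all(abs(rs$ke_mean - 7e-7) < 1e-18))
  expect_true(all(rs$n_voxels > 0))
})

test_that("the junction dissipates more than the straight limbs", {
  ph <- fix_tcpc(0.5)
  maps <- hemodynamic_maps(ph$series)
  rs <- regional_summary(maps, ph$regions)
  conn <- rs$el_mean_mean[rs$region == "connection"]
  limbs <- mean(rs$el_mean_mean[rs$region %in% c("IVC", "SVC")])
  expect_gt(conn, limbs)
})
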