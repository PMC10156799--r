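test_that("emitter seeding matches the requested density inside the source", {
  ph <- fix_tcpc(0.5)
  em <- seed_emitters(ph$regions, "IVC", density = 30, seed = 3L)
  vol <- region_volumes_cm3(ph$regions)[["IVC"]]
  expect_lt(abs(nrow(em$positions) - 30 * vol), 0.1 * 30 * vol)
  expect_lt(abs(em$density_achieved / 30 - 1), 0.1)
  # every emitter inside the IVC label
  idx <- round(fontanflow:::world_to_index(ph$series$grid, em$positions))
  lab <- mapply(function(i, j, k) ph$regions$labels[i, j, k],
                idx[, 1], idx[, 2], idx[, 3])
  expect_true(all(lab == region_names()[["IVC"]]))
  # reproducible under the seed; empty at density zero
  em2 <- seed_emitters(ph$regions, "IVC", density = 30, seed = 3L)
  expect_identical(em$positions, em2$positions)
  expect_identical(nrow(seed_emitters(ph$regions, "IVC", 0)$positions), 0L)
})

test_that("uniform steady flow advects emitters in exact straight lines", {
  g <- grid_spec(c(10, 10, 60), c(2, 2, 2), 1L, 100)
  s <- make_uniform_flow(g, c(0, 0, 0.2))
  pl <- trace_pathlines(s, matrix(c(9, 9, 2), 1), dt = 20, max_cycles = 10L)
  tr <- pl$trajectories[1, , ]
  tr <- tr[stats::complete.cases(tr), ]
  # 0.1 s of flight = 20 mm displacement; straight to machine precision
  k <- 6L  # 5 steps of 20 ms
  expect_equal(tr[k, ], c(9, 9, 22), tolerance = 1e-9)
  expect_lt(max(abs(tr[, 1] - 9), abs(tr[, 2] - 9)), 1e-9 * 22)
})

test_that("rotation orbits close and the integrator converges at 4th order", {
  g <- grid_spec(c(41, 41, 9), c(2, 2, 2), 1L, 100)
  rot <- make_solid_body_rotation(g, omega = 4)
  period <- 2 * pi / 4
  p0 <- matrix(c(40 + 15, 40, 8), 1)
  err_at <- function(n_steps) {
    dt_ms <- period / n_steps * 1e3
    pl <- trace_pathlines(rot, p0, dt = dt_ms, max_cycles = 20L)
    sqrt(sum((pl$trajectories[1, n_steps + 1L, ] - p0)^2))
  }
  e1 <- err_at(80L)
  e2 <- err_at(160L)
  expect_lt(e2, 1e-4)            # closes to well under a micron in mm units
  expect_gt(e1 / e2, 8)          # at least ~3rd order observed, RK4 nominal
  expect_lt(e1 / e2, 64)
})

test_that("a zero-velocity emitter terminates as low_velocity", {
  g <- grid_spec(c(8, 8, 8), c(2, 2, 2), 1L, 100)
  s <- make_uniform_flow(g, c(0, 0, 0))
  pl <- trace_pathlines(s, matrix(c(7, 7, 7), 1), dt = 20)
  expect_equal(as.character(pl$termination[1]), "low_velocity")
  expect_error(trace_pathlines(s, matrix(c(100, 0, 0), 1)), "outside")
})

test_that("crossing counting honours the plane radius and first-crossing rule", {
  lpa <- analysis_plane(c(0, 0, 10), c(0, 0, 1), 5, "LPA_entrance")
  rpa <- analysis_plane(c(0, 0, -10), c(0, 0, -1), 5, "RPA_entrance")
  mk_path <- function(pts) {
    n <- nrow(pts)
    traj <- array(NA_real_, c(1, n, 3))
    traj[1, , ] <- pts
    structure(list(trajectories = traj, times = seq_len(n) - 1,
                   n_points = n,
                   termination = factor("max_time",
                                        levels = levels(factor("max_time"))),
                   first_plane = factor("none"), source_label = "IVC"),
              class = "pathline_set")
  }
  through <- mk_path(cbind(0, 0, seq(-5, 15, by = 2)))
  res <- count_crossings(through, lpa, rpa)
  expect_identical(res$n_lpa, 1L)
  expect_identical(res$n_rpa, 0L)
  beside <- mk_path(cbind(8, 0, seq(-5, 15, by = 2)))
  res2 <- count_crossings(beside, lpa, rpa)
  expect_identical(res2$n_lpa + res2$n_rpa, 0L)
  # crosses RPA first, then LPA: only the first counts
  zig <- mk_path(cbind(0, 0, c(0, -12, 15)))
  res3 <- count_crossings(zig, lpa, rpa)
  expect_identical(res3$n_rpa, 1L)
  expect_identical(res3$n_lpa, 0L)
})

test_that("flow fractions and the 30/70 strict classification rule", {
  mk <- function(n_lpa, n_rpa) {
    structure(list(n_lpa = n_lpa, n_rpa = n_rpa, validity_fraction = 1,
                   fraction_lpa = NA, fraction_rpa = NA,
                   classification = NA),
              class = "flow_distribution_result")
  }
  r <- flow_distribution(mk(30L, 70L))
  expect_equal(r$fraction_lpa, 0.30)
  expect_equal(r$fraction_rpa, 0.70)
  expect_identical(r$classification, "equal")      # boundary is equal
  expect_identical(flow_distribution(mk(70L, 30L))$classification, "equal")
  expect_identical(flow_distribution(mk(71L, 29L))$classification, "unequal")
  expect_identical(flow_distribution(mk(0L, 50L))$classification, "unequal")
  expect_equal(flow_distribution(mk(0L, 50L))$fraction_lpa, 0)
  expect_warning(flow_distribution(mk(0L, 0L)), "undefined")
})

test_that("fractions always sum to one when defined", {
  for (split in c(0.2, 0.65)) {
    res <- estimate_split(fix_tcpc(split))
    expect_equal(res$fraction_lpa + res$fraction_rpa, 1)
  }
})

test_that("pathline counting recovers the ground-truth splits monotonically", {
  splits <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  est <- vapply(splits, function(f) estimate_split(fix_tcpc(f))$fraction_lpa, 0)
  expect_true(all(abs(est - splits) < 0.05))
  expect_true(all(diff(est) > 0))
})

test_that("mirroring the phantom swaps the LPA and RPA fractions", {
  ph <- fix_tcpc(0.65)
  mir <- reflect_tcpc_lr(ph)
  em <- seed_emitters(ph$regions, "IVC", density = 30, seed = 5L)
  em_m <- em
  em_m$positions[, 1] <- -em_m$positions[, 1]
  pl <- trace_pathlines(ph$series, em,
                        entrance_planes = ph$regions$boundary_planes[c("lpa", "rpa")])
  pl_m <- trace_pathlines(mir$series, em_m,
                          entrance_planes = mir$regions$boundary_planes[c("lpa", "rpa")])
  r <- flow_distribution(count_crossings(pl, ph$regions$boundary_planes$lpa,
                                         ph$regions$boundary_planes$rpa))
  r_m <- flow_distribution(count_crossings(pl_m,
                                           mir$regions$boundary_planes$lpa,
                                           mir$regions$boundary_planes$rpa))
  expect_equal(r_m$fraction_lpa, r$fraction_rpa, tolerance = 0.02)
  expect_equal(r_m$fraction_rpa, r$fraction_lpa, tolerance = 0.02)
})

test_that("halving the integration step leaves the recovered fraction stable", {
  ph <- fix_tcpc(0.65)
  f1 <- estimate_split(ph)$fraction_lpa
  f2 <- estimate_split(ph, dt = ph$series$grid$frame_duration / 10)$fraction_lpa
  expect_lt(abs(f1 - f2), 0.01)
})

test_that("most multi-point pathlines reach a plane on the ideal phantom", {
  # the validity fraction is defined over pathlines with > 3 time points;
  # on the noiseless phantom nearly all of those arrive (patient data do
  # far worse, which is why the fraction is reported)
  res <- estimate_split(fix_tcpc(0.5))
  expect_gt(res$validity_fraction, 0.8)
})
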