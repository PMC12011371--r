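test_that("generators are deterministic given (params, seed)", {
  a <- gen_invasion_field(30, 0.5, seed = 9)
  b <- gen_invasion_field(30, 0.5, seed = 9)
  expect_identical(a$gelatin$pixels, b$gelatin$pixels)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    gen_invasion_field(30, 0.5, seed = 10)$gelatin$pixels,
    a$gelatin$pixels))
  t1 <- gen_trajectories(5, 0.3, 0.1, seed = 4)
  t2 <- gen_trajectories(5, 0.3, 0.1, seed = 4)
  expect_identical(t1$frames, t2$frames)
})

test_that("invasion field truth is honoured by construction", {
  s <- gen_invasion_field(100, 0.4, seed = 2)
  expect_equal(sum(s$truth$invasive), 40)
  # no dark patches when nothing invades
  s0 <- gen_invasion_field(50, 0, seed = 2)
  expect_gt(min(s0$gelatin$pixels), 0.5)
  # infeasible packing is reported, not looped forever
  expect_error(gen_invasion_field(500, 1, field_px = 64,
                                  degraded_patch_radius_px = 8),
               "packing|fit")
})

test_that("trajectory generator matches its analytic motion model", {
  still <- gen_trajectories(5, 0, 0, n_frames = 20, seed = 1)
  expect_equal(still$frames[[1]], still$frames[[20]])
  drift <- gen_trajectories(4, 0, 1, dt = 1, n_frames = 30, seed = 1)
  for (i in 1:4) {
    steps <- diff(drift$truth$tracks[[i]][, "x"])^2 +
      diff(drift$truth$tracks[[i]][, "y"])^2
    expect_equal(sqrt(steps), rep(1, 29), tolerance = 1e-12)
  }
  # ensemble MSD oracle: msd(tau) = 4 D tau + (v tau)^2
  sim <- gen_trajectories(200, 0.5, 0.2, dt = 1, n_frames = 60, seed = 3)
  for (k in c(1, 5, 10)) {
    disp2 <- vapply(sim$truth$tracks, function(tr) {
      n <- nrow(tr)
      mean((tr[(k + 1):n, 1] - tr[1:(n - k), 1])^2 +
             (tr[(k + 1):n, 2] - tr[1:(n - k), 2])^2)
    }, numeric(1))
    expected <- 4 * 0.5 * k + (0.2 * k)^2
    expect_equal(mean(disp2), expected, tolerance = 0.1)
  }
})

test_that("calcium trace generator hits the requested amplitude", {
  flat <- gen_calcium_trace(delta_ca = 0, noise_sd = 0.5, seed = 1)
  expect_lt(diff(range(flat$trace$intensity)), 4)
  clean <- gen_calcium_trace(delta_ca = -49, noise_sd = 0, seed = 1)
  expect_equal(min(clean$trace$intensity) - 500, -49)
  expect_error(gen_calcium_trace(n_frames = 15, treatment_frame = 11),
               "treatment_frame")
})

test_that("force curve generator obeys the contact model", {
  sim <- gen_force_curve(1, noise_sd = 0, seed = 1)
  pre <- sim$curve$indenter_position_um < sim$truth$contact_point_um
  expect_equal(mean(sim$curve$deflection_um[pre]), 0)
  expect_true(all(diff(sim$curve$deflection_um) >= -1e-12))
  # cantilever equilibrium holds: k d = Hertz(z - z0 - d)
  k <- sim$curve$spring_constant_N_per_m * 1000
  d <- sim$curve$deflection_um
  z <- sim$curve$indenter_position_um
  delta <- pmax(z - sim$truth$contact_point_um - d, 0)
  hertz <- (4 / 3) * (1 / (1 - 0.25)) * sqrt(5) * delta^1.5
  expect_equal(k * d, hertz, tolerance = 1e-6)
})

test_that("ellipsoid stack records the analytic volume", {
  sph <- gen_ellipsoid_stack(c(5, 5, 5), seed = 1)
  expect_equal(sph$truth$volume_um3, 4 / 3 * pi * 125, tolerance = 1e-12)
  expect_equal(round(sph$truth$volume_um3, 1), 523.6)
  ell <- gen_ellipsoid_stack(c(10, 8, 6), seed = 1)
  expect_equal(round(ell$truth$volume_um3, 1), 2010.6)
  expect_error(gen_ellipsoid_stack(c(0, 0, 0)), "positive")
})

test_that("concordance generator reaches degenerate operating points", {
  perfect <- gen_concordance_table(10, 20, 1, 1, 0, seed = 1)$table
  expect_true(all(perfect$call[perfect$grade == "DCIS_high"] == "Y"))
  expect_true(all(perfect$call[perfect$grade != "DCIS_high"] == "N"))
  alleq <- gen_concordance_table(10, 20, 0.8, 0.9, 1, seed = 1)$table
  expect_true(all(alleq$call == "E"))
  expect_error(diagnostic_concordance(alleq), "usable")
})

test_that("noise-free generated instances invert exactly per modality", {
  lp <- gen_line_profile(0.8, 0.15, 0.05, noise_sd = 0)
  res <- analyze_line_profile(lp$profile)
  expect_equal(c(res$pm_pct, res$cyto_pct, res$nuc_pct), c(80, 15, 5),
               tolerance = 1e-9)
  ca <- delta_ca(gen_calcium_trace(delta_ca = -49, noise_sd = 0)$trace)
  expect_equal(ca$delta_ca, -49, tolerance = 1e-12)
  hz <- fit_hertz(gen_force_curve(1, noise_sd = 0)$curve)
  expect_equal(hz$E_kPa, 1, tolerance = 1e-3)
})
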