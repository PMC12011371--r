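test_that("linking follows single cells, identities and gaps", {
  # one detection per frame -> one full-length track
  one <- lapply(1:20, function(f) cbind(x = f * 0.5, y = 0))
  tr <- link_trajectories(one, dt_min = 1)
  expect_length(tr, 1)
  expect_length(tr[[1]]$time_min, 20)
  expect_equal(tr[[1]]$gaps, 0L)
  # well-separated cells -> identity linking, zero swaps
  sim <- gen_trajectories(25, 0.4, 0.1, n_frames = 60, seed = 6)
  tracks <- link_trajectories(sim$frames, sim$dt)
  expect_length(tracks, 25)
  for (tk in tracks) {
    start <- c(tk$x_um[1], tk$y_um[1])
    truth_id <- which.min(vapply(sim$truth$tracks, function(t0)
      sum((t0[1, ] - start)^2), numeric(1)))
    expect_equal(cbind(x = tk$x_um, y = tk$y_um),
                 sim$truth$tracks[[truth_id]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # one missed detection bridged by interpolation
  gap <- lapply(1:15, function(f) {
    if (f == 8) matrix(numeric(0), 0, 2,
                       dimnames = list(NULL, c("x", "y")))
    else cbind(x = f * 1.0, y = 2)
  })
  tg <- link_trajectories(gap, dt_min = 1, max_gap_frames = 1)
  expect_length(tg, 1)
  expect_equal(tg[[1]]$gaps, 1L)
  expect_equal(tg[[1]]$x_um[8], 8)
  expect_error(link_trajectories(one[1]), "at least 2")
})

test_that("MSD obeys its closed forms", {
  still <- trajectory(1, 0:19, rep(2, 20), rep(3, 20))
  expect_true(all(compute_msd(still)$msd_um2 == 0))
  line <- trajectory(1, 0:39, 1.5 * (0:39), rep(0, 40))
  msd <- compute_msd(line)
  expect_equal(msd$msd_um2, (1.5 * msd$lag_min)^2, tolerance = 1e-12)
  expect_equal(msd$n_pairs, 40 - seq_len(nrow(msd)))
  expect_error(compute_msd(trajectory(1, 0:5, 0:5, 0:5)), "short")
})

test_that("motility fit inverts pure drift and pure diffusion", {
  tau <- 1:10
  drift <- structure(data.frame(lag_min = tau, msd_um2 = (0.7 * tau)^2,
                                n_pairs = 100 - tau),
                     class = c("msd_curve", "data.frame"))
  fd <- fit_motility(drift)
  expect_equal(fd$D_um2_min, 0, tolerance = 1e-9)
  expect_equal(fd$v_um_min, 0.7, tolerance = 1e-9)
  diff_only <- structure(data.frame(lag_min = tau, msd_um2 = 4 * 0.3 * tau,
                                    n_pairs = 100 - tau),
                         class = c("msd_curve", "data.frame"))
  fD <- fit_motility(diff_only)
  expect_equal(fD$D_um2_min, 0.3, tolerance = 1e-9)
  expect_equal(fD$v_um_min, 0, tolerance = 1e-6)
  degen <- structure(data.frame(lag_min = rep(1, 4), msd_um2 = 1:4,
                                n_pairs = 4:1),
                     class = c("msd_curve", "data.frame"))
  expect_error(fit_motility(degen), "degenerate")
})

test_that("estimates are invariant under rigid motions and time rescaling", {
  sim <- gen_trajectories(1, 0.5, 0.2, n_frames = 120, seed = 12)
  tk <- sim$truth$tracks[[1]]
  base <- fit_motility(compute_msd(trajectory(1, 0:119, tk[, 1], tk[, 2])))
  th <- 0.7
  rot <- cbind(tk[, 1] * cos(th) - tk[, 2] * sin(th) + 40,
               tk[, 1] * sin(th) + tk[, 2] * cos(th) - 13)
  moved <- fit_motility(compute_msd(trajectory(1, 0:119, rot[, 1],
                                               rot[, 2])))
  expect_equal(moved$D_um2_min, base$D_um2_min, tolerance = 1e-9)
  expect_equal(moved$v_um_min, base$v_um_min, tolerance = 1e-9)
  # halving dt with the same physical motion leaves (D, v) unchanged:
  # interpolate midpoints of a pure-drift track
  line <- trajectory(1, 0:59, 0.4 * (0:59), rep(0, 60))
  fine <- trajectory(1, (0:118) / 2, 0.4 * (0:118) / 2, rep(0, 119))
  f1 <- fit_motility(compute_msd(line))
  f2 <- fit_motility(compute_msd(fine))
  expect_equal(f1$v_um_min, f2$v_um_min, tolerance = 1e-9)
})

test_that("median estimates track the truth and scale with true D", {
  sim <- gen_trajectories(120, 0.5, 0.2, n_frames = 120, seed = 2)
  tracks <- link_trajectories(sim$frames, sim$dt)
  res <- vapply(tracks, function(tk) {
    a <- analyze_motility(tk)
    c(a$D_um2_min, a$v_um_min, a$v_net_um_min)
  }, numeric(3))
  expect_lt(abs(median(res[1, ]) / 0.5 - 1), 0.15)
  expect_lt(abs(median(res[2, ]) / 0.2 - 1), 0.25)
  expect_gt(stats::cor(res[2, ], res[3, ]), 0)  # v and v_net agree in rank
  meds <- vapply(c(0.1, 0.3, 0.6, 1.0), function(D) {
    s <- gen_trajectories(60, D, 0.1, n_frames = 100, seed = 7)
    tk <- link_trajectories(s$frames, s$dt)
    median(vapply(tk, function(t0) analyze_motility(t0)$D_um2_min,
                  numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
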