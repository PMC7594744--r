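test_that("config validation rejects invalid parameters", {
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(intensity_hi = 0.1, intensity_lo = 0.2), "intensity_hi")
  expect_error(sim_config(sampling_interval = 0), "> 0")
  expect_error(simulate_lineage(sim_config(horizon = 5)), "horizon too short")
  expect_error(bridge_sim_config(tau_c = -3), "tau_c")
  expect_error(bridge_sim_config(w0 = 0.1, w_inf = 0.2), "w0 > w_inf")
  expect_error(frap_sim_config(exchange_rate = -0.1), "exchange_rate")
  expect_error(frap_sim_config(bleach_depth = 1.5), "bleach_depth")
})

test_that("zero-noise lineages are degenerate and lag is exact", {
  sim <- simulate_lineage(sim_config(n_families = 6, sister_jitter_sd = 0,
                                     noise_sd = 0, seed = 3))
  for (f in unique(sim$cells$family)) {
    ids <- sim$cells$cell_id[sim$cells$family == f]
    expect_equal(sim$cells$true_tau_h[sim$cells$cell_id == ids[1]],
                 sim$cells$true_tau_h[sim$cells$cell_id == ids[2]])
    a <- sim$trajectories[sim$trajectories$cell_id == ids[1], ]
    b <- sim$trajectories[sim$trajectories$cell_id == ids[2], ]
    expect_equal(a$intensity_au, b$intensity_au)
  }
  sim2 <- simulate_lineage(sim_config(n_families = 6, exit_lag_mean = 3,
                                      exit_lag_sd = 0, sister_jitter_sd = 0,
                                      seed = 4))
  expect_equal(sim2$cells$true_tau_h - sim2$cells$gating_division_h,
               rep(3, nrow(sim2$cells)))
})

test_that("gating at the second division is tied to the late-cycle trigger", {
  sim <- simulate_lineage(sim_config(n_families = 50, seed = 1))
  cells <- sim$cells
  frac_second <- with(cells, tapply(gate == "second", stage, mean))
  expect_true(frac_second[["late-cycle"]] > frac_second[["early-cycle"]])
  # and both stages are populated under the default trigger model
  expect_true(all(table(cells$stage) > 0))
})

test_that("noiseless bridge widths follow the closed-form curve exactly", {
  cfg <- bridge_sim_config("naive", n_curves = 1, w0 = 1, w_inf = 0.2,
                           tau_c = 45, noise_sd = 0, sampling_interval = 45,
                           duration = 90, seed = 1)
  sim <- simulate_bridge_widths(cfg)
  expect_equal(sim$traces$width_um[sim$traces$t_min == 45],
               0.2 + 0.8 * exp(-1), tolerance = 1e-12)
  expect_error(simulate_bridge_widths(bridge_sim_config(duration = 8)),
               "too short")
})

test_that("condition presets carry the published characteristic times", {
  expect_equal(simulate_bridge_widths(
    bridge_sim_config("naive", seed = 1))$truth$tau_c_min[1], 45)
  expect_equal(simulate_bridge_widths(
    bridge_sim_config("exiting", seed = 1))$truth$tau_c_min[1], 15)
})

test_that("abscission durations are moment-matched and positive", {
  d <- simulate_abscission_durations(8.2, 3.8, 1e4, seed = 7)
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - 8.2), 0.2)
  expect_lt(abs(sd(d) - 3.8), 0.2)
  expect_equal(simulate_abscission_durations(5, 0, 3), rep(5, 3))
  expect_identical(simulate_abscission_durations(5, 1, 0), numeric(0))
  expect_error(simulate_abscission_durations(-1, 1, 5), "mean")
})

test_that("FRAP generator matches the two-compartment closed form", {
  # k = 0: no exchange, sister and neighbor stay at 1
  sim0 <- simulate_frap(frap_sim_config(exchange_rate = 0, noise_sd = 0))
  s <- subset(sim0$traces, role == "sister" & t_s >= 0)
  expect_equal(min(s$intensity_norm), 1)
  # closed form at every post-bleach time
  k <- 0.05; b <- 0.2
  sim <- simulate_frap(frap_sim_config(exchange_rate = k, bleach_depth = b,
                                       duration = 120, noise_sd = 0))
  s <- subset(sim$traces, role == "sister" & t_s >= 0)
  expect_equal(s$intensity_norm,
               (1 + b) / 2 + (1 - b) / 2 * exp(-2 * k * s$t_s),
               tolerance = 1e-12)
  expect_equal(min(s$intensity_norm), 0.6, tolerance = 1e-4)
  bl <- subset(sim$traces, role == "bleached")
  expect_equal(bl$intensity_norm[bl$t_s == 0], b, tolerance = 1e-12)
})

test_that("frame counts have binomial structure", {
  expect_true(all(simulate_frame_counts(50, 30, 0, seed = 1)$n_bridges == 0))
  expect_true(all(simulate_frame_counts(50, 1, 1, seed = 1)$n_bridges == 1))
  cnt <- simulate_frame_counts(1000, 100, 0.3, seed = 2)
  expect_lt(abs(mean(cnt$n_bridges / cnt$n_cells) - 0.3), 0.01)
  expect_error(simulate_frame_counts(10, 100, 1.2), "bridge_fraction")
})

test_that("generators are seed-reproducible and preserve the caller's RNG", {
  a <- simulate_lineage(sim_config(n_families = 4, seed = 11))
  b <- simulate_lineage(sim_config(n_families = 4, seed = 11))
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$cells, b$cells)
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_frap(frap_sim_config(seed = 5)))
  expect_identical(runif(1), x1)
})
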