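exp_trace <- function(tau_c, w0 = 1.5, w_inf = 0.3, t = seq(0, 180, 5),
                      noise_sd = 0, id = "b1", condition = "x", seed = NULL) {
  w <- w_inf + (w0 - w_inf) * exp(-t / tau_c)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    w <- pmax(w + rnorm(length(t), 0, noise_sd), 0)
  }
  data.frame(bridge_id = id, condition = condition, t_min = t, width_um = w)
}

test_that("exponential fit recovers noiseless characteristic times", {
  for (tau in c(45, 15)) {
    f <- fit_exponential(exp_trace(tau))
    expect_true(f$converged)
    expect_equal(f$tau_c_min, tau, tolerance = 1e-4)
    expect_equal(f$w0, 1.5, tolerance = 1e-4)
    expect_equal(f$w_inf, 0.3, tolerance = 1e-4)
  }
  # units equivariance: rescaling time rescales tau_c
  tr <- exp_trace(45)
  tr$t_min <- tr$t_min / 60
  expect_equal(fit_exponential(tr)$tau_c_min, 45 / 60, tolerance = 1e-6)
  expect_error(fit_exponential(exp_trace(45)[1:3, ]), "too few")
  expect_error(fit_exponential(
    data.frame(t_min = 0:9, width_um = rep(1, 10))), "no decay")
})

test_that("fixing the plateau gives a pure exponential fit", {
  tr <- exp_trace(30, w_inf = 0)
  f <- fit_exponential(tr, fix_w_inf = TRUE)
  expect_equal(f$tau_c_min, 30, tolerance = 1e-4)
  expect_identical(f$w_inf, 0)
})

test_that("condition comparison separates the generator presets", {
  sa <- simulate_bridge_widths(bridge_sim_config("naive", seed = 1))
  sb <- simulate_bridge_widths(bridge_sim_config("exiting", seed = 2))
  f <- compare_conditions(sa$traces, sb$traces, method = "F")
  expect_lt(f$p_value, 1e-4)
  expect_equal(f$tau_a, 45, tolerance = 0.2 * 45)
  expect_equal(f$tau_b, 15, tolerance = 0.2 * 15)
  pm <- compare_conditions(sa$traces, sb$traces, method = "permutation",
                           n_perm = 99, seed = 3)
  expect_lt(pm$p_value, 0.05)   # cross-method agreement at alpha = 0.05
  # trace-order invariance of the F test
  shuf <- sa$traces[rev(seq_len(nrow(sa$traces))), ]
  f2 <- compare_conditions(shuf, sb$traces, method = "F")
  expect_equal(f2$p_value, f$p_value, tolerance = 1e-8)
})

test_that("identical conditions give permutation p = 1 and a calibrated F test", {
  tr <- do.call(rbind, lapply(1:4, function(i)
    exp_trace(30, noise_sd = 0.05, id = paste0("b", i), seed = i)))
  p_same <- compare_conditions(tr, tr, method = "permutation",
                               n_perm = 30, seed = 1)
  expect_equal(p_same$p_value, 1)
  # null calibration (reduced scale): same tau_c in both arms, few rejections
  rej <- vapply(1:20, function(s) {
    a <- simulate_bridge_widths(bridge_sim_config(
      "naive", n_curves = 8, seed = s))
    b <- simulate_bridge_widths(bridge_sim_config(
      "naive", n_curves = 8, seed = s + 1000))
    compare_conditions(a$traces, b$traces, method = "F")$p_value < 0.05
  }, logical(1))
  expect_lte(sum(rej), 5)   # expect ~1 of 20 at the nominal 5% level
  expect_error(compare_conditions(tr[tr$bridge_id == "b1", ], tr,
                                  method = "permutation"), ">= 2 traces")
})

test_that("abscission-duration summary matches a two-pass oracle", {
  s <- abscission_durations(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  d <- simulate_abscission_durations(8.2, 3.8, 1e4, seed = 3)
  s2 <- abscission_durations(d)
  m <- sum(d) / length(d)
  expect_equal(s2$mean, m, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((d - m)^2) / (length(d) - 1)),
               tolerance = 1e-12)
  expect_lt(abs(s2$mean - 8.2), 0.2)
  expect_lt(abs(s2$sd - 3.8), 0.2)
  expect_true(is.na(abscission_durations(5)$sd))
  expect_error(abscission_durations(numeric(0)), "no durations")
})

test_that("bridge fraction summarizes per-frame counts", {
  cnt <- data.frame(frame_id = 1:2, n_cells = c(10, 4), n_bridges = c(0, 2))
  bf <- bridge_fraction(cnt)
  expect_equal(bf$per_frame$fraction, c(0, 0.5))
  sim <- simulate_frame_counts(500, 80, 0.3, seed = 4)
  bf2 <- bridge_fraction(sim)
  expect_lt(abs(bf2$mean - 0.3), 2 * bf2$sem)
  expect_warning(bridge_fraction(
    data.frame(frame_id = 1:2, n_cells = c(0, 5), n_bridges = c(0, 1))),
    "0 cells")
})

test_that("density trend handles monotone, flat and shuffled inputs", {
  expect_equal(density_trend(c(0.5, 0.4, 0.3, 0.2), 1:4)$rho, -1)
  flat <- density_trend(rep(0.3, 5), 1:5)
  expect_equal(flat$rho, 0)
  expect_equal(flat$p, 1)
  expect_false(density_trend(runif(5), rep(2, 5))$defined)
  set.seed(11)
  shuffled <- density_trend(runif(50), runif(50))
  expect_lt(abs(shuffled$rho), 0.3)
})
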