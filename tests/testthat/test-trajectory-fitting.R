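test_that("normalization rescales to a first point of exactly 1", {
  tr <- data.frame(t_h = c(0, 1), intensity_au = c(2, 1))
  expect_equal(normalize_trajectory(tr)$intensity_au, c(1, 0.5))
  # idempotence
  expect_equal(normalize_trajectory(normalize_trajectory(tr)),
               normalize_trajectory(tr))
  tr2 <- data.frame(t_h = 0:5, intensity_au = runif(6, 0.5, 2))
  expect_identical(normalize_trajectory(tr2)$intensity_au[1], 1)
  expect_error(normalize_trajectory(
    data.frame(t_h = 0:2, intensity_au = c(0, 1, 1))), "cannot normalize")
})

test_that("sigmoid fit recovers noiseless parameters and flags bad input", {
  fit <- fit_sigmoid(noiseless_traj(tau = 20, steepness = 2, hi = 1, lo = 0.2))
  expect_true(fit$converged)
  expect_equal(fit$tau_h, 20, tolerance = 1e-6)
  expect_equal(fit$hi, 1, tolerance = 1e-6)
  expect_equal(fit$lo, 0.2, tolerance = 1e-6)
  expect_equal(fit$steepness_h, 2, tolerance = 1e-5)
  expect_equal(fit$onset_h, fit$tau_h - 2 * fit$steepness_h)
  expect_error(fit_sigmoid(data.frame(t_h = 1:5, intensity_au = 5:1)),
               "too few samples")
  expect_error(fit_sigmoid(data.frame(t_h = c(0, 2, 1, 3, 4, 5),
                                      intensity_au = rep(1, 6))),
               "strictly increasing")
})

test_that("a constant trajectory never survives the quality filter", {
  fit <- fit_sigmoid(data.frame(t_h = 0:20, intensity_au = rep(0.8, 21)))
  kept <- filter_fits(fit)
  expect_false(kept$kept)
})

test_that("fitted tau is translation-equivariant and scale-invariant", {
  tr <- noiseless_traj(tau = 18, steepness = 1.5)
  set.seed(5)
  tr$intensity_au <- pmax(tr$intensity_au + rnorm(nrow(tr), 0, 0.03), 0)
  f0 <- fit_sigmoid(tr)
  shifted <- tr; shifted$t_h <- shifted$t_h + 7.5
  expect_equal(fit_sigmoid(shifted)$tau_h, f0$tau_h + 7.5, tolerance = 1e-6)
  scaled <- tr; scaled$intensity_au <- scaled$intensity_au * 13
  expect_equal(fit_sigmoid(scaled)$tau_h, f0$tau_h, tolerance = 1e-6)
})

test_that("filter applies the sigma/tau ratio rule and is monotone", {
  fits <- data.frame(cell_id = c("a", "b", "c", "d"),
                     tau_h = c(20, 20, 20, 20),
                     sigma_tau_h = c(0.2, 24, 6, Inf),
                     converged = c(TRUE, TRUE, TRUE, FALSE),
                     t_min_h = 0, t_max_h = 40)
  out <- filter_fits(fits)                 # default max_ratio = 1
  expect_equal(out$kept, c(TRUE, FALSE, TRUE, FALSE))
  # sigma = 0.01 tau kept; sigma = 1.2 tau discarded (rows a and b)
  # monotonicity: shrinking max_ratio never adds kept fits
  kept_sets <- lapply(c(1, 0.5, 0.2, 0.005), function(r)
    which(filter_fits(fits, max_ratio = r)$kept))
  for (i in seq_len(length(kept_sets) - 1))
    expect_true(all(kept_sets[[i + 1]] %in% kept_sets[[i]]))
  # tau outside the observation window is discarded
  fits$t_max_h <- 15
  expect_false(any(filter_fits(fits)$kept))
  expect_error(filter_fits(fits, max_ratio = 0), "max_ratio")
})

test_that("kept set agrees with an independent multi-start refit", {
  sim <- simulate_lineage(sim_config(n_families = 25, seed = 42))
  fits <- filter_fits(fit_trajectories(sim$trajectories))
  # oracle: refit each trajectory from a grid of tau starts, keep best RSS
  refit_tau <- function(tr) {
    span <- range(tr$t_h)
    best <- NULL
    for (tau0 in seq(span[1] + 2, span[2] - 2, length.out = 5)) {
      f <- tryCatch(minpack.lm::nlsLM(
        intensity_au ~ lo + (hi - lo) / (1 + exp((t_h - tau) / s)),
        data = tr,
        start = list(hi = max(tr$intensity_au), lo = min(tr$intensity_au),
                     tau = tau0, s = 2),
        lower = c(hi = -Inf, lo = -Inf, tau = -Inf, s = 1e-6)),
        error = function(e) NULL)
      if (!is.null(f)) {
        rss <- sum(residuals(f)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
    se <- tryCatch(sqrt(diag(vcov(best$fit)))[["tau"]],
                   error = function(e) Inf)
    c(tau = coef(best$fit)[["tau"]], sigma = se)
  }
  oracle <- t(vapply(split(sim$trajectories, sim$trajectories$cell_id),
                     refit_tau, numeric(2)))
  oracle <- oracle[fits$cell_id, ]
  kept_oracle <- is.finite(oracle[, "sigma"]) &
    oracle[, "sigma"] < oracle[, "tau"] &
    oracle[, "tau"] >= fits$t_min_h & oracle[, "tau"] <= fits$t_max_h
  expect_equal(unname(fits$kept), unname(kept_oracle))
  expect_equal(fits$tau_h[fits$kept],
               unname(oracle[fits$kept, "tau"]), tolerance = 1e-4)
})

test_that("exit-time recovery error stays below the sampling interval", {
  sim <- simulate_lineage(sim_config(n_families = 30, seed = 7))
  fits <- filter_fits(fit_trajectories(sim$trajectories))
  m <- merge(fits[fits$kept, c("cell_id", "tau_h")],
             sim$cells[c("cell_id", "true_tau_h")], by = "cell_id")
  expect_gt(nrow(m), 40)
  expect_lt(median(abs(m$tau_h - m$true_tau_h)), 1)   # sampling interval 1 h
})
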