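# shared fixture builders (all programmatic, no files)

# a noiseless logistic-decay trajectory
noiseless_traj <- function(tau = 20, steepness = 2, hi = 1, lo = 0.2,
                           t = 0:40) {
  data.frame(t_h = t, intensity_au = logistic_decay(t, hi, lo, tau, steepness))
}

# division-coupled exit/division pairs: tau = div + lag + jitter
coupled_pairs <- function(n = 40, lag = 3, jitter_sd = 1, seed = 1) {
  set.seed(seed)
  d1 <- runif(n, 5, 25)
  two <- runif(n) < 0.5
  d2 <- ifelse(two, d1 + rnorm(n, 14, 1.5), NA)
  gate <- ifelse(two, d2, d1)
  tau <- gate + lag + rnorm(n, 0, jitter_sd)
  p <- data.frame(tau_h = tau, d1_h = d1, d2_h = d2)
  p$latest_division_h <- mapply(function(tau, a, b)
    latest_division(tau, c(a, b)[!is.na(c(a, b))]), p$tau_h, p$d1_h, p$d2_h)
  p
}

# exit times independent of division times; exits fall after every division
# (as they do biologically), so the latest- and closest-division rules agree
# and no cell is excluded -- the calibration isolates the bootstrap itself
uncoupled_pairs <- function(n = 40, seed = 1) {
  set.seed(seed)
  d1 <- runif(n, 5, 15)
  two <- runif(n) < 0.5
  d2 <- ifelse(two, d1 + rnorm(n, 10, 1.5), NA)
  tau <- runif(n, 30, 45)
  p <- data.frame(tau_h = tau, d1_h = d1, d2_h = d2)
  p$latest_division_h <- mapply(function(tau, a, b)
    latest_division(tau, c(a, b)[!is.na(c(a, b))]), p$tau_h, p$d1_h, p$d2_h)
  p
}

# direct-formula R^2 of y on x (independent of the package's lm path)
brute_force_r2 <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - (a + b * x))^2) / sum((y - mean(y))^2)
}
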