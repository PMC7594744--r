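#' Configuration for the synthetic bridge-width generator
#'
#' Width of the cytokinetic bridge connecting two sister cells decays
#' exponentially from an initial width `w0` toward a plateau `w_inf` with
#' characteristic (e-folding) time `tau_c`; time 0 is the end of cytokinesis.
#' Two condition presets ship as defaults: `"naive"` cells thin slowly
#' (`tau_c` = 45 min) and `"exiting"` cells (24 h after trigger of
#' naive-pluripotency exit) thin fast (`tau_c` = 15 min).
#'
#' @param condition `"naive"` or `"exiting"`; selects preset `tau_c`,
#'   `n_curves` and plateau. Individual arguments override the preset.
#' @param n_curves number of bridge time courses.
#' @param w0 initial width, micrometres.
#' @param w_inf plateau width, micrometres (0 gives a pure exponential).
#' @param tau_c characteristic time, minutes.
#' @param noise_sd additive Gaussian noise on widths, micrometres.
#' @param sampling_interval imaging interval, minutes.
#' @param duration length of each time course, minutes.
#' @param seed optional integer seed.
#' @return a validated list of class `"bridge_sim_config"`.
#' @export
bridge_sim_config <- function(condition = c("naive", "exiting"),
                              n_curves = NULL, w0 = 1.5, w_inf = NULL,
                              tau_c = NULL, noise_sd = 0.05,
                              sampling_interval = 5, duration = 180,
                              seed = NULL) {
  condition <- match.arg(condition)
  preset <- switch(condition,
                   naive   = list(tau_c = 45, n_curves = 22, w_inf = 0.3),
                   exiting = list(tau_c = 15, n_curves = 55, w_inf = 0.15))
  cfg <- list(condition = condition,
              n_curves = if (is.null(n_curves)) preset$n_curves else n_curves,
              w0 = w0,
              w_inf = if (is.null(w_inf)) preset$w_inf else w_inf,
              tau_c = if (is.null(tau_c)) preset$tau_c else tau_c,
              noise_sd = noise_sd, sampling_interval = sampling_interval,
              duration = duration, seed = seed)
  if (!(cfg$w0 > cfg$w_inf && cfg$w_inf >= 0))
    stop_config("need w0 > w_inf >= 0")
  if (cfg$tau_c <= 0) stop_config("`tau_c` must be > 0")
  if (cfg$noise_sd < 0) stop_config("`noise_sd` must be >= 0")
  if (cfg$n_curves < 1) stop_config("`n_curves` must be >= 1")
  if (cfg$sampling_interval <= 0) stop_config("`sampling_interval` must be > 0")
  structure(cfg, class = "bridge_sim_config")
}

#' Simulate bridge-width time courses
#'
#' `w(t) = w_inf + (w0 - w_inf) exp(-t / tau_c) + noise`, clipped at 0,
#' sampled on a regular grid starting at the end of cytokinesis (t = 0).
#'
#' @param config a [bridge_sim_config()] object.
#' @return list with `traces` (long table `bridge_id`, `condition`, `t_min`,
#'   `width_um`) and `truth` (per bridge: true `w0`, `w_inf`, `tau_c_min`).
#' @examples
#' sim <- simulate_bridge_widths(bridge_sim_config("exiting", seed = 1))
#' head(sim$traces)
#' @export
simulate_bridge_widths <- function(config = bridge_sim_config()) {
  if (!inherits(config, "bridge_sim_config"))
    config <- do.call(bridge_sim_config, config)
  if (config$duration < 2 * config$sampling_interval)
    stop_config("duration too short to fit: need >= 2 sampling intervals")
  with_seed(config$seed, {
    tgrid <- seq(0, config$duration, by = config$sampling_interval)
    ideal <- config$w_inf + (config$w0 - config$w_inf) * exp(-tgrid / config$tau_c)
    traces <- lapply(seq_len(config$n_curves), function(i) {
      w <- ideal
      if (config$noise_sd > 0) w <- w + rnorm(length(tgrid), 0, config$noise_sd)
      data.frame(bridge_id = sprintf("%s_B%03d", config$condition, i),
                 condition = config$condition, t_min = tgrid,
                 width_um = pmax(w, 0), stringsAsFactors = FALSE)
    })
    truth <- data.frame(bridge_id = sprintf("%s_B%03d", config$condition,
                                            seq_len(config$n_curves)),
                        condition = config$condition,
                        w0 = config$w0, w_inf = config$w_inf,
                        tau_c_min = config$tau_c, stringsAsFactors = FALSE)
    list(traces = do.call(rbind, traces), truth = truth, config = config)
  })
}

#' Simulate abscission durations
#'
#' Draws positive abscission durations (time from the end of cytokinesis to
#' dissolution of the microtubule bridge) from a lognormal distribution
#' moment-matched to the requested mean and standard deviation. A lognormal is
#' used because only a mean and sd characterize the measured distributions and
#' durations must be positive. Reference values: 1.5 +/- 0.5 h for HeLa cells,
#' 8.2 +/- 3.8 h for naive ES cells.
#'
#' @param mean,sd target mean and standard deviation, hours; `sd = 0` gives a
#'   degenerate point mass at `mean`.
#' @param n number of durations; `n = 0` returns an empty vector.
#' @param seed optional integer seed.
#' @return numeric vector of durations, hours.
#' @examples
#' mean(simulate_abscission_durations(8.2, 3.8, 1e4, seed = 7))
#' @export
simulate_abscission_durations <- function(mean, sd, n, seed = NULL) {
  if (mean <= 0) stop_config("`mean` must be > 0")
  if (sd < 0) stop_config("`sd` must be >= 0")
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  # lognormal with E = mean, SD = sd
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  with_seed(seed, rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2)))
}

#' Simulate per-frame cell and bridge counts
#'
#' One row per analysis frame, with the bridge count drawn binomially with
#' per-cell probability `bridge_fraction`.
#'
#' @param n_frames number of frames.
#' @param cells_per_frame cells per frame (recycled to `n_frames`).
#' @param bridge_fraction expected bridges per cell, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return data.frame `frame_id`, `n_cells`, `n_bridges`.
#' @export
simulate_frame_counts <- function(n_frames, cells_per_frame, bridge_fraction,
                                  seed = NULL) {
  if (bridge_fraction < 0 || bridge_fraction > 1)
    stop_config("`bridge_fraction` must be in [0, 1]")
  if (any(cells_per_frame < 1)) stop_config("`cells_per_frame` must be >= 1")
  n_cells <- rep_len(cells_per_frame, n_frames)
  with_seed(seed, data.frame(
    frame_id = seq_len(n_frames), n_cells = n_cells,
    n_bridges = rbinom(n_frames, size = n_cells, prob = bridge_fraction)))
}
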