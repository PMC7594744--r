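#' Configuration for the synthetic lineage / reporter-trajectory generator
#'
#' Parameters of the generative model behind [simulate_lineage()]. The model
#' emulates colonies of ES cells tracked by time-lapse after 2i/LIF removal
#' (t = 0): each founder ("mother") cell sits at a random position of its cell
#' cycle when exit is triggered, divides once or twice, and the reporter
#' (REX1-GFP-like) intensity of the pair of cells born at the *gating*
#' division decays sigmoidally around a family exit time. Exit gates at the
#' first division when that division falls late after trigger (i.e. exit was
#' triggered early in the cycle), and at the second division otherwise.
#'
#' @param n_families number of founder cells (each contributes one sister
#'   pair of analyzed trajectories).
#' @param cycle_length_mean,cycle_length_sd cell-cycle length distribution,
#'   hours (normal, truncated at 1 h).
#' @param trigger_phase_model distribution of cell-cycle position at t = 0;
#'   only `"uniform"` is implemented.
#' @param early_late_boundary_h first divisions later than this many hours
#'   after t = 0 mark exit triggered early in the cycle (these families gate
#'   at the first division); default 12 h.
#' @param exit_lag_mean,exit_lag_sd lag, in hours, from the gating division to
#'   the family exit time (normal).
#' @param sister_jitter_sd per-cell jitter, hours, around the shared family
#'   exit time.
#' @param intensity_hi,intensity_lo pre- and post-exit reporter plateaus,
#'   arbitrary units.
#' @param sigmoid_steepness steepness (scale) of the logistic decay, hours.
#' @param noise_sd additive measurement noise on intensities, arbitrary units.
#' @param sampling_interval imaging interval, hours.
#' @param horizon length of the observation window, hours.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return a validated list of class `"sim_config"`.
#' @seealso [simulate_lineage()]
#' @export
sim_config <- function(n_families = 50,
                       cycle_length_mean = 14, cycle_length_sd = 1.5,
                       trigger_phase_model = "uniform",
                       early_late_boundary_h = 12,
                       exit_lag_mean = 3, exit_lag_sd = 2.3,
                       sister_jitter_sd = 1.2,
                       intensity_hi = 1, intensity_lo = 0.2,
                       sigmoid_steepness = 2,
                       noise_sd = 0.05,
                       sampling_interval = 1, horizon = 40,
                       seed = NULL) {
  cfg <- list(n_families = n_families,
              cycle_length_mean = cycle_length_mean,
              cycle_length_sd = cycle_length_sd,
              trigger_phase_model = trigger_phase_model,
              early_late_boundary_h = early_late_boundary_h,
              exit_lag_mean = exit_lag_mean, exit_lag_sd = exit_lag_sd,
              sister_jitter_sd = sister_jitter_sd,
              intensity_hi = intensity_hi, intensity_lo = intensity_lo,
              sigmoid_steepness = sigmoid_steepness,
              noise_sd = noise_sd,
              sampling_interval = sampling_interval, horizon = horizon,
              seed = seed)
  sds <- c("cycle_length_sd", "exit_lag_sd", "sister_jitter_sd", "noise_sd")
  for (s in sds) if (cfg[[s]] < 0) stop_config("`", s, "` must be >= 0")
  if (cfg$n_families < 1) stop_config("`n_families` must be >= 1")
  if (cfg$sampling_interval <= 0) stop_config("`sampling_interval` must be > 0")
  if (cfg$horizon <= 0) stop_config("`horizon` must be > 0")
  if (!(cfg$intensity_hi > cfg$intensity_lo && cfg$intensity_lo >= 0))
    stop_config("need intensity_hi > intensity_lo >= 0")
  if (cfg$sigmoid_steepness <= 0) stop_config("`sigmoid_steepness` must be > 0")
  if (!identical(cfg$trigger_phase_model, "uniform"))
    stop_config("only trigger_phase_model = \"uniform\" is implemented")
  structure(cfg, class = "sim_config")
}

#' Logistic decay curve
#'
#' `I(t) = lo + (hi - lo) / (1 + exp((t - tau) / steepness))`, the functional
#' form used both by the trajectory generator and by [fit_sigmoid()]. Its
#' single inflection is at `t = tau`.
#'
#' @param t time, hours.
#' @param hi,lo upper and lower plateaus.
#' @param tau inflection (exit) time, hours.
#' @param steepness logistic scale, hours.
#' @export
logistic_decay <- function(t, hi, lo, tau, steepness) {
  lo + (hi - lo) / (1 + exp((t - tau) / steepness))
}

#' Simulate division-coupled reporter trajectories for a set of lineages
#'
#' Generates, per founder cell, its division time(s), the gating rule label,
#' a family exit time (gating division + lag) and two sister trajectories
#' sampled on a regular grid with additive Gaussian noise, clipped at 0.
#' Sister coupling is modeled as the shared family exit time plus independent
#' per-cell jitter. Daughter volumes (smaller/larger ratio drawn Beta(5, 2),
#' independent of exit timing) are emitted so asymmetry statistics can be
#' exercised.
#'
#' @param config a [sim_config()] object.
#' @return a list with components
#' \describe{
#'   \item{cells}{per analyzed cell: `cell_id`, `parent_id`, `family`,
#'     `d1_h`, `d2_h` (NA when the family gates at the first division),
#'     `gate` (`"first"`/`"second"`), `gating_division_h`, `stage`
#'     (`"early-cycle"`/`"late-cycle"`), `true_tau_h`, `volume_au`,
#'     `volume_ratio`.}
#'   \item{trajectories}{long table `cell_id`, `t_h`, `intensity_au`;
#'     t = 0 is 2i/LIF removal.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_lineage(sim_config(n_families = 5, seed = 1))
#' head(sim$cells)
#' @export
simulate_lineage <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (config$horizon < config$cycle_length_mean)
    stop_config("horizon too short: must cover at least one mean cell cycle")
  with_seed(config$seed, {
    nf <- config$n_families
    rcycle <- function(n)
      pmax(1, rnorm(n, config$cycle_length_mean, config$cycle_length_sd))
    c1 <- rcycle(nf); c2 <- rcycle(nf)
    phase <- runif(nf)                   # fraction of cycle already elapsed
    d1 <- (1 - phase) * c1               # first division after trigger
    d2 <- d1 + c2
    gate_first <- d1 > config$early_late_boundary_h
    gating_div <- ifelse(gate_first, d1, d2)
    stage <- ifelse(gate_first, "early-cycle", "late-cycle")
    lag <- rnorm(nf, config$exit_lag_mean, config$exit_lag_sd)
    family_tau <- gating_div + lag
    ratio <- stats::rbeta(nf, 5, 2)      # smaller/larger daughter volume
    small_is_a <- runif(nf) < 0.5

    tgrid <- seq(0, config$horizon, by = config$sampling_interval)
    cells <- vector("list", nf); trajs <- vector("list", nf)
    for (f in seq_len(nf)) {
      mother <- sprintf("F%03d_M", f)
      parent <- if (gate_first[f]) mother else sprintf("F%03d_D1", f)
      suffix <- if (gate_first[f]) c("D1", "D2") else c("GD1", "GD2")
      ids <- sprintf("F%03d_%s", f, suffix)
      tau_cell <- family_tau[f] + rnorm(2, 0, config$sister_jitter_sd)
      vols <- 2 / (1 + ratio[f]) * c(1, ratio[f])      # larger, smaller
      if (small_is_a[f]) vols <- rev(vols)
      cells[[f]] <- data.frame(
        cell_id = ids, parent_id = parent, family = f,
        d1_h = d1[f], d2_h = if (gate_first[f]) NA_real_ else d2[f],
        gate = if (gate_first[f]) "first" else "second",
        gating_division_h = gating_div[f], stage = stage[f],
        true_tau_h = tau_cell, volume_au = vols,
        volume_ratio = ratio[f], stringsAsFactors = FALSE)
      for (k in 1:2) {
        y <- logistic_decay(tgrid, config$intensity_hi, config$intensity_lo,
                            tau_cell[k], config$sigmoid_steepness)
        if (config$noise_sd > 0) y <- y + rnorm(length(tgrid), 0, config$noise_sd)
        trajs[[f]][[k]] <- data.frame(cell_id = ids[k], t_h = tgrid,
                                      intensity_au = pmax(y, 0),
                                      stringsAsFactors = FALSE)
      }
    }
    list(cells = do.call(rbind, cells),
         trajectories = do.call(rbind, unlist(trajs, recursive = FALSE)),
         config = config)
  })
}
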