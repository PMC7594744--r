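#' Normalize a reporter trajectory to its first time point
#'
#' Divides every intensity by the first one, so the curve starts at exactly 1.
#' Normalization removes cell-to-cell differences in absolute reporter
#' expression before variance statistics are computed.
#'
#' @param traj data.frame with columns `t_h` and `intensity_au` (a single
#'   cell's trajectory, times increasing).
#' @return the trajectory with `intensity_au` rescaled.
#' @export
normalize_trajectory <- function(traj) {
  check_trajectory(traj, min_points = 1)
  first <- traj$intensity_au[[1]]
  if (!is.finite(first) || first <= 0)
    stop("cannot normalize: first intensity must be > 0", call. = FALSE)
  traj$intensity_au <- traj$intensity_au / first
  traj
}

check_trajectory <- function(traj, min_points = 6) {
  if (!all(c("t_h", "intensity_au") %in% names(traj)))
    stop("trajectory needs columns `t_h` and `intensity_au`", call. = FALSE)
  if (nrow(traj) < min_points)
    stop("too few samples: need at least ", min_points, " points", call. = FALSE)
  if (any(diff(traj$t_h) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(traj$intensity_au < 0))
    stop("intensities must be >= 0", call. = FALSE)
  invisible(traj)
}

#' Fit a sigmoidal decay to one reporter trajectory
#'
#' Least-squares fit of the 4-parameter logistic decay
#' `I(t) = lo + (hi - lo) / (1 + exp((t - tau) / steepness))` (see
#' [logistic_decay()]). The exit time tau is the inflection of the fitted
#' curve — a logistic has exactly one — and its standard error `sigma_tau_h`
#' comes from the Jacobian-based parameter covariance at the optimum. An
#' "onset" reading of the curve (`tau - 2 steepness`, where the decay first
#' departs visibly from the upper plateau) is reported as `onset_h` for
#' completeness; tau is the primary estimate.
#'
#' Starting values: `hi` = max of the first 3 points, `lo` = min of the last
#' 3 points, `tau` = time of half-crossing, `steepness` = 10% of the time
#' span; optimization is bounded with `steepness > 0`. Non-convergence (or a
#' singular covariance) is flagged, never raised.
#'
#' @param traj data.frame with `t_h`, `intensity_au` (>= 6 points, strictly
#'   increasing times) and optionally `cell_id`.
#' @return one-row data.frame: `cell_id`, `hi`, `lo`, `tau_h`, `steepness_h`,
#'   `sigma_tau_h`, `onset_h`, `rss`, `converged`, `kept` (NA until
#'   [filter_fits()] is applied), `t_min_h`, `t_max_h`.
#' @examples
#' t <- 0:40
#' y <- logistic_decay(t, 1, 0.2, 20, 2)
#' fit_sigmoid(data.frame(t_h = t, intensity_au = y))
#' @export
fit_sigmoid <- function(traj) {
  check_trajectory(traj, min_points = 6)
  tt <- traj$t_h; yy <- traj$intensity_au
  cell_id <- if ("cell_id" %in% names(traj)) traj$cell_id[[1]] else NA_character_
  hi0 <- max(yy[1:3]); lo0 <- min(tail(yy, 3))
  half <- (hi0 + lo0) / 2
  below <- which(yy <= half)
  tau_half <- if (length(below)) tt[below[1]] else stats::median(tt)
  # half-crossing first, quartiles of the window as fallback starts
  tau_starts <- unique(c(tau_half,
                         unname(stats::quantile(tt, c(0.25, 0.5, 0.75)))))
  s0 <- 0.1 * diff(range(tt))
  out <- data.frame(cell_id = cell_id, hi = NA_real_, lo = NA_real_,
                    tau_h = NA_real_, steepness_h = NA_real_,
                    sigma_tau_h = Inf, onset_h = NA_real_, rss = NA_real_,
                    converged = FALSE, kept = NA,
                    t_min_h = min(tt), t_max_h = max(tt),
                    stringsAsFactors = FALSE)
  fit <- NULL
  for (tau0 in tau_starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ lo + (hi - lo) / (1 + exp((tt - tau) / steepness)),
        start = list(hi = hi0, lo = lo0, tau = tau0, steepness = s0),
        lower = c(hi = -Inf, lo = -Inf, tau = -Inf, steepness = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) ||
         sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2) - 1e-12))
      fit <- cand
  }
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  # enforce the decaying orientation: hi is the pre-exit plateau
  if (cf[["hi"]] < cf[["lo"]]) {
    # a rising fit means no decay signal; keep values, flag via sigma below
    cf[c("hi", "lo")] <- cf[c("lo", "hi")]
  }
  out$hi <- cf[["hi"]]; out$lo <- cf[["lo"]]
  out$tau_h <- cf[["tau"]]; out$steepness_h <- cf[["steepness"]]
  out$onset_h <- cf[["tau"]] - 2 * cf[["steepness"]]
  out$rss <- sum(stats::residuals(fit)^2)
  out$converged <- TRUE
  out$sigma_tau_h <- tryCatch({
    se <- sqrt(diag(vcov(fit)))[["tau"]]
    if (is.finite(se)) se else Inf
  }, error = function(e) Inf)
  out
}

#' Fit sigmoidal decays to a table of trajectories
#'
#' @param trajectories long table `cell_id`, `t_h`, `intensity_au`.
#' @return data.frame of per-cell [fit_sigmoid()] rows.
#' @export
fit_trajectories <- function(trajectories) {
  ids <- unique(trajectories$cell_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- trajectories[trajectories$cell_id == id, , drop = FALSE]
    f <- fit_sigmoid(tr[order(tr$t_h), , drop = FALSE])
    f$cell_id <- id
    f
  }))
}

#' Quality-filter sigmoid fits
#'
#' Keeps a fit when it converged, its exit-time uncertainty is small relative
#' to the exit time itself (`sigma_tau_h < max_ratio * tau_h`; curves whose
#' error of fit is on the order of tau carry no usable exit time), and tau
#' lies inside the observation window. Row order is preserved.
#'
#' @param fits data.frame from [fit_trajectories()] / [fit_sigmoid()].
#' @param max_ratio discard threshold on `sigma_tau_h / tau_h` (> 0);
#'   default 1.
#' @return `fits` with the logical column `kept` filled in.
#' @export
filter_fits <- function(fits, max_ratio = 1) {
  if (!is.numeric(max_ratio) || max_ratio <= 0)
    stop_config("`max_ratio` must be > 0")
  fits$kept <- fits$converged &
    is.finite(fits$sigma_tau_h) &
    fits$sigma_tau_h < max_ratio * fits$tau_h &
    fits$tau_h >= fits$t_min_h & fits$tau_h <= fits$t_max_h
  fits$kept[is.na(fits$kept)] <- FALSE
  fits
}
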