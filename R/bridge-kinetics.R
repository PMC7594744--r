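#' Fit exponential decay to a bridge-width time course
#'
#' Least-squares fit of `w(t) = w_inf + (w0 - w_inf) exp(-t / tau_c)` with
#' bounds `w_inf >= 0`, `tau_c > 0`. `tau_c` is the characteristic
#' (e-folding) time of bridge thinning. For sparse traces the plateau can be
#' fixed to 0 (`fix_w_inf = TRUE`) to avoid overparameterization.
#'
#' @param trace data.frame with `t_min` (increasing) and `width_um` (>= 0);
#'   at least 4 points.
#' @param fix_w_inf fit a pure exponential with `w_inf = 0`.
#' @return one-row data.frame `bridge_id`, `condition`, `w0`, `w_inf`,
#'   `tau_c_min`, `rss`, `converged`.
#' @examples
#' t <- seq(0, 180, 5)
#' w <- 0.3 + 1.2 * exp(-t / 45)
#' fit_exponential(data.frame(t_min = t, width_um = w))
#' @export
fit_exponential <- function(trace, fix_w_inf = FALSE) {
  if (!all(c("t_min", "width_um") %in% names(trace)))
    stop("trace needs columns `t_min` and `width_um`", call. = FALSE)
  if (nrow(trace) < 4) stop("too few samples: need at least 4 points",
                            call. = FALSE)
  if (any(diff(trace$t_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(trace$width_um < 0)) stop("widths must be >= 0", call. = FALSE)
  tt <- trace$t_min; ww <- trace$width_um
  if (var(ww) == 0) stop("no decay: constant trace", call. = FALSE)
  bridge_id <- if ("bridge_id" %in% names(trace)) trace$bridge_id[[1]] else NA
  condition <- if ("condition" %in% names(trace)) trace$condition[[1]] else NA
  w0_0 <- ww[[1]]
  winf_0 <- if (fix_w_inf) 0 else max(min(tail(ww, 3)), 0)
  out <- data.frame(bridge_id = bridge_id, condition = condition,
                    w0 = NA_real_, w_inf = NA_real_, tau_c_min = NA_real_,
                    rss = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  fit <- NULL
  for (tau0 in .tau_starts(tt, ww, winf_0)) {
    fit <- tryCatch({
      if (fix_w_inf)
        minpack.lm::nlsLM(ww ~ w0 * exp(-tt / tau_c),
                          start = list(w0 = w0_0, tau_c = tau0),
                          lower = c(w0 = 0, tau_c = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(ww ~ w_inf + (w0 - w_inf) * exp(-tt / tau_c),
                          start = list(w0 = w0_0, w_inf = winf_0, tau_c = tau0),
                          lower = c(w0 = 0, w_inf = 0, tau_c = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$w0 <- cf[["w0"]]
  out$w_inf <- if (fix_w_inf) 0 else cf[["w_inf"]]
  out$tau_c_min <- cf[["tau_c"]]
  out$rss <- sum(stats::residuals(fit)^2)
  out$converged <- TRUE
  out
}

#' Fit exponentials to every bridge in a long trace table
#'
#' @param traces long table `bridge_id`, `condition`, `t_min`, `width_um`.
#' @param fix_w_inf passed to [fit_exponential()].
#' @return data.frame of per-bridge fits.
#' @export
fit_bridge_traces <- function(traces, fix_w_inf = FALSE) {
  ids <- unique(traces$bridge_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- traces[traces$bridge_id == id, , drop = FALSE]
    fit_exponential(tr[order(tr$t_min), , drop = FALSE], fix_w_inf = fix_w_inf)
  }))
}

# starting values for tau_c: 1/e-crossing of the (plateau-corrected) trace,
# then coarser fractions of the time span as fallbacks
.tau_starts <- function(tt, ww, winf_0) {
  span <- diff(range(tt))
  target <- winf_0 + (ww[[1]] - winf_0) / exp(1)
  cross <- tt[which(ww <= target)[1]]
  starts <- c(cross, span / 10, span / 3)
  unique(pmax(starts[is.finite(starts)], min(diff(tt)) / 2, 1e-3))
}

# pooled per-condition exponential fit; returns list(coef, rss, n)
.pooled_exp_fit <- function(tt, ww) {
  m <- tapply(ww, tt, mean)             # mean curve guides initialization
  tm <- as.numeric(names(m))
  winf_0 <- max(min(m), 0)
  fit <- NULL; last_err <- NULL
  for (tau0 in .tau_starts(tm, as.numeric(m), winf_0)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      ww ~ w_inf + (w0 - w_inf) * exp(-tt / tau_c),
      start = list(w0 = m[[1]], w_inf = winf_0, tau_c = tau0),
      lower = c(w0 = 0, w_inf = 0, tau_c = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop(last_err)
  list(coef = coef(fit), rss = sum(stats::residuals(fit)^2), n = length(ww))
}

#' Compare bridge-thinning characteristic times between two conditions
#'
#' Pools every trace of a condition and fits one exponential per condition.
#' Two tests of "same characteristic time" are provided:
#' \describe{
#'   \item{`"F"` (default)}{extra-sum-of-squares F test between the nested
#'     models: a null fit sharing one `tau_c` across conditions (separate
#'     amplitudes/plateaus) versus the full fit with a `tau_c` per
#'     condition.}
#'   \item{`"permutation"`}{condition labels are shuffled across traces;
#'     the statistic is `|log(tau_A / tau_B)|` of the pooled per-condition
#'     fits, and the p-value is the add-one exceedance fraction.}
#' }
#'
#' @param traces_a,traces_b long trace tables (`bridge_id`, `t_min`,
#'   `width_um`) for the two conditions.
#' @param method `"F"` or `"permutation"`.
#' @param n_perm permutation count (permutation method only); default 199.
#' @param seed optional integer seed (permutation method only).
#' @return list `tau_a`, `tau_b` (pooled per-condition characteristic times,
#'   minutes), `method`, `p_value`, plus `f_statistic`/`df` (F method) or
#'   `statistic`/`n_perm` (permutation method).
#' @export
compare_conditions <- function(traces_a, traces_b,
                               method = c("F", "permutation"),
                               n_perm = 199, seed = NULL) {
  method <- match.arg(method)
  if (nrow(traces_a) == 0 || nrow(traces_b) == 0)
    stop("both conditions must be non-empty", call. = FALSE)
  fa <- .pooled_exp_fit(traces_a$t_min, traces_a$width_um)
  fb <- .pooled_exp_fit(traces_b$t_min, traces_b$width_um)
  tau_a <- fa$coef[["tau_c"]]; tau_b <- fb$coef[["tau_c"]]
  if (method == "F") {
    tt <- c(traces_a$t_min, traces_b$t_min)
    ww <- c(traces_a$width_um, traces_b$width_um)
    is_a <- rep(c(1, 0), c(nrow(traces_a), nrow(traces_b)))
    null_fit <- minpack.lm::nlsLM(
      ww ~ is_a * (ai + (a0 - ai) * exp(-tt / tau_s)) +
        (1 - is_a) * (bi + (b0 - bi) * exp(-tt / tau_s)),
      start = list(a0 = fa$coef[["w0"]], ai = fa$coef[["w_inf"]],
                   b0 = fb$coef[["w0"]], bi = fb$coef[["w_inf"]],
                   tau_s = (tau_a + tau_b) / 2),
      lower = c(a0 = 0, ai = 0, b0 = 0, bi = 0, tau_s = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    rss0 <- sum(stats::residuals(null_fit)^2)
    rss1 <- fa$rss + fb$rss
    df1 <- 1                      # one extra parameter in the full model
    df2 <- length(ww) - 6
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
    list(tau_a = tau_a, tau_b = tau_b, method = "F", p_value = p,
         f_statistic = f, df = c(df1, df2))
  } else {
    na <- length(unique(traces_a$bridge_id))
    nb <- length(unique(traces_b$bridge_id))
    if (na < 2 || nb < 2)
      stop("permutation method needs >= 2 traces per condition", call. = FALSE)
    obs <- abs(log(tau_a / tau_b))
    traces_a$bridge_id <- paste0("A.", traces_a$bridge_id)
    traces_b$bridge_id <- paste0("B.", traces_b$bridge_id)
    pool <- rbind(traces_a[c("bridge_id", "t_min", "width_um")],
                  traces_b[c("bridge_id", "t_min", "width_um")])
    ids <- unique(pool$bridge_id)
    perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      lab_a <- sample(ids, na)
      pa <- pool[pool$bridge_id %in% lab_a, , drop = FALSE]
      pb <- pool[!(pool$bridge_id %in% lab_a), , drop = FALSE]
      ta <- tryCatch(.pooled_exp_fit(pa$t_min, pa$width_um)$coef[["tau_c"]],
                     error = function(e) NA_real_)
      tb <- tryCatch(.pooled_exp_fit(pb$t_min, pb$width_um)$coef[["tau_c"]],
                     error = function(e) NA_real_)
      abs(log(ta / tb))
    }, numeric(1)))
    perm_stats <- perm_stats[is.finite(perm_stats)]
    p <- (1 + sum(perm_stats >= obs)) / (1 + length(perm_stats))
    list(tau_a = tau_a, tau_b = tau_b, method = "permutation", p_value = p,
         statistic = obs, n_perm = length(perm_stats))
  }
}

#' Summarize abscission durations
#'
#' @param durations numeric vector of abscission durations (>= 0), hours.
#' @return list `mean`, `sd` (sample, n-1 denominator; `NA` for a single
#'   event), `n`.
#' @examples
#' abscission_durations(c(1, 2, 3))
#' @export
abscission_durations <- function(durations) {
  if (length(durations) == 0) stop("no durations supplied", call. = FALSE)
  if (any(durations < 0)) stop("durations must be >= 0", call. = FALSE)
  list(mean = mean(durations),
       sd = if (length(durations) > 1) sd(durations) else NA_real_,
       n = length(durations))
}

#' Fraction of cells with bridges, per frame and pooled
#'
#' `fraction = n_bridges / n_cells` in each analysis frame; frames with zero
#' cells are excluded with a warning. The pooled summary is the mean fraction
#' across frames with its standard error.
#'
#' @param counts data.frame `frame_id`, `n_cells`, `n_bridges`.
#' @return list `per_frame` (input plus `fraction`), `mean`, `sem`, `n_frames`.
#' @export
bridge_fraction <- function(counts) {
  stopifnot(all(c("n_cells", "n_bridges") %in% names(counts)))
  bad <- counts$n_cells == 0
  if (any(bad)) {
    warning(sum(bad), " frame(s) with 0 cells excluded")
    counts <- counts[!bad, , drop = FALSE]
  }
  counts$fraction <- counts$n_bridges / counts$n_cells
  n <- nrow(counts)
  list(per_frame = counts, mean = mean(counts$fraction),
       sem = if (n > 1) sd(counts$fraction) / sqrt(n) else NA_real_,
       n_frames = n)
}

#' Rank correlation of bridge fraction with a covariate
#'
#' Spearman correlation of per-frame (or per-timepoint) bridge fractions
#' against a covariate such as cell density or time in differentiation
#' medium.
#'
#' @param fractions numeric vector of bridge fractions.
#' @param covariate numeric covariate, same length.
#' @return list `rho`, `p`, `n`, `defined` (`FALSE`, with `NA` statistics,
#'   when either variable is constant).
#' @export
density_trend <- function(fractions, covariate) {
  if (length(fractions) != length(covariate))
    stop("inputs must have equal length", call. = FALSE)
  if (length(fractions) < 3) stop("need >= 3 points", call. = FALSE)
  if (sd(covariate) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(fractions),
                defined = FALSE))
  if (sd(fractions) == 0)
    # no trend in a flat response: rho 0, p 1 under any permutation
    return(list(rho = 0, p = 1, n = length(fractions), defined = TRUE))
  ct <- suppressWarnings(cor.test(fractions, covariate, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(fractions),
       defined = TRUE)
}
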