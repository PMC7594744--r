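#' Smooth a FRAP trace with a trailing moving average
#'
#' Moving average over the trailing `window` samples (shorter at the start of
#' the trace, so the length is preserved). A trailing window is used because
#' an even-width centered window has no natural alignment.
#'
#' @param trace data.frame with `t_s` (increasing) and `intensity_norm`.
#' @param window number of samples; default 4 (about 4.5 s at the usual
#'   1.1 s frame interval).
#' @return the trace with `intensity_norm` smoothed.
#' @export
smooth_trace <- function(trace, window = 4) {
  if (!is.numeric(window) || window < 1) stop_config("`window` must be >= 1")
  window <- as.integer(window)
  y <- trace$intensity_norm
  cs <- cumsum(y)
  i <- seq_along(y)
  lo <- pmax(i - window + 1L, 1L)
  trace$intensity_norm <- (cs - c(0, cs)[lo]) / (i - lo + 1L)
  trace
}

#' Normalize a FRAP trace to its pre-bleach level
#'
#' Divides the whole trace by the mean of the pre-bleach samples
#' (`t_s < 0`), so the pre-bleach level becomes exactly 1. This removes
#' cell-to-cell variability in absolute GFP expression.
#'
#' @param trace data.frame with `t_s` and `intensity_norm`; at least one
#'   sample with `t_s < 0` and positive pre-bleach mean.
#' @return the normalized trace.
#' @export
normalize_frap <- function(trace) {
  pre <- trace$intensity_norm[trace$t_s < 0]
  if (length(pre) == 0) stop("no pre-bleach samples (t_s < 0)", call. = FALSE)
  m <- mean(pre)
  if (!is.finite(m) || m <= 0)
    stop("non-positive pre-bleach mean", call. = FALSE)
  trace$intensity_norm <- trace$intensity_norm / m
  trace
}

#' Post-bleach minimum of a FRAP trace
#'
#' The minimum intensity reached after the bleach (`t_s >= 0`). In a sister
#' cell connected to the bleached cell by a bridge this minimum drops below 1
#' because cytoplasm is exchanged; in an unconnected neighbor it stays near 1.
#'
#' @param trace a normalized (and typically smoothed) trace with `t_s`,
#'   `intensity_norm`.
#' @return scalar minimum.
#' @export
post_bleach_minimum <- function(trace) {
  post <- trace$intensity_norm[trace$t_s >= 0]
  if (length(post) == 0) stop("no post-bleach samples", call. = FALSE)
  min(post)
}

#' Post-bleach minima for a set of FRAP traces, optionally versus bridge width
#'
#' Normalizes, smooths (smoothing first, then the minimum is read off the
#' smoothed curve; set `window = 1` to disable) and extracts the post-bleach
#' minimum of every trace. When bridge widths are supplied, the Pearson
#' correlation of minimum versus width across traces is reported — a test of
#' whether wider bridges transfer visibly more cytoplasm.
#'
#' @param traces long table `trace_id`, `role`, `t_s`, `intensity_norm`.
#' @param window smoothing window in samples; default 4.
#' @param bridge_widths optional named numeric vector (names = trace ids),
#'   micrometres.
#' @return list `minima` (data.frame `trace_id`, `role`, `min_norm`, and
#'   `bridge_width_um` when supplied) and `width_correlation` (list `r`,
#'   `p`, `n`, or `NULL` when widths are absent).
#' @export
frap_minima <- function(traces, window = 4, bridge_widths = NULL) {
  sp <- split(traces, traces$trace_id)
  minima <- do.call(rbind, lapply(sp, function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    sm <- smooth_trace(normalize_frap(tr), window = window)
    data.frame(trace_id = tr$trace_id[[1]], role = tr$role[[1]],
               min_norm = post_bleach_minimum(sm), stringsAsFactors = FALSE)
  }))
  row.names(minima) <- NULL
  width_correlation <- NULL
  if (!is.null(bridge_widths)) {
    minima$bridge_width_um <- unname(bridge_widths[minima$trace_id])
    ok <- is.finite(minima$bridge_width_um)
    if (sum(ok) >= 3) {
      ct <- cor.test(minima$min_norm[ok], minima$bridge_width_um[ok])
      width_correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                                n = sum(ok))
    }
  }
  list(minima = minima, width_correlation = width_correlation)
}
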