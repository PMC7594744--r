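#' Latest division before (or shortly after) a cell's exit time
#'
#' Returns the largest division time that is no later than `tau + grace`.
#' The grace window absorbs the experimental uncertainty in determining the
#' exit time, so a division just after the estimated tau still counts as
#' preceding exit. When no division qualifies, `NA` is returned and the cell
#' is excluded from downstream regression.
#'
#' @param tau exit time, hours.
#' @param division_times non-empty numeric vector of division times, hours.
#' @param grace window after tau within which a division still qualifies,
#'   hours; default 2.5.
#' @return the qualifying division time (hours), or `NA_real_`.
#' @examples
#' latest_division(25, c(10, 24))   # 24
#' latest_division(25, c(10, 29))   # 10: 29 is past the grace window
#' latest_division(5, 10)           # NA: no qualifying division
#' @export
latest_division <- function(tau, division_times, grace = 2.5) {
  if (length(division_times) == 0)
    stop("`division_times` must be non-empty", call. = FALSE)
  ok <- division_times <= tau + grace
  if (!any(ok)) return(NA_real_)
  max(division_times[ok])
}

#' Ordinary least-squares regression of exit time on latest division time
#'
#' @param pairs data.frame with columns `tau_h` and `latest_division_h`
#'   (rows with `NA` in either are dropped); >= 3 complete pairs required.
#' @return list `slope`, `intercept`, `r_squared`, `n_cells`.
#' @export
regress_exit_vs_division <- function(pairs) {
  d <- pairs[complete.cases(pairs[, c("tau_h", "latest_division_h")]), ,
             drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 pairs with a defined latest division",
                        call. = FALSE)
  x <- d$latest_division_h; y <- d$tau_h
  if (var(x) == 0) stop("degenerate regressor: all latest divisions equal",
                        call. = FALSE)
  fit <- lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - rss / tss, n_cells = nrow(d))
}

# R^2 of y on each column of X (simple regression); zero-variance columns -> 0
.r2_columns <- function(y, X) {
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  r2 <- (colSums(yc * Xc))^2 / (sum(yc^2) * sxx)
  r2[sxx == 0] <- 0
  r2
}

#' Reassignment bootstrap null for the exit-division correlation
#'
#' Tests whether the observed regression R-squared between exit time and
#' latest division time could arise by chance. Each replicate reassigns every
#' cell's exit time to the division times of an independently, uniformly
#' drawn cell (with replacement, self-assignment allowed); within a
#' replicate, when the drawn cell has two divisions, the one closest to the
#' exit time is used. The empirical p is the fraction of replicate R-squared
#' values at or above the observed one (one-sided: could the observed
#' correlation be matched by chance?).
#'
#' A replicate whose resampled regressor is constant carries no linear
#' structure and is assigned R-squared 0.
#'
#' @param pairs data.frame with `tau_h`, `d1_h`, `d2_h` (`d2_h` `NA` for
#'   single-division cells) and `latest_division_h` (used for the observed
#'   statistic; rows with `NA` there are excluded throughout).
#' @param n_boot number of replicates; default 1000.
#' @param seed optional integer seed.
#' @param corrected if `TRUE`, also report the add-one corrected p,
#'   `(1 + k)/(1 + n_boot)`.
#' @return list of class `"coupling_result"`: `r_squared`, `slope`,
#'   `intercept`, `n_cells`, `n_excluded`, `boot_r_squared`
#'   (length `n_boot`), `p_empirical`, optionally `p_corrected`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_null <- function(pairs, n_boot = 1000, seed = NULL,
                           corrected = FALSE) {
  if (n_boot < 1) stop_config("`n_boot` must be >= 1")
  obs <- regress_exit_vs_division(pairs)
  keep <- !is.na(pairs$latest_division_h) & !is.na(pairs$tau_h)
  d <- pairs[keep, , drop = FALSE]
  n <- nrow(d)
  tau <- d$tau_h; d1 <- d$d1_h; d2 <- d$d2_h
  boot <- with_seed(seed, {
    # vectorized over replicates: n x n_boot donor index matrix
    J <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    D1 <- matrix(d1[J], nrow = n)
    D2 <- matrix(d2[J], nrow = n)
    use2 <- !is.na(D2) & (abs(D2 - tau) < abs(D1 - tau))
    X <- ifelse(use2, D2, D1)
    .r2_columns(tau, X)
  })
  res <- list(r_squared = obs$r_squared, slope = obs$slope,
              intercept = obs$intercept, n_cells = n,
              n_excluded = nrow(pairs) - n,
              boot_r_squared = boot,
              p_empirical = mean(boot >= obs$r_squared),
              n_boot = n_boot, seed = seed)
  if (corrected)
    res$p_corrected <- (1 + sum(boot >= obs$r_squared)) / (1 + n_boot)
  structure(res, class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("Exit-division coupling: R^2 = %.3f (slope %.2f, n = %d",
              x$r_squared, x$slope, x$n_cells))
  if (x$n_excluded > 0) cat(sprintf(", %d excluded", x$n_excluded))
  cat(sprintf(")\nBootstrap null (%d replicates): p = %.4g\n",
              x$n_boot, x$p_empirical))
  invisible(x)
}

#' Classify exit relative to divisions and cell-cycle stage at trigger
#'
#' Labels each cell by where its exit time falls relative to its divisions:
#' within `window` hours of the first division, within `window` hours of the
#' second, or in between (ties — tau within the window of both — go to the
#' nearer division). Each cell is also labelled by cell-cycle stage at
#' trigger: `"early-cycle"` when the first division happens more than
#' `boundary` hours after trigger, `"late-cycle"` otherwise (a first division
#' at exactly `boundary` counts as late-cycle).
#'
#' @param cells data.frame with `tau_h`, `d1_h` and optional `d2_h`.
#' @param window half-width of the division window, hours; default 4.
#' @param boundary early/late boundary on the first-division time, hours;
#'   default 12.
#' @return list with `cells` (input plus `category`, `stage`) and
#'   `percentages` (per-stage percentage of cells in each category).
#' @examples
#' classify_exit_division(data.frame(tau_h = 15, d1_h = 14, d2_h = 26))
#' @export
classify_exit_division <- function(cells, window = 4, boundary = 12) {
  stopifnot(all(c("tau_h", "d1_h") %in% names(cells)))
  d2 <- if ("d2_h" %in% names(cells)) cells$d2_h else rep(NA_real_, nrow(cells))
  a1 <- abs(cells$tau_h - cells$d1_h)
  a2 <- abs(cells$tau_h - d2)
  in1 <- a1 <= window
  in2 <- !is.na(d2) & a2 <= window
  category <- rep("between", nrow(cells))
  category[in1 & !in2] <- "first"
  category[in2 & !in1] <- "second"
  both <- in1 & in2
  category[both] <- ifelse(a1[both] <= a2[both], "first", "second")[seq_len(sum(both))]
  stage <- ifelse(cells$d1_h > boundary, "early-cycle", "late-cycle")
  cells$category <- factor(category, levels = c("first", "second", "between"))
  cells$stage <- factor(stage, levels = c("early-cycle", "late-cycle"))
  pct <- 100 * prop.table(table(cells$stage, cells$category), margin = 1)
  list(cells = cells, percentages = pct)
}
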