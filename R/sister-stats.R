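#' Time-averaged population variance of normalized trajectories
#'
#' At every time point, the variance across all cells around the population
#' mean (population convention, divide by n); variances are then averaged
#' across time. This "global" variance is the spread that would be seen
#' between any two cells if being sisters carried no information.
#'
#' @param trajectories long table `cell_id`, `t_h`, `intensity_au`; all cells
#'   must share an identical time grid (resampling is the caller's job).
#' @return scalar time-averaged variance.
#' @export
global_variance <- function(trajectories) {
  M <- trajectory_matrix(trajectories)
  if (ncol(M) < 2) stop("need >= 2 cells", call. = FALSE)
  mean(rowMeans((M - rowMeans(M))^2))
}

#' Time-averaged variance between the two cells of a sister pair
#'
#' Same convention as [global_variance()] (population variance, divide by n),
#' so a sister pair and a 2-cell population give identical numbers and the
#' two statistics are directly comparable.
#'
#' @param traj_a,traj_b the two sisters' trajectories (`t_h`,
#'   `intensity_au`), on identical time grids.
#' @return scalar time-averaged variance.
#' @export
pair_variance <- function(traj_a, traj_b) {
  a <- traj_a[order(traj_a$t_h), , drop = FALSE]
  b <- traj_b[order(traj_b$t_h), , drop = FALSE]
  if (nrow(a) != nrow(b) || any(a$t_h != b$t_h))
    stop("time grids not aligned", call. = FALSE)
  # population variance of two values: ((a-m)^2 + (b-m)^2)/2 = (a-b)^2/4
  mean((a$intensity_au - b$intensity_au)^2 / 4)
}

# cells x time matrix from a long trajectory table; errors if grids differ
trajectory_matrix <- function(trajectories) {
  sp <- split(trajectories, trajectories$cell_id)
  grids <- lapply(sp, function(d) sort(d$t_h))
  g0 <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(g0) && all(g == g0),
                 logical(1))
  if (!all(same)) stop("time grids not aligned", call. = FALSE)
  vapply(sp, function(d) d$intensity_au[order(d$t_h)], numeric(length(g0)))
}

#' Sister-pair versus global variance of normalized reporter curves
#'
#' Normalizes every trajectory to its first point, computes the global
#' population variance and each sister pair's variance (both time-averaged,
#' population convention), and reports the fold reduction
#' `global / mean(pair)`. A fold reduction well above 1 means sisters track
#' each other much more closely than random cells do.
#'
#' @param trajectories long table `cell_id`, `t_h`, `intensity_au` on a
#'   common grid.
#' @param pairs data.frame with `cell_id_a`, `cell_id_b` naming sister pairs.
#' @return list `global_variance`, `pair_variances` (named per pair),
#'   `fold_reduction`.
#' @export
sister_variance_analysis <- function(trajectories, pairs) {
  norm <- do.call(rbind, lapply(split(trajectories, trajectories$cell_id),
                                normalize_trajectory))
  gv <- global_variance(norm)
  pv <- mapply(function(a, b) {
    pair_variance(norm[norm$cell_id == a, , drop = FALSE],
                  norm[norm$cell_id == b, , drop = FALSE])
  }, pairs$cell_id_a, pairs$cell_id_b)
  names(pv) <- paste(pairs$cell_id_a, pairs$cell_id_b, sep = "|")
  list(global_variance = gv, pair_variances = pv,
       fold_reduction = gv / mean(pv))
}

#' Sister pairs from a lineage table
#'
#' @param cells data.frame with `cell_id` and `parent_id`; every parent with
#'   exactly two children yields one pair.
#' @return data.frame `cell_id_a`, `cell_id_b`, `parent_id`.
#' @export
sister_pairs <- function(cells) {
  sp <- split(cells$cell_id, cells$parent_id)
  sp <- sp[lengths(sp) == 2]
  data.frame(cell_id_a = vapply(sp, `[`, "", 1),
             cell_id_b = vapply(sp, `[`, "", 2),
             parent_id = names(sp), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Absolute exit-time differences: sister pairs versus random pairs
#'
#' Contrasts `|tau_a - tau_b|` for sister pairs against the same statistic
#' for pairs of unrelated cells drawn uniformly, without repetition, among
#' all distinct non-sister pairs.
#'
#' @param tau named numeric vector of exit times (names = cell ids).
#' @param pairs data.frame `cell_id_a`, `cell_id_b` of sister pairs.
#' @param n_random number of random pairs; default = number of sister pairs.
#' @param seed optional integer seed.
#' @return list `sister_diff`, `random_diff` (numeric vectors) and `test`
#'   (two-sided Wilcoxon rank-sum comparison).
#' @export
exit_time_differences <- function(tau, pairs, n_random = nrow(pairs),
                                  seed = NULL) {
  ids <- names(tau)
  if (length(ids) < 2) stop("need >= 2 cells", call. = FALSE)
  sister_diff <- abs(tau[pairs$cell_id_a] - tau[pairs$cell_id_b])
  all_pairs <- t(utils::combn(ids, 2))
  skey <- paste(pmin(pairs$cell_id_a, pairs$cell_id_b),
                pmax(pairs$cell_id_a, pairs$cell_id_b))
  akey <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                pmax(all_pairs[, 1], all_pairs[, 2]))
  cand <- all_pairs[!(akey %in% skey), , drop = FALSE]
  if (nrow(cand) < n_random)
    stop("fewer candidate non-sister pairs than requested", call. = FALSE)
  pick <- with_seed(seed, sample.int(nrow(cand), n_random))
  random_diff <- abs(tau[cand[pick, 1]] - tau[cand[pick, 2]])
  test <- if (length(sister_diff) > 0 && length(random_diff) > 0)
    stats::wilcox.test(unname(sister_diff), unname(random_diff),
                       exact = FALSE) else NULL
  list(sister_diff = unname(sister_diff), random_diff = unname(random_diff),
       test = test)
}

#' Correlation of division asymmetry with exit-time (or reporter-decrease) ratio
#'
#' Pearson correlation between the volume asymmetry ratio of a division
#' (smaller/larger daughter) and a response ratio ordered the same way
#' (smaller cell over larger cell) — e.g. the ratio of the sisters' exit
#' times, or of their reporter decreases over the first hours after
#' division. A correlation near 0 indicates that size asymmetry at division
#' carries no information about exit dynamics.
#'
#' @param volume_ratio numeric, smaller/larger daughter volume per pair.
#' @param response_ratio numeric, smaller-cell/larger-cell response per pair.
#' @return list `r`, `p`, `n`, `defined` (`FALSE` when either variable has
#'   zero variance, in which case `r` and `p` are `NA`).
#' @export
asymmetry_correlation <- function(volume_ratio, response_ratio) {
  ok <- is.finite(volume_ratio) & is.finite(response_ratio)
  x <- volume_ratio[ok]; y <- response_ratio[ok]
  if (length(x) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

#' Reporter-decrease ratio of a sister pair after division
#'
#' The decrease of each sister's reporter intensity over the first `window`
#' hours after the gating division, returned as smaller-cell over
#' larger-cell ratio.
#'
#' @param traj_small,traj_large trajectories (`t_h`, `intensity_au`) of the
#'   smaller and larger sister.
#' @param division_h division time, hours.
#' @param window horizon after division over which the decrease is measured,
#'   hours; default 6.
#' @return scalar ratio (`NA` if the larger cell's decrease is 0).
#' @export
reporter_decrease_ratio <- function(traj_small, traj_large, division_h,
                                    window = 6) {
  dec <- function(tr) {
    w <- tr[tr$t_h >= division_h & tr$t_h <= division_h + window, , drop = FALSE]
    if (nrow(w) < 2) stop("too few samples in post-division window",
                          call. = FALSE)
    w$intensity_au[[1]] - w$intensity_au[[nrow(w)]]
  }
  ds <- dec(traj_small); dl <- dec(traj_large)
  if (dl == 0) return(NA_real_)
  ds / dl
}
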