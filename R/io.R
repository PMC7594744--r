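#' @name table-io
#' @title Read and write the pipeline's TSV tables
#'
#' @description
#' All tables are tab-separated with a header; columns are matched by name,
#' so column order is free. Time columns carry their unit in the name
#' (`t_h` hours from 2i/LIF removal, `t_min` minutes from cytokinesis end,
#' `t_s` seconds from the bleach). Schema violations raise errors naming the
#' offending column; duplicated samples (same id and time) are rejected.
#'
#' Schemas:
#' * trajectories: `cell_id`, `t_h`, `intensity_au`
#' * lineage: `cell_id`, `parent_id`, `division_times_h`
#'   (`;`-separated list of division times)
#' * bridges: `bridge_id`, `condition`, `t_min`, `width_um`
#' * frap: `trace_id`, `role`, `t_s`, `intensity_norm`
#' * counts: `frame_id`, `n_cells`, `n_bridges`
#'
#' @param path file path.
#' @param x table to write.
#' @return `read_*` return validated data.frames; `write_pipeline_table()`
#'   returns `path` invisibly.
NULL

.schemas <- list(
  trajectories = list(cols = c("cell_id", "t_h", "intensity_au"),
                      numeric = c("t_h", "intensity_au"),
                      key = c("cell_id", "t_h")),
  lineage = list(cols = c("cell_id", "parent_id", "division_times_h"),
                 numeric = character(0), key = "cell_id"),
  bridges = list(cols = c("bridge_id", "condition", "t_min", "width_um"),
                 numeric = c("t_min", "width_um"),
                 key = c("bridge_id", "t_min")),
  frap = list(cols = c("trace_id", "role", "t_s", "intensity_norm"),
              numeric = c("t_s", "intensity_norm"),
              key = c("trace_id", "t_s")),
  counts = list(cols = c("frame_id", "n_cells", "n_bridges"),
                numeric = c("n_cells", "n_bridges"), key = "frame_id"))

read_schema_table <- function(path, schema_name) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .schemas[[schema_name]]
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  missing <- setdiff(schema$cols, names(d))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "NA")
    if (length(bad))
      stop("parse error in ", basename(path), ": non-numeric `", col,
           "` at line(s) ", paste(head(bad + 1L, 5), collapse = ", "),
           call. = FALSE)
    d[[col]] <- v
  }
  if (length(schema$key)) {
    key <- do.call(paste, d[schema$key])
    if (anyDuplicated(key))
      stop("duplicate sample in ", basename(path), ": key (",
           paste(schema$key, collapse = ", "), ") repeated", call. = FALSE)
  }
  d[schema$cols]
}

#' @rdname table-io
#' @export
read_trajectories <- function(path) read_schema_table(path, "trajectories")

#' @rdname table-io
#' @export
read_lineage <- function(path) read_schema_table(path, "lineage")

#' @rdname table-io
#' @export
read_bridge_traces <- function(path) read_schema_table(path, "bridges")

#' @rdname table-io
#' @export
read_frap_traces <- function(path) read_schema_table(path, "frap")

#' @rdname table-io
#' @export
read_frame_counts <- function(path) read_schema_table(path, "counts")

#' @rdname table-io
#' @export
write_pipeline_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a lineage truth table to the lineage TSV schema
#'
#' @param cells the `cells` component of [simulate_lineage()] output.
#' @return data.frame `cell_id`, `parent_id`, `division_times_h`.
#' @export
lineage_table <- function(cells) {
  div <- ifelse(is.na(cells$d2_h),
                sprintf("%.6g", cells$d1_h),
                sprintf("%.6g;%.6g", cells$d1_h, cells$d2_h))
  data.frame(cell_id = cells$cell_id, parent_id = cells$parent_id,
             division_times_h = div, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on simulated (or supplied) data
#'
#' Executes simulate -> sigmoid fit -> quality filter -> division-coupling
#' bootstrap -> sister statistics -> bridge kinetics -> FRAP quantification
#' and collects every headline statistic in one machine-readable report.
#' Stages whose inputs are absent are skipped, so a config with only bridge
#' inputs yields a bridge-only report.
#'
#' @param config nested list; recognized blocks (all optional):
#'   \describe{
#'     \item{`sim`}{arguments for [sim_config()]; enables the trajectory
#'       stages.}
#'     \item{`bridges`}{list with `naive` and `exiting` argument lists for
#'       [bridge_sim_config()].}
#'     \item{`frap`}{arguments for [frap_sim_config()].}
#'     \item{`fit`}{`max_ratio` for [filter_fits()].}
#'     \item{`coupling`}{`grace`, `n_boot` for the coupling stage.}
#'   }
#'   A YAML file holding the same structure can be read with
#'   `yaml::read_yaml()` and passed here.
#' @param seed integer seed used for every stochastic stage (per-stage
#'   sub-seeds are derived from it).
#' @param out_dir optional directory; when given, tables and the JSON report
#'   are written there.
#' @return report list (also written as `report.json` under `out_dir`).
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("abclock")),
                 seed = seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_tab <- function(x, name) {
    if (!is.null(out_dir))
      write_pipeline_table(x, file.path(out_dir, paste0(name, ".tsv")))
  }

  if (!is.null(config$sim)) {
    sim_args <- config$sim; sim_args$seed <- seed
    sim <- simulate_lineage(do.call(sim_config, sim_args))
    save_tab(sim$trajectories, "trajectories")
    save_tab(lineage_table(sim$cells), "lineage")

    fits <- fit_trajectories(sim$trajectories)
    max_ratio <- config$fit$max_ratio %||% 1
    fits <- filter_fits(fits, max_ratio = max_ratio)
    save_tab(fits, "fits")
    report$fits <- list(n_cells = nrow(fits), n_kept = sum(fits$kept))

    grace <- config$coupling$grace %||% 2.5
    n_boot <- config$coupling$n_boot %||% 1000
    kept <- merge(fits[fits$kept, c("cell_id", "tau_h")],
                  sim$cells[c("cell_id", "parent_id", "d1_h", "d2_h")],
                  by = "cell_id")
    kept$latest_division_h <- mapply(function(tau, d1, d2) {
      latest_division(tau, c(d1, d2)[!is.na(c(d1, d2))], grace = grace)
    }, kept$tau_h, kept$d1_h, kept$d2_h)
    cpl <- bootstrap_null(kept, n_boot = n_boot, seed = seed + 1L)
    report$coupling <- list(r_squared = cpl$r_squared, slope = cpl$slope,
                            intercept = cpl$intercept,
                            p_empirical = cpl$p_empirical,
                            n_boot = cpl$n_boot, n_cells = cpl$n_cells,
                            n_excluded = cpl$n_excluded)
    cls <- classify_exit_division(merge(
      fits[fits$kept, c("cell_id", "tau_h")],
      sim$cells[c("cell_id", "d1_h", "d2_h")], by = "cell_id"))
    report$classification <- as.list(as.data.frame.matrix(cls$percentages))

    pairs <- sister_pairs(sim$cells)
    sv <- sister_variance_analysis(sim$trajectories, pairs)
    report$sisters <- list(global_variance = sv$global_variance,
                           mean_pair_variance = mean(sv$pair_variances),
                           fold_reduction = sv$fold_reduction)
    tau <- setNames(fits$tau_h[fits$kept], fits$cell_id[fits$kept])
    pairs_ok <- pairs[pairs$cell_id_a %in% names(tau) &
                        pairs$cell_id_b %in% names(tau), , drop = FALSE]
    if (nrow(pairs_ok) >= 2) {
      etd <- exit_time_differences(tau, pairs_ok, seed = seed + 2L)
      report$sisters$median_sister_diff_h <- median(etd$sister_diff)
      report$sisters$median_random_diff_h <- median(etd$random_diff)
      report$sisters$rank_sum_p <- etd$test$p.value
    }
  }

  if (!is.null(config$bridges)) {
    bargs_a <- config$bridges$naive %||% list()
    bargs_b <- config$bridges$exiting %||% list()
    bargs_a$condition <- "naive"; bargs_a$seed <- seed + 3L
    bargs_b$condition <- "exiting"; bargs_b$seed <- seed + 4L
    sim_a <- simulate_bridge_widths(do.call(bridge_sim_config, bargs_a))
    sim_b <- simulate_bridge_widths(do.call(bridge_sim_config, bargs_b))
    save_tab(rbind(sim_a$traces, sim_b$traces), "bridges")
    fits_a <- fit_bridge_traces(sim_a$traces)
    fits_b <- fit_bridge_traces(sim_b$traces)
    save_tab(rbind(fits_a, fits_b), "bridge_fits")
    cmp <- compare_conditions(sim_a$traces, sim_b$traces, method = "F")
    report$bridges <- list(
      mean_tau_c_naive = mean(fits_a$tau_c_min[fits_a$converged]),
      mean_tau_c_exiting = mean(fits_b$tau_c_min[fits_b$converged]),
      pooled_tau_naive = cmp$tau_a, pooled_tau_exiting = cmp$tau_b,
      comparison_method = cmp$method, comparison_p = cmp$p_value)
    dur <- simulate_abscission_durations(8.2, 3.8, 50, seed = seed + 5L)
    report$abscission <- abscission_durations(dur)
  }

  if (!is.null(config$frap)) {
    fargs <- config$frap; fargs$seed <- seed + 6L
    sim_f <- simulate_frap(do.call(frap_sim_config, fargs))
    save_tab(sim_f$traces, "frap")
    mins <- frap_minima(sim_f$traces)
    report$frap <- setNames(as.list(mins$minima$min_norm),
                            paste0("min_", mins$minima$role))
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
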