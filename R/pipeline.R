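#' @keywords internal
"_PACKAGE"

# Logging: level threshold set by options(larvatrack.log_level = ...),
# one of "debug", "info", "warn", "quiet".
log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

lt_log <- function(level, fmt, ...) {
  threshold <- getOption("larvatrack.log_level", "info")
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  invisible(NULL)
}

file_hash <- function(path) {
  unname(tools::md5sum(path))
}

#' Read a run configuration file
#'
#' YAML with a `kinematics` section mirroring the [kinematics_config()]
#' fields plus top-level `alpha`. Unknown keys are an error naming the key,
#' so a typo in a config never silently falls back to a default.
#'
#' @param path Path to a YAML configuration file.
#' @return List with elements `kinematics` (a `"kinematics_config"`) and
#'   `alpha`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known_top <- c("kinematics", "alpha")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  kin_args <- raw$kinematics
  if (!is.null(kin_args)) {
    bad <- setdiff(names(kin_args), names(formals(kinematics_config)))
    if (length(bad)) {
      stop(sprintf("unknown kinematics config key(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  alpha <- if (is.null(raw$alpha)) 0.05 else raw$alpha
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  list(
    kinematics = do.call(kinematics_config, as.list(kin_args)),
    alpha = alpha
  )
}

#' Read a simulation design file
#'
#' YAML mirroring [simulation_design()]: optional `arena`
#' (`diameter_mm`), optional `baseline` ([behavior_params()] fields),
#' mandatory `groups` (each with `label`, `n_larvae`, and an `effect`
#' block with [treatment_effect()] fields), optional `duration_s`,
#' `sample_interval_s`, `seed`. Unknown keys are an error naming the key.
#'
#' @param path Path to a YAML design file.
#' @return A `"simulation_design"`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("design file not found: '%s'", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known_top <- c("arena", "baseline", "groups", "duration_s",
                 "sample_interval_s", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop(sprintf("unknown design key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(raw$groups) || !length(raw$groups)) {
    stop("design must define at least one group under 'groups'",
         call. = FALSE)
  }
  check_keys <- function(lst, fn, where) {
    bad <- setdiff(names(lst), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(raw$arena, arena_spec, "arena")
  check_keys(raw$baseline, behavior_params, "baseline")
  arena <- do.call(arena_spec, as.list(raw$arena))
  baseline <- do.call(behavior_params, as.list(raw$baseline))
  groups <- lapply(raw$groups, function(g) {
    extra <- setdiff(names(g), c("label", "n_larvae", "effect", "injection"))
    if (length(extra)) {
      stop(sprintf("unknown group key(s): %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    if (is.null(g$label) || is.null(g$n_larvae)) {
      stop("every group needs 'label' and 'n_larvae'", call. = FALSE)
    }
    check_keys(g$effect, treatment_effect, sprintf("group '%s' effect",
                                                   g$label))
    list(
      label = g$label,
      effect = do.call(treatment_effect, as.list(g$effect)),
      n_larvae = g$n_larvae,
      injection = g$injection
    )
  })
  simulation_design(
    baseline = baseline, groups = groups, arena = arena,
    duration_s = if (is.null(raw$duration_s)) 300 else raw$duration_s,
    sample_interval_s = if (is.null(raw$sample_interval_s)) 1
                        else raw$sample_interval_s,
    seed = if (is.null(raw$seed)) 1L else raw$seed
  )
}

#' Simulate an experiment from a design file
#'
#' Reads the design, optionally overrides its seed, simulates every group,
#' and writes the canonical track CSV plus (optionally) the latent
#' ground-truth CSV. The run log records the design file hash and the seed
#' actually used.
#'
#' @param design_file Path to a YAML design file (see [read_design()]).
#' @param out_tracks Output path for the track CSV.
#' @param out_truth Optional output path for the latent-state CSV
#'   (`larva_id,t_s,state,latent_turn,step_mm`); `NULL` skips it.
#' @param seed Optional integer overriding the design's seed.
#' @return Invisibly, the list returned by [simulate_experiment()].
#' @export
cmd_simulate <- function(design_file, out_tracks, out_truth = NULL,
                         seed = NULL) {
  design <- read_design(design_file)
  if (!is.null(seed)) design$seed <- as.integer(seed)
  lt_log("info", "simulate: design '%s' (md5 %s), seed %d",
         design_file, file_hash(design_file), design$seed)
  sim <- simulate_experiment(design)
  write_tracks(sim$trajectories, out_tracks)
  lt_log("info", "simulate: wrote %d trajectories to '%s' (md5 %s)",
         length(sim$trajectories), out_tracks, file_hash(out_tracks))
  if (!is.null(out_truth)) {
    utils::write.csv(sim$truth, out_truth, row.names = FALSE, quote = TRUE)
    lt_log("info", "simulate: wrote ground truth to '%s'", out_truth)
  }
  invisible(sim)
}

#' Score a track file into the per-larva summary table
#'
#' Reads trajectories, scores each with the kinematics configuration, and
#' writes the summary CSV. Larvae with fewer than 3 points are skipped with
#' a warning.
#'
#' @param tracks_path Path to a canonical track CSV.
#' @param out Output path for the summary CSV.
#' @param config Optional path to a YAML run config (see
#'   [read_run_config()]); `NULL` uses all defaults.
#' @param dialect Track file dialect passed to [read_tracks()].
#' @return Invisibly, the summary data frame.
#' @export
cmd_analyze <- function(tracks_path, out, config = NULL,
                        dialect = "canonical_csv") {
  cfg <- if (is.null(config)) kinematics_config()
         else read_run_config(config)$kinematics
  lt_log("info", "analyze: tracks '%s' (md5 %s)", tracks_path,
         file_hash(tracks_path))
  trajs <- read_tracks(tracks_path, dialect = dialect,
                       sample_interval_s = cfg$sample_interval_s)
  summary_df <- summarize_tracks(trajs, cfg)
  write_summary(summary_df, out)
  lt_log("info", "analyze: scored %d/%d larvae -> '%s'",
         nrow(summary_df), length(trajs), out)
  invisible(summary_df)
}

#' Compare all behavioral metrics across groups from a summary file
#'
#' Reads the per-larva summary table and writes the long comparison report
#' (`metric,F,df1,df2,p,pair,mean_diff,critical,significant`) produced by
#' [compare_all_metrics()].
#'
#' @param summary_path Path to a summary CSV (see [cmd_analyze()]).
#' @param out Output path for the report CSV.
#' @param group_col Grouping column name (default `"treatment"`).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return Invisibly, the report data frame.
#' @export
cmd_compare <- function(summary_path, out, group_col = "treatment",
                        alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  summary_df <- read_summary(summary_path)
  lt_log("info", "compare: summary '%s' (md5 %s), alpha %g",
         summary_path, file_hash(summary_path), alpha)
  report <- compare_all_metrics(summary_df, group_col = group_col,
                                alpha = alpha)
  utils::write.csv(report, out, row.names = FALSE, quote = TRUE)
  lt_log("info", "compare: wrote report to '%s'", out)
  invisible(report)
}
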