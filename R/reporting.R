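#' Read a run configuration
#'
#' Declarative YAML controlling the pipeline: parameter source, initial
#' distribution, cohort settings, experiment settings. All fields are
#' optional; the defaults reproduce the study conditions (50,000 subjects,
#' 31-visit 6..186-month grid, 1000 repetitions, 5%..100% noise fractions).
#' Seeds are always explicit — no wall-clock seeding.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    params_file = NULL,          # NULL -> packaged table1 fixture
    mean = rep(0, 4),
    covariance = default_initial_covariance(),
    n_subjects = 50000L,
    visit_grid_months = seq(6, 186, by = 6),
    months_per_unit = 37,
    obs_noise_sd = rep(0, 4),
    reps = 1000L,
    sd_fractions = seq(0.05, 1, by = 0.05),
    reserve_coefficient = -0.1,
    seed = 1L
  )
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(user)] <- user
  if (!is.null(cfg$covariance)) cfg$covariance <- matrix(
    unlist(cfg$covariance), nrow = length(cfg$mean), byrow = TRUE)
  class(cfg) <- "run_config"
  cfg
}

config_params <- function(cfg) {
  if (is.null(cfg$params_file)) table1_params() else
    read_cascade_params(cfg$params_file)
}

config_cohort <- function(cfg, n = NULL) {
  cohort_config(n_subjects = if (is.null(n)) cfg$n_subjects else n,
                visit_grid_months = cfg$visit_grid_months,
                months_per_unit = cfg$months_per_unit,
                obs_noise_sd = cfg$obs_noise_sd,
                seed = cfg$seed)
}

simulate_cohort <- function(cfg, reserve = NULL) {
  params <- config_params(cfg)
  dist <- initial_distribution(cfg$mean, cfg$covariance)
  x0 <- draw_initial_states(dist, cfg$n_subjects, seed = cfg$seed)
  simulate_trajectories(params, x0, config_cohort(cfg), reserve = reserve)
}

#' Generate and write a synthetic cohort
#'
#' Simulates trajectories under the configured cascade parameters, writes the
#' long-format panel CSV (with observation noise if configured) and the exact
#' model-value trajectory CSV.
#'
#' @param config a `run_config` (see [read_run_config()]) or a YAML path.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
cmd_simulate <- function(config = NULL, out_dir = ".") {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trajs <- simulate_cohort(cfg)
  panel <- build_panel(trajs, config_cohort(cfg))
  exact_path <- file.path(out_dir, "trajectories.csv")
  write_panel(panel, exact_path)
  if (any(cfg$obs_noise_sd > 0)) {
    panel <- add_observation_noise(panel, cfg$obs_noise_sd,
                                   seed = cfg$seed + 2L)
  }
  panel_path <- file.path(out_dir, "panel.csv")
  write_panel(panel, panel_path)
  invisible(c(panel = panel_path, trajectories = exact_path))
}

format_summary_table <- function(summary) {
  fmt <- function(m, lo, hi) sprintf("%.4f [%.4f, %.4f]", m, lo, hi)
  data.frame(term = summary$term,
             estimate = fmt(summary$mean, summary$lo, summary$hi))
}

#' Run a sampling experiment end to end
#'
#' `mode = "main"`: linear cascade, the three sampling strategies
#' (consistent, random, residualized random) side by side. `"secondary"`:
#' same with the cognitive-reserve product term active. `"noise-sweep"`: the
#' residualized random experiment across the configured time-noise
#' fractions. Writes a JSON summary, a text table, a CSV (sweep mode) and,
#' when ggplot2 is available, the stage-colored biomarker scatter figures.
#'
#' @param config a `run_config` or YAML path.
#' @param mode one of `"main"`, `"secondary"`, `"noise-sweep"`.
#' @param out_dir output directory.
#' @return Invisibly, the summary object written.
#' @export
cmd_experiment <- function(config = NULL,
                           mode = c("main", "secondary", "noise-sweep"),
                           out_dir = ".") {
  mode <- match.arg(mode)
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reserve <- if (mode == "secondary") {
    reserve_spec(coefficient = cfg$reserve_coefficient)
  } else NULL
  trajs <- simulate_cohort(cfg, reserve = reserve)
  if (mode == "noise-sweep") {
    sweep <- noise_sensitivity_sweep(trajs, fractions = cfg$sd_fractions,
                                     reps = cfg$reps, seed = cfg$seed)
    utils::write.csv(sweep, file.path(out_dir, "noise_sweep.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sweep, file.path(out_dir, "noise_sweep.json"),
                         dataframe = "rows", digits = NA)
    out <- sweep
  } else {
    res <- list(
      consistent = run_consistent_experiment(trajs),
      random = run_random_experiment(trajs, reps = cfg$reps,
                                     seed = cfg$seed),
      random_residualized = run_random_experiment(trajs, reps = cfg$reps,
                                                  residualize = TRUE,
                                                  seed = cfg$seed + 1L)
    )
    tab <- Reduce(function(a, b) merge(a, b, by = "term", sort = FALSE),
                  lapply(names(res), function(nm) {
                    ft <- format_summary_table(res[[nm]])
                    names(ft)[2] <- nm
                    ft
                  }))
    writeLines(utils::capture.output(print(tab, row.names = FALSE)),
               file.path(out_dir, paste0(mode, "_table.txt")))
    jsonlite::write_json(res, file.path(out_dir, paste0(mode, "_summary.json")),
                         dataframe = "rows", digits = NA)
    plot_stage_scatter(trajs, out_dir, seed = cfg$seed)
    out <- res
  }
  log <- list(mode = mode, seed = cfg$seed, n_subjects = cfg$n_subjects,
              reps = cfg$reps,
              package_version = as.character(utils::packageVersion("cascadebias")))
  jsonlite::write_json(log, file.path(out_dir, paste0(mode, "_runinfo.json")),
                       auto_unbox = TRUE)
  invisible(out)
}

# Stage-colored scatter of each pathology biomarker against hippocampal
# volume under random sampling: the visual mechanism of the artifact.
plot_stage_scatter <- function(trajs, out_dir, seed = 1L, max_points = 5000L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible(NULL))
  cs <- crosssection_random(trajs, seed = seed)
  if (nrow(cs) > max_points) cs <- cs[seq_len(max_points), ]
  cs$years <- cs$sampling_time_months / 12
  for (v in c("AV45", "CSFtau")) {
    p <- ggplot2::ggplot(cs, ggplot2::aes(
      x = .data[[v]], y = .data[["HippoV"]],
      colour = .data[["years"]])) +
      ggplot2::geom_point(alpha = 0.4, size = 0.6) +
      ggplot2::scale_colour_viridis_c(name = "years") +
      ggplot2::labs(x = paste(v, "(z)"), y = "HippoV (z)",
                    title = paste("Random cross-section:", v,
                                  "vs hippocampal volume")) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, paste0("scatter_", v, ".png")), p,
                    width = 5, height = 4, dpi = 150)
  }
  invisible(NULL)
}

#' Estimate cascade parameters from a panel file
#'
#' Reads a long-format panel CSV, runs the mixed-model family selection
#' ([select_and_assemble()]) and writes the assembled parameters (table1.json
#' schema) plus the full per-model cAIC selection report.
#'
#' @param panel_path path to a panel CSV (see [write_panel()]).
#' @param out_dir output directory.
#' @param months_per_unit time scale for the fitted coefficients.
#' @return Invisibly, the `select_and_assemble()` result.
#' @export
cmd_estimate <- function(panel_path, out_dir = ".", months_per_unit = 37) {
  if (!file.exists(panel_path)) stop("panel file not found: ", panel_path,
                                     call. = FALSE)
  panel <- read_panel(panel_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- select_and_assemble(panel, months_per_unit = months_per_unit)
  write_cascade_params(res$params, file.path(out_dir, "estimated_params.json"))
  jsonlite::write_json(res$report, file.path(out_dir, "selection_report.json"),
                       dataframe = "rows", digits = NA)
  invisible(res)
}
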