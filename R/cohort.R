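#' Initial-state distribution of the cohort
#'
#' Baseline biomarker configurations are drawn from a multivariate Gaussian
#' in z-units. The default is a documented surrogate for the (unpublished)
#' empirical baseline covariance: zero mean, unit variances, and correlations
#' whose signs follow AD biology — worse cognition goes with smaller
#' hippocampi and more tau/amyloid, atrophy goes with more pathology, and tau
#' tracks amyloid.
#'
#' @param mean length-4 mean vector (z-units).
#' @param covariance 4 x 4 symmetric positive-semidefinite matrix.
#' @return An object of class `initial_distribution`.
#' @export
initial_distribution <- function(mean = rep(0, 4),
                                 covariance = default_initial_covariance()) {
  covariance <- as.matrix(covariance)
  n <- length(mean)
  if (!all(dim(covariance) == n)) stop("covariance dimension mismatch",
                                       call. = FALSE)
  if (max(abs(covariance - t(covariance))) > 1e-12) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("covariance is not positive semi-definite",
                             call. = FALSE)
  structure(list(mean = as.numeric(mean), covariance = unname(covariance)),
            class = "initial_distribution")
}

#' @rdname initial_distribution
#' @export
default_initial_covariance <- function() {
  R <- diag(4)
  rownames(R) <- colnames(R) <- cascade_labels()
  R["ADAS-cog", "HippoV"] <- R["HippoV", "ADAS-cog"] <- -0.4
  R["ADAS-cog", "CSFtau"] <- R["CSFtau", "ADAS-cog"] <- 0.3
  R["ADAS-cog", "AV45"]   <- R["AV45", "ADAS-cog"]   <- 0.3
  R["HippoV", "CSFtau"]   <- R["CSFtau", "HippoV"]   <- -0.2
  R["HippoV", "AV45"]     <- R["AV45", "HippoV"]     <- -0.25
  R["CSFtau", "AV45"]     <- R["AV45", "CSFtau"]     <- 0.3
  unname(R)
}

#' Cohort simulation configuration
#'
#' @param n_subjects number of simulated trajectories; the sampling
#'   experiments use 50,000, estimation-style panels use 176.
#' @param visit_grid_months visit times in months after baseline; default
#'   6-month steps over 6..186 (31 visits), the span of the emulated panel.
#' @param months_per_unit scale from months to abstract model-time units
#'   (default 37, about one SD of follow-up duration). All sampling-artifact
#'   results are invariant to this scale.
#' @param obs_noise_sd per-biomarker observation-noise SD in z-units
#'   (length 4), applied by [add_observation_noise()].
#' @param age_mean,age_sd,edu_mean,edu_sd demographic Gaussians in years
#'   (defaults 72.8 +/- 6.4 and 16.1 +/- 2.7).
#' @param seed integer seed; every random step derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50000L,
                          visit_grid_months = seq(6, 186, by = 6),
                          months_per_unit = 37,
                          obs_noise_sd = rep(0, 4),
                          age_mean = 72.8, age_sd = 6.4,
                          edu_mean = 16.1, edu_sd = 2.7,
                          seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (is.unsorted(visit_grid_months, strictly = TRUE) ||
      any(visit_grid_months < 0)) {
    stop("visit_grid_months must be increasing and non-negative",
         call. = FALSE)
  }
  if (months_per_unit <= 0) stop("months_per_unit must be positive",
                                 call. = FALSE)
  if (any(obs_noise_sd < 0)) stop("obs_noise_sd must be non-negative",
                                  call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_grid_months = as.numeric(visit_grid_months),
                 months_per_unit = months_per_unit,
                 obs_noise_sd = as.numeric(obs_noise_sd),
                 age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw initial biomarker configurations
#'
#' i.i.d. multivariate-Gaussian baseline states, reproducible under `seed`.
#'
#' @param dist an [initial_distribution()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return `n x 4` matrix of initial states, columns in cascade order.
#' @export
draw_initial_states <- function(dist, n, seed = 1L) {
  if (!inherits(dist, "initial_distribution")) {
    dist <- do.call(initial_distribution, as.list(dist))
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    x <- MASS::mvrnorm(n, mu = dist$mean, Sigma = dist$covariance)
    if (!is.matrix(x)) x <- matrix(x, nrow = 1)
    unname(x)
  })
}

#' Simulate cohort trajectories on the visit grid
#'
#' Evaluates every subject's state at each visit. The visit grid in months is
#' mapped to model time by `months_per_unit`; without a reserve term the exact
#' closed-form propagator is used, with one the stacked system is integrated
#' by Dormand-Prince.
#'
#' @param params a [cascade_params()].
#' @param initial_states `n x 4` matrix of baseline states.
#' @param config a [cohort_config()].
#' @param reserve optional [reserve_spec()]; `NULL` for the linear model.
#' @return An object of class `trajectory_set`: list with `states`
#'   (`n x 4 x n_visits` array), `times_months`, `times_model`, `labels`.
#' @export
simulate_trajectories <- function(params, initial_states, config,
                                  reserve = NULL) {
  validate_cascade_params(params)
  x0 <- as.matrix(initial_states)
  if (ncol(x0) != params$n) stop("initial states dimension mismatch",
                                 call. = FALSE)
  tm <- config$visit_grid_months / config$months_per_unit
  nT <- length(tm)
  n <- nrow(x0)
  if (is.null(reserve)) {
    states <- array(NA_real_, dim = c(n, params$n, nT))
    for (k in seq_len(nT)) {
      states[, , k] <- propagate_closed_form(params, x0, tm[k])
    }
  } else {
    grid <- if (tm[1] > 0) c(0, tm) else tm
    sol <- integrate_numeric(function(x) reserve_rhs(params, reserve, x),
                             x0, grid)
    keep <- match(tm, grid)
    states <- sol$states[, , keep, drop = FALSE]
  }
  structure(list(states = states, times_months = config$visit_grid_months,
                 times_model = tm, labels = params$labels),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory_set:", dim(x$states)[1], "subjects x",
      dim(x$states)[2], "variables x", dim(x$states)[3], "visits (months",
      min(x$times_months), "-", max(x$times_months), ")\n")
  invisible(x)
}

#' Convert trajectories to a long-format longitudinal panel
#'
#' One row per subject-visit with model-exact biomarker values and per-subject
#' Gaussian demographics. Add measurement error separately with
#' [add_observation_noise()].
#'
#' @param trajs a `trajectory_set` from [simulate_trajectories()].
#' @param config a [cohort_config()]; demographics use its means/SDs and the
#'   draw derives from `config$seed`.
#' @return A `data.frame` with columns `subject_id`, `time_months`, `ADAS`,
#'   `HippoV`, `CSFtau`, `AV45`, `age_years`, `education_years`.
#' @export
build_panel <- function(trajs, config) {
  n <- dim(trajs$states)[1]
  nT <- dim(trajs$states)[3]
  demo <- with_seed(config$seed + 1L, data.frame(
    subject_id = seq_len(n),
    age_years = stats::rnorm(n, config$age_mean, config$age_sd),
    education_years = stats::rnorm(n, config$edu_mean, config$edu_sd)
  ))
  flat <- matrix(aperm(trajs$states, c(3, 1, 2)), nrow = n * nT)
  panel <- data.frame(
    subject_id = rep(seq_len(n), each = nT),
    time_months = rep(trajs$times_months, times = n),
    ADAS = flat[, 1], HippoV = flat[, 2],
    CSFtau = flat[, 3], AV45 = flat[, 4]
  )
  panel$age_years <- demo$age_years[panel$subject_id]
  panel$education_years <- demo$education_years[panel$subject_id]
  validate_panel(panel)
}

#' Add per-record observation noise to a panel
#'
#' i.i.d. Gaussian measurement error per biomarker per record, emulating the
#' residual variance an estimation procedure faces on real data.
#'
#' @param panel a longitudinal panel (see [build_panel()]).
#' @param sd length-4 non-negative vector of noise SDs, in cascade order.
#' @param seed integer seed.
#' @return The panel with noisy biomarker columns.
#' @export
add_observation_noise <- function(panel, sd, seed = 1L) {
  if (length(sd) == 1L) sd <- rep(sd, 4)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  cols <- c("ADAS", "HippoV", "CSFtau", "AV45")
  with_seed(seed, {
    for (k in seq_along(cols)) {
      if (sd[k] > 0) {
        panel[[cols[k]]] <- panel[[cols[k]]] +
          stats::rnorm(nrow(panel), 0, sd[k])
      }
    }
  })
  panel
}

panel_columns <- function() {
  c("subject_id", "time_months", "ADAS", "HippoV", "CSFtau", "AV45",
    "age_years", "education_years")
}

validate_panel <- function(panel) {
  miss <- setdiff(panel_columns(), names(panel))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  num <- panel[, c("time_months", "ADAS", "HippoV", "CSFtau", "AV45")]
  if (nrow(panel) > 0 && !all(vapply(num, is.numeric, logical(1)))) {
    stop("panel has non-numeric measurement columns", call. = FALSE)
  }
  if (nrow(panel) > 0 && !all(is.finite(as.matrix(num)))) {
    stop("panel has non-finite values", call. = FALSE)
  }
  if (anyDuplicated(panel[, c("subject_id", "time_months")])) {
    stop("duplicate (subject_id, time_months) records", call. = FALSE)
  }
  panel[, panel_columns()]
}

#' Write / read a longitudinal panel as CSV
#'
#' Plain UTF-8 CSV with the canonical header
#' `subject_id,time_months,ADAS,HippoV,CSFtau,AV45,age_years,education_years`.
#' Reading validates column names, numeric cells and uniqueness of
#' (subject, time) records.
#'
#' @param panel a longitudinal panel `data.frame`.
#' @param path file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   validated panel.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!identical(names(panel), panel_columns())) {
    stop("malformed panel header in ", path, call. = FALSE)
  }
  validate_panel(panel)
}
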