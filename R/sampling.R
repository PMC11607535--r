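#' Cross-sectional samples from a trajectory set
#'
#' A cross-section holds exactly one record per subject: the four model
#' variables at that subject's sampling time, the sampling time itself, and
#' optionally a noise-corrupted copy of it (see [jitter_time()]).
#'
#' `crosssection_at()` emulates a time-consistent design: every subject is
#' observed at the same visit. `crosssection_random()` emulates a naturalistic
#' cross-sectional study: each subject's visit index is drawn independently
#' and uniformly over the grid, so the sample mixes disease stages.
#'
#' @param trajs a `trajectory_set` from [simulate_trajectories()].
#' @param grid_index visit index (1-based) into the trajectory grid.
#' @return A `data.frame` of class `cross_section` with columns `subject_id`,
#'   `sampling_time_months`, `noisy_time_months`, `ADAS`, `HippoV`, `CSFtau`,
#'   `AV45`.
#' @export
crosssection_at <- function(trajs, grid_index) {
  nT <- dim(trajs$states)[3]
  if (grid_index < 1 || grid_index > nT) {
    stop("grid_index out of range [1, ", nT, "]", call. = FALSE)
  }
  n <- dim(trajs$states)[1]
  make_cross_section(trajs$states[, , grid_index, drop = TRUE],
                     rep(trajs$times_months[grid_index], n))
}

#' @rdname crosssection_at
#' @param seed integer seed for the per-subject visit draw.
#' @export
crosssection_random <- function(trajs, seed = 1L) {
  n <- dim(trajs$states)[1]
  nT <- dim(trajs$states)[3]
  idx <- with_seed(seed, sample.int(nT, n, replace = TRUE))
  vars <- dim(trajs$states)[2]
  picked <- vapply(seq_len(vars), function(v) {
    trajs$states[cbind(seq_len(n), v, idx)]
  }, numeric(n))
  make_cross_section(picked, trajs$times_months[idx])
}

make_cross_section <- function(states, times_months) {
  states <- as.matrix(states)
  cs <- data.frame(
    subject_id = seq_len(nrow(states)),
    sampling_time_months = times_months,
    noisy_time_months = NA_real_,
    ADAS = states[, 1], HippoV = states[, 2],
    CSFtau = states[, 3], AV45 = states[, 4]
  )
  class(cs) <- c("cross_section", "data.frame")
  cs
}

#' Add Gaussian noise to sampling times
#'
#' Emulates an imperfect disease-stage estimate: true sampling times plus
#' independent Gaussian error with SD equal to `sd_fraction` of the full
#' simulation interval (186 months by default). Noisy times only ever serve
#' as the residualization regressor — they never change which state was
#' sampled.
#'
#' @param times_months numeric vector of true sampling times.
#' @param sd_fraction non-negative noise SD as a fraction of `interval_months`.
#' @param interval_months the scaling interval (default 186).
#' @param seed integer seed.
#' @return Numeric vector of noisy times.
#' @export
jitter_time <- function(times_months, sd_fraction, interval_months = 186,
                        seed = 1L) {
  if (sd_fraction < 0) stop("sd_fraction must be non-negative", call. = FALSE)
  if (sd_fraction == 0) return(times_months)
  with_seed(seed, times_months +
              stats::rnorm(length(times_months), 0,
                           sd_fraction * interval_months))
}

#' Partial the effect of sampling time out of cross-section variables
#'
#' Replaces each selected variable by its residual from a simple linear
#' regression on the (optionally noisy) sampling time. By OLS orthogonality
#' the residuals have exactly zero sample covariance with the regressor, so
#' downstream interaction products can no longer load on the shared
#' disease-time axis. Products are always formed *after* residualization.
#'
#' @param cross a `cross_section`.
#' @param variables which columns to residualize; by default every analysis
#'   variable, outcome included (each variable in turn is the dependent of a
#'   simple regression on time). Restrict to
#'   `c("HippoV", "CSFtau", "AV45")` to partial time out of the main-effect
#'   biomarkers only.
#' @param use_noisy_time if `TRUE`, regress on `noisy_time_months` (which must
#'   be set, e.g. via [jitter_time()]) instead of the true sampling time.
#' @return The cross-section with the selected columns replaced by residuals.
#' @export
residualize_on_time <- function(cross,
                                variables = c("ADAS", "HippoV", "CSFtau",
                                              "AV45"),
                                use_noisy_time = FALSE) {
  tvar <- if (use_noisy_time) cross$noisy_time_months else
    cross$sampling_time_months
  if (use_noisy_time && anyNA(tvar)) {
    stop("noisy_time_months is not set; call jitter_time() first",
         call. = FALSE)
  }
  if (length(unique(tvar)) < 3L) {
    stop("need >= 3 distinct time values to residualize", call. = FALSE)
  }
  tc <- tvar - mean(tvar)
  sst <- sum(tc^2)
  for (v in variables) {
    y <- cross[[v]]
    slope <- sum(tc * y) / sst
    cross[[v]] <- y - mean(y) - slope * tc
  }
  cross
}
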