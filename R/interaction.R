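#' z-standardize a cross-section
#'
#' Centers and scales each analysis variable to sample mean 0, SD 1 within
#' the cross-section, mirroring the z-standardization applied to the
#' empirical data before regression.
#'
#' @param cross a `cross_section`.
#' @param variables columns to standardize; default outcome plus the three
#'   biomarkers.
#' @return The standardized cross-section.
#' @export
standardize <- function(cross,
                        variables = c("ADAS", "HippoV", "CSFtau", "AV45")) {
  for (v in variables) {
    y <- cross[[v]]
    s <- stats::sd(y)
    if (!is.finite(s) || s <= 0) {
      stop("variable ", v, " has zero variance; cannot standardize",
           call. = FALSE)
    }
    cross[[v]] <- (y - mean(y)) / s
  }
  cross
}

interaction_terms <- function() {
  c("AV45", "CSFtau", "HippoV", "AV45:HippoV", "CSFtau:HippoV")
}

#' Standardized interaction regression on a cross-section
#'
#' Ordinary least squares of the cognitive outcome on the three biomarker
#' main effects plus the two moderation products with hippocampal volume
#' (with intercept):
#' \deqn{ADAS \sim AV45 + CSFtau + HippoV + AV45 \cdot HippoV +
#'       CSFtau \cdot HippoV}
#' Variables are assumed standardized (see [standardize()]); product columns
#' are formed from the standardized mains, so the coefficients are on the
#' standardized scale.
#'
#' @param cross a standardized `cross_section`.
#' @return List with `coefficients` (named, the five terms plus
#'   `(Intercept)`), `se` (classical OLS standard errors) and `n_obs`.
#' @export
fit_interaction_model <- function(cross) {
  X <- cbind(`(Intercept)` = 1,
             AV45 = cross$AV45, CSFtau = cross$CSFtau, HippoV = cross$HippoV,
             `AV45:HippoV` = cross$AV45 * cross$HippoV,
             `CSFtau:HippoV` = cross$CSFtau * cross$HippoV)
  y <- cross$ADAS
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("rank-deficient interaction design (collinear biomarkers)",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  list(coefficients = fit$coefficients, se = se, n_obs = n)
}

summarize_estimates <- function(est_matrix) {
  # est_matrix: replicates x terms
  terms <- colnames(est_matrix)
  data.frame(
    term = terms,
    mean = colMeans(est_matrix),
    lo = apply(est_matrix, 2, stats::quantile, probs = 0.025, names = FALSE),
    hi = apply(est_matrix, 2, stats::quantile, probs = 0.975, names = FALSE),
    n_reps = nrow(est_matrix),
    row.names = NULL
  )
}

#' Time-consistent sampling experiment
#'
#' Fits the interaction regression once per visit on that visit's
#' cross-section (every subject observed at the same time), then summarizes
#' each term's estimates across visits by their mean and 2.5-97.5 percentile
#' interval. Because the state at a fixed time is an affine function of the
#' Gaussian initial state, the population interaction coefficients here are
#' exactly zero: this column is the artifact-free benchmark.
#'
#' @param trajs a `trajectory_set`.
#' @return An `experiment_summary` data frame: one row per regression term
#'   with `mean`, `lo`, `hi`, `n_reps`.
#' @export
run_consistent_experiment <- function(trajs) {
  nT <- dim(trajs$states)[3]
  est <- t(vapply(seq_len(nT), function(k) {
    fit <- fit_interaction_model(standardize(crosssection_at(trajs, k)))
    fit$coefficients[interaction_terms()]
  }, numeric(5)))
  colnames(est) <- interaction_terms()
  out <- summarize_estimates(est)
  class(out) <- c("experiment_summary", "data.frame")
  out
}

#' Random-time sampling experiment
#'
#' Repeats: draw one uniform random visit per subject, optionally partial
#' sampling time (exact, or jittered by Gaussian noise when `sd_fraction` is
#' given) out of the main-effect variables, standardize, and fit the
#' interaction regression. Term estimates are summarized across repetitions
#' by mean and 2.5-97.5 percentile interval.
#'
#' @param trajs a `trajectory_set`.
#' @param reps number of independent random cross-sections.
#' @param residualize partial time out before fitting?
#' @param sd_fraction optional noise SD for the time regressor, as a fraction
#'   of `interval_months`; `NULL` uses the exact sampling times.
#' @param variables columns passed to [residualize_on_time()].
#' @param interval_months scaling interval for the time noise.
#' @param seed integer seed; repetition `r` derives its own stream from it.
#' @return An `experiment_summary` data frame.
#' @export
run_random_experiment <- function(trajs, reps = 1000L, residualize = FALSE,
                                  sd_fraction = NULL,
                                  variables = c("ADAS", "HippoV", "CSFtau",
                                                "AV45"),
                                  interval_months = 186, seed = 1L) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  est <- t(vapply(seq_len(reps), function(r) {
    cs <- crosssection_random(trajs, seed = seed + 7L * r)
    if (residualize) {
      if (!is.null(sd_fraction) && sd_fraction > 0) {
        cs$noisy_time_months <- jitter_time(cs$sampling_time_months,
                                            sd_fraction, interval_months,
                                            seed = seed + 7L * r + 3L)
        cs <- residualize_on_time(cs, variables, use_noisy_time = TRUE)
      } else {
        cs <- residualize_on_time(cs, variables)
      }
    }
    fit <- fit_interaction_model(standardize(cs))
    fit$coefficients[interaction_terms()]
  }, numeric(5)))
  colnames(est) <- interaction_terms()
  out <- summarize_estimates(est)
  class(out) <- c("experiment_summary", "data.frame")
  out
}

#' Sensitivity of time residualization to staging noise
#'
#' Runs the residualized random-sampling experiment across a grid of
#' time-noise magnitudes (default 5%..100% of the interval in 5% steps) and
#' returns the two moderation terms' summaries per noise fraction. As the
#' noise grows the residualization regressor decouples from true disease
#' time, and the faux interactions reappear.
#'
#' @inheritParams run_random_experiment
#' @param fractions noise SD fractions to sweep.
#' @return Data frame `(fraction, term, mean, lo, hi, n_reps)` restricted to
#'   the two interaction terms.
#' @export
noise_sensitivity_sweep <- function(trajs, fractions = seq(0.05, 1, by = 0.05),
                                    reps = 1000L, interval_months = 186,
                                    seed = 1L) {
  if (any(fractions <= 0)) stop("fractions must be positive", call. = FALSE)
  res <- lapply(seq_along(fractions), function(i) {
    s <- run_random_experiment(trajs, reps = reps, residualize = TRUE,
                               sd_fraction = fractions[i],
                               interval_months = interval_months,
                               seed = seed + 1000L * i)
    s <- s[s$term %in% c("AV45:HippoV", "CSFtau:HippoV"), ]
    cbind(fraction = fractions[i], s)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Agreement between predicted and observed panels
#'
#' Per-variable simple linear regression of observed values on model
#' predictions over matched (subject, time) records; reports the standardized
#' slope and adjusted R-squared, the agreement metric used to judge how much
#' of the observed temporal evolution the cascade model captures.
#'
#' @param predicted,observed longitudinal panels with identical
#'   (subject_id, time_months) records.
#' @return Data frame with `variable`, `std_slope`, `adj_r_squared`, `n`.
#' @export
agreement_regression <- function(predicted, observed) {
  key_p <- paste(predicted$subject_id, predicted$time_months)
  key_o <- paste(observed$subject_id, observed$time_months)
  m <- match(key_p, key_o)
  if (anyNA(m) || length(key_p) != length(key_o)) {
    stop("predicted and observed panels must have matching (subject, time) ",
         "records", call. = FALSE)
  }
  observed <- observed[m, ]
  vars <- c("ADAS", "HippoV", "CSFtau", "AV45")
  n <- nrow(predicted)
  if (n < 3) stop("need >= 3 matched pairs", call. = FALSE)
  out <- lapply(vars, function(v) {
    x <- scale(predicted[[v]])[, 1]
    y <- scale(observed[[v]])[, 1]
    fit <- stats::lm(y ~ x)
    data.frame(variable = v,
               std_slope = unname(stats::coef(fit)[2]),
               adj_r_squared = summary(fit)$adj.r.squared,
               n = n)
  })
  do.call(rbind, out)
}
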