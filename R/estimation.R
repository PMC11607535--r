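panel_var <- function(label) {
  c("ADAS-cog" = "ADAS", "HippoV" = "HippoV",
    "CSFtau" = "CSFtau", "AV45" = "AV45")[[label]]
}

#' Enumerate the nested mixed-model family for one cascade variable
#'
#' For a dependent variable, every admissible combination of its cascade
#' predecessors as predictors: each predecessor may be absent, enter as a
#' main effect, or enter as main effect plus its interaction with time
#' (the hierarchy constraint: an interaction implies its main effect).
#' The no-biomarker model (time and covariates only) is always included.
#' Predecessor sets follow the cascade order: the cognitive outcome may
#' depend on all three biomarkers, hippocampal volume on CSF tau and
#' amyloid-PET, CSF tau on amyloid-PET, and amyloid-PET on none.
#'
#' @param dependent variable index in cascade order (1 = outcome .. 4).
#' @param labels variable ordering.
#' @param hierarchical if `FALSE`, also allow interaction-only terms
#'   (statistically ill-posed; provided for completeness).
#' @return List of model specs: each a list with `dependent`, `main` and
#'   `time_interactions` (character vectors of predecessor labels).
#' @export
enumerate_model_family <- function(dependent, labels = cascade_labels(),
                                   hierarchical = TRUE) {
  n <- length(labels)
  if (dependent < 1 || dependent > n) stop("dependent out of range",
                                           call. = FALSE)
  preds <- if (dependent < n) labels[(dependent + 1L):n] else character(0)
  states <- if (hierarchical) c("absent", "main", "main_int") else
    c("absent", "main", "int", "main_int")
  grids <- rep(list(states), length(preds))
  combos <- if (length(preds)) expand.grid(grids, stringsAsFactors = FALSE) else
    data.frame(row.names = 1)
  lapply(seq_len(nrow(combos)), function(r) {
    st <- if (length(preds)) unlist(combos[r, , drop = TRUE]) else character(0)
    list(dependent = dependent,
         main = preds[st %in% c("main", "main_int")],
         time_interactions = preds[st %in% c("int", "main_int")])
  })
}

spec_label <- function(spec, labels = cascade_labels()) {
  parts <- c(spec$main,
             if (length(spec$time_interactions))
               paste0(spec$time_interactions, ":time"))
  if (!length(parts)) "time + covariates only" else
    paste(parts, collapse = " + ")
}

#' Fit one mixed model of the cascade family
#'
#' Linear mixed model of a cascade variable on time (in model units), its
#' selected predecessor main effects and predecessor-by-time interactions,
#' with age and education as fixed covariates and a per-subject random
#' intercept:
#' \deqn{x_i = \alpha_i t + \sum_j \beta_{ij} x_j + \sum_j \gamma_{ij} x_j t
#'       + covariates + b_{subject} + \epsilon}
#' The time coefficient estimates the drift \eqn{c_i}; each biomarker-by-time
#' coefficient estimates the coupling \eqn{a_{ij}}.
#'
#' @param panel a longitudinal panel (see [build_panel()]).
#' @param spec one element of [enumerate_model_family()].
#' @param months_per_unit scale mapping `time_months` to model time, so the
#'   fitted coefficients are on the cascade-parameter scale.
#' @param REML fit by REML? Default `FALSE` (maximum likelihood), appropriate
#'   when comparing models differing in fixed effects.
#' @return List with `alpha` (time coefficient), `beta`, `gamma` (named by
#'   predecessor label), `caic`, `marginal_aic`, `converged`, `fit` (the
#'   underlying `lmerMod`), and `spec`.
#' @export
fit_lmm <- function(panel, spec, months_per_unit = 37, REML = FALSE) {
  panel <- validate_panel(panel)
  if (length(unique(panel$subject_id)) < 2L) {
    stop("need >= 2 subjects to fit a random-intercept model", call. = FALSE)
  }
  labels <- cascade_labels()
  dat <- panel
  dat$time_model <- dat$time_months / months_per_unit
  dep <- panel_var(labels[spec$dependent])
  main_cols <- vapply(spec$main, panel_var, character(1))
  int_cols <- vapply(spec$time_interactions, panel_var, character(1))
  for (cc in int_cols) dat[[paste0(cc, "_x_time")]] <-
    dat[[cc]] * dat$time_model
  rhs <- c("time_model", "age_years", "education_years", main_cols,
           if (length(int_cols)) paste0(int_cols, "_x_time"),
           "(1 | subject_id)")
  form <- stats::as.formula(paste(dep, "~", paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = dat, REML = REML)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(alpha = NA_real_, beta = NULL, gamma = NULL,
                caic = Inf, marginal_aic = Inf, converged = FALSE,
                message = conditionMessage(fit), fit = NULL, spec = spec))
  }
  fe <- lme4::fixef(fit)
  gamma <- if (length(int_cols)) {
    g <- fe[paste0(int_cols, "_x_time")]
    names(g) <- spec$time_interactions
    g
  } else NULL
  beta <- if (length(main_cols)) {
    b <- fe[main_cols]
    names(b) <- spec$main
    b
  } else NULL
  ca <- tryCatch(conditional_aic(fit), error = function(e) NA_real_)
  maic <- stats::AIC(fit)
  if (!is.finite(ca)) ca <- maic  # documented fallback
  list(alpha = unname(fe[["time_model"]]), beta = beta, gamma = gamma,
       caic = ca, marginal_aic = maic, converged = TRUE, fit = fit,
       spec = spec)
}

#' Conditional AIC of a random-intercept mixed model
#'
#' Vaida-Blanchard conditional AIC: minus twice the conditional
#' log-likelihood (Gaussian density of the response around the
#' BLUP-including fitted values) plus twice the effective number of
#' parameters, `rho + 1`, where `rho` is the trace of the conditional hat
#' matrix obtained from the mixed-model equations and the `+ 1` counts the
#' residual variance.
#'
#' @param fit an `lmerMod` with a single random-intercept term.
#' @return The cAIC value (scalar).
#' @export
conditional_aic <- function(fit) {
  y <- lme4::getME(fit, "y")
  X <- lme4::getME(fit, "X")
  Z <- as.matrix(lme4::getME(fit, "Z"))
  sigma2 <- stats::sigma(fit)^2
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp != "Residual"][1]
  p <- ncol(X)
  if (!is.finite(tau2) || tau2 < 1e-10) {
    rho <- p
    yhat <- as.vector(X %*% lme4::fixef(fit))
  } else {
    C <- cbind(X, Z)
    CtC <- crossprod(C)
    ridge <- diag(c(rep(0, p), rep(sigma2 / tau2, ncol(Z))))
    rho <- sum(diag(solve(CtC + ridge, CtC)))
    yhat <- stats::fitted(fit)
  }
  cll <- sum(stats::dnorm(y, yhat, sqrt(sigma2), log = TRUE))
  -2 * cll + 2 * (rho + 1)
}

#' Recover cascade parameters from a longitudinal panel
#'
#' For each cascade variable, fits its whole nested model family
#' ([enumerate_model_family()], [fit_lmm()]), selects the fit with minimum
#' conditional AIC, and maps the selected time and biomarker-by-time
#' coefficients into a [cascade_params()] via [params_from_regression()];
#' predecessors absent from the winning model contribute zero coupling
#' entries.
#'
#' @inheritParams fit_lmm
#' @param hierarchical passed to [enumerate_model_family()].
#' @return List with `params` (the assembled [cascade_params()]) and
#'   `report`: a data frame with one row per candidate model (dependent
#'   variable, model formula sketch, cAIC, marginal AIC, convergence,
#'   selected flag).
#' @export
select_and_assemble <- function(panel, months_per_unit = 37, REML = FALSE,
                                hierarchical = TRUE) {
  labels <- cascade_labels()
  alpha <- numeric(length(labels))
  gamma <- stats::setNames(vector("list", length(labels)), labels)
  report <- list()
  for (i in seq_along(labels)) {
    family <- enumerate_model_family(i, labels, hierarchical = hierarchical)
    fits <- lapply(family, function(sp)
      fit_lmm(panel, sp, months_per_unit = months_per_unit, REML = REML))
    caics <- vapply(fits, function(f)
      if (f$converged) f$caic else Inf, numeric(1))
    if (!any(is.finite(caics))) {
      stop("all candidate models failed for ", labels[i], call. = FALSE)
    }
    n_failed <- sum(!vapply(fits, `[[`, logical(1), "converged"))
    if (n_failed > 0) {
      warning(n_failed, " candidate model(s) for ", labels[i],
              " failed to converge and were excluded", call. = FALSE)
    }
    best <- which.min(caics)
    alpha[i] <- fits[[best]]$alpha
    gamma[[labels[i]]] <- fits[[best]]$gamma
    report[[i]] <- data.frame(
      dependent = labels[i],
      model = vapply(family, spec_label, character(1)),
      caic = vapply(fits, `[[`, numeric(1), "caic"),
      marginal_aic = vapply(fits, `[[`, numeric(1), "marginal_aic"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      selected = seq_along(fits) == best
    )
  }
  gamma <- Filter(Negate(is.null), gamma)
  params <- params_from_regression(alpha, gamma, labels = labels)
  list(params = params, report = do.call(rbind, report))
}
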