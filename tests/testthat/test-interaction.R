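test_that("standardization gives mean 0, SD 1 and is idempotent", {
  tr <- make_trajs(n = 300, seed = 1)
  cs <- crosssection_random(tr, seed = 2)
  z <- standardize(cs)
  for (v in c("ADAS", "HippoV", "CSFtau", "AV45")) {
    expect_lt(abs(mean(z[[v]])), 1e-10)
    expect_lt(abs(sd(z[[v]]) - 1), 1e-10)
  }
  z2 <- standardize(z)
  expect_equal(z2$ADAS, z$ADAS, tolerance = 1e-10)
  cs$AV45 <- 1
  expect_error(standardize(cs), "zero variance")
})

test_that("interaction OLS recovers known generative coefficients", {
  set.seed(3)
  n <- 5000
  cs <- make_cross_section(cbind(0, rnorm(n), rnorm(n), rnorm(n)),
                           rep(c(6, 12, 18), length.out = n))
  # main effects only
  cs$ADAS <- 0.2 * cs$AV45 - 0.7 * cs$HippoV + rnorm(n, sd = 0.1)
  fit <- fit_interaction_model(standardize(cs))
  truth <- c(AV45 = 0.2, CSFtau = 0, HippoV = -0.7,
             "AV45:HippoV" = 0, "CSFtau:HippoV" = 0)
  # generative scale: outcome sd ~ sqrt(.04+.49+.01), coefficients shrink by it
  sc <- sd(cs$ADAS)
  for (term in names(truth)) {
    expect_lt(abs(fit$coefficients[[term]] - truth[[term]] / sc),
              3 * fit$se[[term]])
  }

  # built-in product term
  cs$ADAS <- 0.15 * cs$AV45 * cs$HippoV + rnorm(n, sd = 0.1)
  fit2 <- fit_interaction_model(standardize(cs))
  expect_lt(abs(fit2$coefficients[["AV45:HippoV"]] -
                  0.15 / sd(cs$ADAS)), 3 * fit2$se[["AV45:HippoV"]])

  # duplicated biomarker column: rank deficiency is an error
  cs$CSFtau <- cs$AV45
  expect_error(fit_interaction_model(standardize(cs)), "rank-deficient")
})

test_that("consistent experiment aggregates per-visit fits", {
  # static dynamics: every visit shows the same cross-section
  p0 <- cascade_params(matrix(0, 4, 4), rep(0, 4))
  tr0 <- make_trajs(n = 400, seed = 5, params = p0, grid = c(6, 60, 120))
  s0 <- run_consistent_experiment(tr0)
  expect_equal(s0$mean, s0$lo)
  expect_equal(s0$mean, s0$hi)
  expect_equal(s0$n_reps, rep(3, 5))

  s <- run_consistent_experiment(make_trajs(n = 400, seed = 5))
  expect_identical(s$term,
                   c("AV45", "CSFtau", "HippoV", "AV45:HippoV",
                     "CSFtau:HippoV"))
  expect_true(all(s$lo <= s$mean & s$mean <= s$hi))
})

test_that("random experiment summarizes repetitions; reps = 1 is degenerate", {
  tr <- make_trajs(n = 400, seed = 6)
  s1 <- run_random_experiment(tr, reps = 1, seed = 7)
  expect_equal(s1$lo, s1$mean)
  expect_equal(s1$hi, s1$mean)
  cs <- standardize(crosssection_random(tr, seed = 7 + 7))
  direct <- fit_interaction_model(cs)
  expect_equal(s1$mean, unname(direct$coefficients[s1$term]))
})

test_that("agreement regression reports standardized slope and adjusted R2", {
  tr <- make_trajs(n = 200, seed = 8, grid = seq(6, 180, 12))
  cfg <- cohort_config(n_subjects = 200, visit_grid_months = seq(6, 180, 12),
                       seed = 8)
  pred <- build_panel(tr, cfg)

  # observed == predicted (lm warns about the perfect fit; that is the point)
  ag <- suppressWarnings(agreement_regression(pred, pred))
  expect_equal(ag$std_slope, rep(1, 4), tolerance = 1e-10)
  expect_equal(ag$adj_r_squared, rep(1, 4), tolerance = 1e-10)

  # noise calibrated for R^2 ~ 0.8: y = x + e, var(e)/var(x) = 0.25
  obs <- pred
  set.seed(9)
  for (v in c("ADAS", "HippoV", "CSFtau", "AV45")) {
    obs[[v]] <- pred[[v]] + rnorm(nrow(pred), 0, 0.5 * sd(pred[[v]]))
  }
  ag2 <- agreement_regression(pred, obs)
  expect_true(all(abs(ag2$adj_r_squared - 0.8) < 0.03))

  # observed independent of predicted
  obs3 <- pred
  set.seed(10)
  for (v in c("ADAS", "HippoV", "CSFtau", "AV45")) {
    obs3[[v]] <- rnorm(nrow(pred))
  }
  ag3 <- agreement_regression(pred, obs3)
  expect_true(all(abs(ag3$std_slope) < 0.06))
  expect_true(all(ag3$adj_r_squared < 0.01))

  expect_error(agreement_regression(pred, obs[-1, ]), "matching")
})
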