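test_that("initial-state draws are Gaussian, seeded and validated", {
  d0 <- initial_distribution(mean = c(1, 2, 3, 4),
                             covariance = matrix(0, 4, 4))
  x <- draw_initial_states(d0, 5, seed = 1)
  expect_equal(x, matrix(rep(c(1, 2, 3, 4), each = 5), 5))

  d <- initial_distribution()
  a <- draw_initial_states(d, 100, seed = 9)
  b <- draw_initial_states(d, 100, seed = 9)
  expect_identical(a, b)

  big <- draw_initial_states(d, 50000, seed = 3)
  expect_true(all(abs(colMeans(big)) < 0.02))
  expect_true(all(abs(apply(big, 2, var) - 1) < 0.05))

  bad <- diag(4); bad[1, 2] <- 0.5
  expect_error(initial_distribution(covariance = bad), "symmetric")
  neg <- diag(c(1, 1, 1, -1))
  expect_error(initial_distribution(covariance = neg),
               "positive semi-definite")
})

test_that("trajectory simulation respects the grid and the dynamics", {
  tb <- table1_params()
  x0 <- draw_initial_states(initial_distribution(), 100, seed = 2)
  cfg0 <- cohort_config(n_subjects = 100, visit_grid_months = 0, seed = 2)
  tr0 <- simulate_trajectories(tb, x0, cfg0)
  expect_equal(tr0$states[, , 1], x0)

  cfg <- cohort_config(n_subjects = 100, seed = 2)
  tr <- simulate_trajectories(tb, x0, cfg)
  # constant positive drift: amyloid strictly increases along the grid
  av45 <- tr$states[, 4, ]
  expect_true(all(diff(t(av45)) > 0))
  # on average cognition worsens and hippocampal volume shrinks over follow-up
  expect_gt(mean(tr$states[, 1, 31]), mean(tr$states[, 1, 1]))
  expect_lt(mean(tr$states[, 2, 31]), mean(tr$states[, 2, 1]))

  # reserve path with zero coefficient equals the closed form
  trz <- simulate_trajectories(tb, x0, cfg,
                               reserve = reserve_spec(coefficient = 0))
  expect_lt(max(abs(trz$states - tr$states)), 1e-8)
})

test_that("panel construction, demographics and noise behave as configured", {
  tb <- table1_params()
  cfg <- cohort_config(n_subjects = 2, seed = 4)
  tr <- make_trajs(n = 2, seed = 4)
  panel <- build_panel(tr, cfg)
  expect_equal(nrow(panel), 2 * 31)
  expect_identical(names(panel), panel_columns())

  cfg10k <- cohort_config(n_subjects = 10000, visit_grid_months = c(6, 12),
                          seed = 6)
  tr10k <- make_trajs(n = 10000, seed = 6, grid = c(6, 12))
  p10k <- build_panel(tr10k, cfg10k)
  ages <- p10k$age_years[!duplicated(p10k$subject_id)]
  expect_lt(abs(mean(ages) - 72.8), 0.2)

  # observation noise: sd = 0 is a no-op; unit sd adds unit variance
  expect_identical(add_observation_noise(panel, rep(0, 4), seed = 1), panel)
  big <- build_panel(make_trajs(n = 2000, seed = 8, grid = seq(6, 120, 6)),
                     cohort_config(n_subjects = 2000,
                                   visit_grid_months = seq(6, 120, 6),
                                   seed = 8))
  noisy <- add_observation_noise(big, rep(1, 4), seed = 9)
  for (v in c("ADAS", "HippoV", "CSFtau", "AV45")) {
    expect_lt(abs(var(noisy[[v]] - big[[v]]) - 1), 0.03)
  }
  expect_identical(add_observation_noise(big, rep(1, 4), seed = 9), noisy)
})

test_that("panel CSV round-trips and validates", {
  tb <- table1_params()
  cfg <- cohort_config(n_subjects = 3, visit_grid_months = c(6, 12, 18),
                       seed = 5)
  tr <- make_trajs(n = 3, seed = 5, grid = c(6, 12, 18))
  panel <- build_panel(tr, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back, panel, tolerance = 1e-12)

  # empty panel: header-only file
  write_panel(panel[0, ], path)
  expect_equal(nrow(read_panel(path)), 0)
  expect_identical(readLines(path)[1], paste(panel_columns(), collapse = ","))

  # duplicated (subject, time) rejected
  dup <- rbind(panel, panel[1, ])
  expect_error(write_panel(dup, path), "duplicate")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_panel(path), "malformed")
})
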