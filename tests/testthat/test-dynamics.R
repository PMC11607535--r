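test_that("nilpotent_exponential is exact", {
  A <- random_triangular(7)
  expect_equal(nilpotent_exponential(A, 0), diag(4))
  expect_equal(nilpotent_exponential(matrix(0, 3, 3), 7), diag(3))

  # last cascade variable has no inputs: its exp row stays the identity row
  tb <- table1_params()
  E <- nilpotent_exponential(tb$A, 1)
  expect_equal(E[4, ], c(0, 0, 0, 1))

  # independent oracle: scaling-and-squaring matrix exponential
  E1 <- nilpotent_exponential(A, 0.5)
  E2 <- as.matrix(Matrix::expm(Matrix::Matrix(0.5 * A)))
  expect_lt(max(abs(E1 - E2)), 1e-12)

  expect_error(nilpotent_exponential(matrix(1, 2, 3), 1), "square")
  expect_error(nilpotent_exponential(diag(2), 1), "triangular")
})

test_that("closed-form propagation solves the linear system exactly", {
  tb <- table1_params()
  set.seed(11)
  x0 <- rnorm(4)
  expect_equal(propagate_closed_form(tb, x0, 0), x0)

  # decoupled last component: x4(t) = x4(0) + c4 t
  z <- propagate_closed_form(tb, rep(0, 4), 1)
  expect_equal(z[4], 0.19057)

  # oracle: Dormand-Prince integration of the same rhs
  grid <- c(0, seq(0.5, 5, by = 0.5))
  num <- integrate_numeric(function(x) linear_rhs(tb, x), x0, grid)
  cf <- t(vapply(grid, function(t) propagate_closed_form(tb, x0, t),
                 numeric(4)))
  expect_lt(max(abs(num$states - cf)), 1e-8)

  expect_error(propagate_closed_form(tb, rnorm(3), 1), "length")
  expect_error(propagate_closed_form(tb, x0, -1), "non-negative")
})

test_that("propagation satisfies semigroup and superposition properties", {
  for (seed in 1:5) {
    p <- random_cascade_params(seed)
    set.seed(seed + 100)
    x0 <- rnorm(4)
    s <- runif(1, 0, 3)
    t <- runif(1, 0, 3)
    two_step <- propagate_closed_form(p, propagate_closed_form(p, x0, s), t)
    one_step <- propagate_closed_form(p, x0, s + t)
    expect_lt(max(abs(two_step - one_step)), 1e-10)

    # x(t; x0) - x(t; 0) is linear in x0
    y0 <- rnorm(4)
    h <- propagate_closed_form(p, rep(0, 4), t)
    fx <- propagate_closed_form(p, x0, t) - h
    fy <- propagate_closed_form(p, y0, t) - h
    fxy <- propagate_closed_form(p, x0 + y0, t) - h
    expect_lt(max(abs(fxy - (fx + fy))), 1e-10)
  }
})

test_that("linear and reserve right-hand sides match hand arithmetic", {
  tb <- table1_params()
  expect_equal(linear_rhs(tb, rep(0, 4)), tb$c)
  # from the printed cells: unit hippocampal volume input
  r <- linear_rhs(tb, c(0, 1, 0, 0))
  expect_equal(r[1], -0.23286 + -0.08587)
  expect_equal(r[2], -0.42319)
  p0 <- cascade_params(matrix(0, 4, 4), c(1, 2, 3, 4))
  expect_equal(linear_rhs(p0, rnorm(4)), p0$c)

  res <- reserve_spec()
  expect_equal(res$coefficient, -0.1)
  # x2 = 0: both products vanish
  x <- c(0.5, 0, 1, 1)
  expect_equal(reserve_rhs(tb, res, x), linear_rhs(tb, x))
  # unit values: addend = -0.1 * (1 + 1)
  x1 <- c(0, 1, 1, 1)
  expect_equal(reserve_rhs(tb, res, x1)[1] - linear_rhs(tb, x1)[1], -0.2)
  # sign flip
  x2 <- c(0, -1, 1, 0)
  expect_equal(reserve_rhs(tb, res, x2)[1] - linear_rhs(tb, x2)[1], 0.1)
  expect_error(reserve_spec(target = 5), "out of range")
})

test_that("numeric integration is Dormand-Prince accurate and validated", {
  sol <- integrate_numeric(function(x) -x, 1, c(0, 1))
  expect_equal(sol$states[2, 1], exp(-1), tolerance = 1e-8)

  # reserve term damps the outcome relative to the linear model
  tb <- table1_params()
  res <- reserve_spec()
  grid <- c(0, 1, 2, 3)
  lin <- t(vapply(grid, function(t)
    propagate_closed_form(tb, c(0, 1, 1, 1), t), numeric(4)))
  nl <- integrate_numeric(function(x) reserve_rhs(tb, res, x),
                          c(0, 1, 1, 1), grid)$states
  expect_true(all(nl[-1, 1] < lin[-1, 1]))

  # zero reserve coefficient degenerates to the linear model
  res0 <- reserve_spec(coefficient = 0)
  nl0 <- integrate_numeric(function(x) reserve_rhs(tb, res0, x),
                           c(0, 1, 1, 1), grid)$states
  expect_lt(max(abs(nl0 - lin)), 1e-8)

  expect_error(integrate_numeric(function(x) -x, 1, c(1, 0)), "increasing")
  expect_error(integrate_numeric(function(x) -x, 1, c(0, 1), rel_tol = 0),
               "positive")
})
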