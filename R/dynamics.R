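#' Exact matrix exponential of a nilpotent matrix
#'
#' For a strictly triangular (hence nilpotent) `A`, the Taylor series of
#' `exp(t A)` terminates: `A^n == 0`, so
#' \deqn{e^{tA} = \sum_{k=0}^{n-1} \frac{t^k}{k!} A^k}
#' is exact, not an approximation.
#'
#' @param A strictly upper- (or lower-) triangular square matrix.
#' @param t scalar time.
#' @return The matrix `exp(t A)`, exactly.
#' @export
nilpotent_exponential <- function(A, t) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != ncol(A)) stop("A must be square", call. = FALSE)
  strict_upper <- all(A[lower.tri(A, diag = TRUE)] == 0)
  strict_lower <- all(A[upper.tri(A, diag = TRUE)] == 0)
  if (!strict_upper && !strict_lower) {
    stop("A must be strictly triangular", call. = FALSE)
  }
  out <- diag(n)
  term <- diag(n)
  for (k in seq_len(n - 1L)) {
    term <- term %*% A * (t / k)
    out <- out + term
  }
  out
}

# Finite-series building blocks of the inhomogeneous solution:
#   x(t) = e^{tA} x0 + e^{tA} * S(t) c,
#   S(t) = int_0^t e^{-sA} ds = sum_{k=0}^{n-1} (-1)^k t^{k+1} / (k! (k+1)) A^k
propagator_matrices <- function(params, t) {
  A <- params$A
  n <- params$n
  expA <- nilpotent_exponential(A, t)
  S <- diag(n) * t
  term <- diag(n)
  for (k in seq_len(n - 1L)) {
    term <- term %*% A * (-1 / k)          # (-1)^k A^k / k!
    S <- S + term * (t^(k + 1) / (k + 1))
  }
  list(expA = expA, drift = as.vector(expA %*% S %*% params$c))
}

#' Propagate the linear cascade in closed form
#'
#' Exact solution of \eqn{dx/dt = A x + c} at time `t`:
#' \deqn{x(t) = e^{tA} x_0 + e^{tA} \int_0^t e^{-sA} ds \; c}
#' with both matrix exponentials evaluated by their terminating Taylor sums
#' (see [nilpotent_exponential()]).
#'
#' @param params a [cascade_params()] object.
#' @param x0 initial state: a length-n vector, or an m x n matrix of initial
#'   states (one row per subject).
#' @param t non-negative scalar time, in model-time units.
#' @return State at time `t`, same shape as `x0`.
#' @export
propagate_closed_form <- function(params, x0, t) {
  validate_cascade_params(params)
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  mats <- propagator_matrices(params, t)
  if (is.matrix(x0)) {
    if (ncol(x0) != params$n) stop("x0 has ", ncol(x0), " columns; expected ",
                                   params$n, call. = FALSE)
    sweep(x0 %*% t(mats$expA), 2L, mats$drift, "+")
  } else {
    if (length(x0) != params$n) stop("x0 has length ", length(x0),
                                     "; expected ", params$n, call. = FALSE)
    as.vector(mats$expA %*% x0) + mats$drift
  }
}

#' Rate of change under the linear cascade
#'
#' Evaluates \eqn{A x + c}.
#'
#' @inheritParams propagate_closed_form
#' @param x state vector (length n) or m x n state matrix.
#' @return Rate vector/matrix, same shape as `x`.
#' @export
linear_rhs <- function(params, x) {
  if (is.matrix(x)) {
    if (ncol(x) != params$n) stop("dimension mismatch", call. = FALSE)
    sweep(x %*% t(params$A), 2L, params$c, "+")
  } else {
    if (length(x) != params$n) stop("dimension mismatch", call. = FALSE)
    as.vector(params$A %*% x) + params$c
  }
}

#' Cognitive-reserve interaction term specification
#'
#' The reserve-extended model adds a product term to one component's rate:
#' with the defaults,
#' \deqn{dx_1/dt \mathrel{+}= -0.1\,(x_2 x_3 + x_2 x_4)}
#' so that at higher hippocampal volume (`x2`) the detrimental effect of CSF
#' tau (`x3`) and amyloid-PET (`x4`) on the cognitive outcome accrues more
#' slowly — a built-in moderation effect.
#'
#' @param coefficient scalar multiplier of the summed products (default -0.1).
#' @param target index of the rate component receiving the term (default 1,
#'   the cognitive outcome).
#' @param pairs list of index pairs multiplied inside the sum; default
#'   `list(c(2, 3), c(2, 4))`.
#' @param n state dimension used for index validation.
#' @return An object of class `reserve_spec`.
#' @export
reserve_spec <- function(coefficient = -0.1, target = 1L,
                         pairs = list(c(2L, 3L), c(2L, 4L)), n = 4L) {
  idx <- c(target, unlist(pairs))
  if (any(idx < 1L | idx > n)) stop("reserve indices out of range", call. = FALSE)
  if (any(lengths(pairs) != 2L)) stop("each factor pair needs two indices",
                                      call. = FALSE)
  structure(list(coefficient = coefficient, target = as.integer(target),
                 pairs = lapply(pairs, as.integer), n = as.integer(n)),
            class = "reserve_spec")
}

#' Rate of change under the reserve-extended cascade
#'
#' [linear_rhs()] plus the reserve product term on the target component.
#'
#' @inheritParams linear_rhs
#' @param reserve a [reserve_spec()].
#' @return Rate vector/matrix, same shape as `x`.
#' @export
reserve_rhs <- function(params, reserve, x) {
  out <- linear_rhs(params, x)
  if (is.matrix(x)) {
    add <- 0
    for (p in reserve$pairs) add <- add + x[, p[1]] * x[, p[2]]
    out[, reserve$target] <- out[, reserve$target] + reserve$coefficient * add
  } else {
    add <- 0
    for (p in reserve$pairs) add <- add + x[p[1]] * x[p[2]]
    out[reserve$target] <- out[reserve$target] + reserve$coefficient * add
  }
  out
}

#' Integrate cascade dynamics numerically (Dormand-Prince)
#'
#' Adaptive Runge-Kutta 4(5) (Dormand-Prince, deSolve's `"ode45"`) solution of
#' an arbitrary rate function on a time grid. Accepts a matrix of initial
#' states and integrates all subjects as one stacked system, which is how the
#' reserve-extended cohort simulations stay fast.
#'
#' @param rhs function of a state vector (or m x n state matrix) returning
#'   rates of the same shape, e.g. `function(x) reserve_rhs(params, res, x)`.
#' @param x0 initial state vector, or m x n matrix of initial states.
#' @param times ascending non-negative output grid (model-time units); the
#'   first entry is the initial time.
#' @param rel_tol,abs_tol solver tolerances.
#' @return For vector `x0`, a list with `times` and a `length(times) x n`
#'   matrix `states`. For matrix `x0`, `states` is an
#'   m x n x length(times) array.
#' @export
integrate_numeric <- function(rhs, x0, times, rel_tol = 1e-8,
                              abs_tol = 1e-10) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1] < 0) stop("times must be non-negative", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be positive",
                                         call. = FALSE)
  mat_input <- is.matrix(x0)
  m <- if (mat_input) nrow(x0) else 1L
  nvar <- if (mat_input) ncol(x0) else length(x0)
  deriv <- function(t, y, parms) {
    x <- if (mat_input) matrix(y, nrow = m) else y
    list(as.vector(rhs(x)))
  }
  sol <- deSolve::ode(y = as.vector(x0), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    bad <- if (nrow(sol) >= 1) sol[nrow(sol), 1] else times[1]
    stop("numeric integration failed near t = ", bad, call. = FALSE)
  }
  vals <- unname(sol[, -1, drop = FALSE])
  if (mat_input) {
    states <- array(t(vals), dim = c(m, nvar, length(times)))
    list(times = times, states = states)
  } else {
    list(times = times, states = vals)
  }
}
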