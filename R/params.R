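#' Cascade model parameters
#'
#' Container for the linear biomarker-cascade model \eqn{dx/dt = A x + c}.
#' The state ordering is inverse to the cascade's chronological order: the
#' cognitive outcome first, then the biomarkers that precede it, so that each
#' variable's rate may depend only on variables *later* in the vector. Under
#' that ordering `A` is strictly upper triangular and therefore nilpotent
#' (`A^n == 0` exactly), which makes the matrix exponential a finite sum.
#'
#' @param A n x n coupling matrix, strictly upper triangular. Entry `A[i, j]`
#'   is the contribution of variable `j` (in z-units) to the rate of change of
#'   variable `i` (z-units per model-time unit).
#' @param c length-n drift vector: rate of change of each variable at the
#'   origin of state space (z-units per model-time unit).
#' @param labels ordered variable names; defaults to the four-variable AD
#'   cascade `c("ADAS-cog", "HippoV", "CSFtau", "AV45")` when `A` is 4 x 4.
#' @return An object of class `cascade_params` with elements `A`, `c`,
#'   `labels` and `n`.
#' @examples
#' p <- table1_params()
#' p$A
#' linear_rhs(p, c(0, 1, 0, 0))
#' @export
cascade_params <- function(A, c, labels = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  c <- as.numeric(c)
  n <- nrow(A)
  if (is.null(labels)) {
    labels <- if (n == 4L) cascade_labels() else paste0("x", seq_len(n))
  }
  obj <- structure(
    list(A = unname(A), c = c, labels = as.character(labels), n = n),
    class = "cascade_params"
  )
  validate_cascade_params(obj)
  obj
}

#' Default variable ordering of the four-variable AD cascade
#'
#' Cognitive outcome first, then its cascade predecessors: hippocampal volume,
#' CSF total tau, amyloid-PET (AV45).
#' @return Character vector of length 4.
#' @export
cascade_labels <- function() c("ADAS-cog", "HippoV", "CSFtau", "AV45")

#' Validate cascade parameters
#'
#' Checks squareness, dimension agreement, finiteness, strict upper
#' triangularity of `A` and exact nilpotency (`A^n == 0`).
#'
#' @param params object to validate.
#' @return `params`, invisibly; errors otherwise.
#' @export
validate_cascade_params <- function(params) {
  if (!inherits(params, "cascade_params")) {
    stop("not a cascade_params object", call. = FALSE)
  }
  A <- params$A
  n <- params$n
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("A must be a square matrix", call. = FALSE)
  }
  if (length(params$c) != n) {
    stop("length of c (", length(params$c), ") does not match dim(A) = ", n,
         call. = FALSE)
  }
  if (length(params$labels) != n) {
    stop("labels length does not match dimension", call. = FALSE)
  }
  if (!all(is.finite(A)) || !all(is.finite(params$c))) {
    stop("A and c must be finite", call. = FALSE)
  }
  if (any(A[lower.tri(A, diag = TRUE)] != 0)) {
    stop("A must be strictly upper triangular (zero diagonal and below) ",
         "under the cascade ordering", call. = FALSE)
  }
  An <- matrix_power(A, n)
  if (any(An != 0)) stop("A is not nilpotent: A^n != 0", call. = FALSE)
  invisible(params)
}

matrix_power <- function(A, k) {
  out <- diag(nrow(A))
  for (i in seq_len(k)) out <- out %*% A
  out
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Linear biomarker-cascade parameters (dx/dt = A x + c)\n")
  M <- cbind(x$A, c = x$c)
  dimnames(M) <- list(x$labels, c(x$labels, "c"))
  print(M, ...)
  invisible(x)
}

#' Parameters printed for the empirical AD cascade fit
#'
#' The coupling matrix and drift estimated from the ADNI-derived longitudinal
#' panel (mixed-model coefficients mapped via [params_from_regression()]),
#' shipped as a JSON fixture. Units are z-scores per model-time unit.
#'
#' @return A [cascade_params()] object.
#' @export
table1_params <- function() {
  read_cascade_params(system.file("extdata", "table1.json",
                                  package = "cascadebias", mustWork = TRUE))
}

#' Read / write cascade parameters as JSON
#'
#' The on-disk schema is `{"labels": [...], "A": [[...], ...], "c": [...]}`
#' with `A` in row-major nested arrays.
#'
#' @param path file path.
#' @return `read_cascade_params` returns a [cascade_params()] object;
#'   `write_cascade_params` returns `path` invisibly.
#' @export
read_cascade_params <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!all(c("labels", "A", "c") %in% names(obj))) {
    stop("params JSON must contain 'labels', 'A' and 'c'", call. = FALSE)
  }
  cascade_params(obj$A, obj$c, labels = obj$labels)
}

#' @rdname read_cascade_params
#' @param params a [cascade_params()] object.
#' @export
write_cascade_params <- function(params, path) {
  validate_cascade_params(params)
  jsonlite::write_json(
    list(labels = params$labels, A = params$A, c = params$c),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Assemble cascade parameters from regression coefficients
#'
#' Maps per-variable mixed-model coefficients into the ODE system: the
#' time coefficient \eqn{\alpha_i} becomes the drift entry \eqn{c_i}, and each
#' biomarker-by-time coefficient \eqn{\gamma_{ij}} becomes the coupling entry
#' \eqn{a_{ij}}. Predictors absent from a variable's selected model yield zero
#' entries. A gamma entry naming a predictor that does not come later in the
#' cascade ordering violates triangularity and is rejected.
#'
#' @param alpha named or ordered numeric vector of per-variable time
#'   coefficients (one per cascade variable).
#' @param gamma list, one element per variable (named by variable or in
#'   cascade order), each a named numeric vector mapping predictor label to
#'   its biomarker-by-time coefficient. Empty or missing elements mean no
#'   couplings for that variable.
#' @param labels variable ordering; defaults to [cascade_labels()].
#' @return A [cascade_params()] object.
#' @examples
#' params_from_regression(
#'   alpha = c(-0.1, -0.4, 0.1, 0.2),
#'   gamma = list("ADAS-cog" = c(HippoV = -0.2))
#' )
#' @export
params_from_regression <- function(alpha, gamma = list(),
                                   labels = cascade_labels()) {
  n <- length(labels)
  if (length(alpha) != n) stop("alpha must have one entry per variable",
                               call. = FALSE)
  if (!is.null(names(alpha)) && !all(names(alpha) == "")) {
    if (!setequal(names(alpha), labels)) {
      stop("alpha names do not match labels", call. = FALSE)
    }
    alpha <- alpha[labels]
  }
  A <- matrix(0, n, n)
  if (length(gamma)) {
    gnames <- names(gamma)
    if (is.null(gnames)) gnames <- labels[seq_along(gamma)]
    for (k in seq_along(gamma)) {
      gi <- gamma[[k]]
      if (is.null(gi) || length(gi) == 0) next
      i <- match(gnames[k], labels)
      if (is.na(i)) stop("unknown variable in gamma: ", gnames[k],
                         call. = FALSE)
      for (pred in names(gi)) {
        j <- match(pred, labels)
        if (is.na(j)) stop("unknown predictor in gamma: ", pred, call. = FALSE)
        if (j <= i) {
          stop("gamma entry ", gnames[k], " ~ ", pred,
               " violates the cascade ordering (predictors must come later ",
               "in the state vector)", call. = FALSE)
        }
        A[i, j] <- unname(gi[[pred]])
      }
    }
  }
  cascade_params(A, unname(alpha), labels = labels)
}
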