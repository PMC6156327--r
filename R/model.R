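#' Minimal miR-200/ZEB switch model
#'
#' Constructs the dimensionless two-variable model of the mutually inhibiting
#' miR-200/ZEB circuit with ZEB self-activation. `x1` is the ZEB expression
#' level, `x2` the miR-200 level, and the dynamics are
#' \deqn{dx_1/dt = a x_1^{n_1}/(\theta^{n_1}+x_1^{n_1}) +
#'       c \theta^{n_2}/(\theta^{n_2}+x_2^{n_2}) - k_1 x_1}
#' \deqn{dx_2/dt = b \theta^{n_3}/(\theta^{n_3}+x_1^{n_3}) - k_2 x_2}
#' The upstream SNAIL signal is abstracted into `a` (activation of ZEB) and
#' `b` (repression of miR-200). The two production terms of the ZEB equation
#' are summed (simultaneous, "and"-type regulation).
#'
#' @param a activation strength of ZEB (by signal and by itself), `>= 0`.
#' @param b inhibition strength of miR-200 (by signal and by ZEB), `>= 0`.
#' @param c inhibition strength of ZEB by miR-200, `>= 0`.
#' @param k1,k2 self-degradation rates, `> 0`.
#' @param n1,n2,n3 Hill coefficients (positive integers): self-activation of
#'   ZEB, repression of ZEB by miR-200, repression of miR-200 by ZEB.
#' @param theta Hill threshold, `> 0`.
#' @return An object of class `"emt_model"`.
#' @examples
#' m <- emt_model(a = 1.1, b = 8)
#' drift(m, c(0.5, 0.5))
#' @export
emt_model <- function(a, b, c = 1.0, k1 = 1.0, k2 = 1.0,
                      n1 = 2L, n2 = 6L, n3 = 3L, theta = 0.5) {
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
    as.numeric(x)
  }
  a <- chk_num(a, "a"); b <- chk_num(b, "b"); c <- chk_num(c, "c")
  k1 <- chk_num(k1, "k1"); k2 <- chk_num(k2, "k2")
  theta <- chk_num(theta, "theta")
  if (a < 0 || b < 0 || c < 0)
    stop("regulation strengths 'a', 'b', 'c' must be >= 0", call. = FALSE)
  if (k1 <= 0 || k2 <= 0)
    stop("degradation rates 'k1', 'k2' must be > 0", call. = FALSE)
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  chk_hill <- function(n, nm) {
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
        n < 1 || n != round(n))
      stop("Hill coefficient '", nm, "' must be a positive integer",
           call. = FALSE)
    as.integer(n)
  }
  m <- list(a = a, b = b, c = c, k1 = k1, k2 = k2,
            n1 = chk_hill(n1, "n1"), n2 = chk_hill(n2, "n2"),
            n3 = chk_hill(n3, "n3"), theta = theta)
  class(m) <- "emt_model"
  m
}

#' @export
print.emt_model <- function(x, ...) {
  cat("miR-200/ZEB switch model (x1 = ZEB, x2 = miR-200)\n")
  cat(sprintf("  a = %g, b = %g, c = %g, k1 = %g, k2 = %g\n",
              x$a, x$b, x$c, x$k1, x$k2))
  cat(sprintf("  Hill: n1 = %d, n2 = %d, n3 = %d, theta = %g\n",
              x$n1, x$n2, x$n3, x$theta))
  invisible(x)
}

#' @export
coef.emt_model <- function(object, ...) {
  with(object, c(a = a, b = b, c = c, k1 = k1, k2 = k2,
                 n1 = n1, n2 = n2, n3 = n3, theta = theta))
}

# parameter vector in the order the C++ steppers expect
par_vec <- function(model) as.numeric(coef(model))

as_state <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = length(x) > 2)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("state must have two columns (x1, x2)", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("state coordinates must be finite and >= 0", call. = FALSE)
  x
}

# Hill building blocks, vectorized; limits at 0 handled by 0^n = 0 (n >= 1).
hill_up <- function(x, n, theta) {
  h <- x^n
  h / (theta^n + h)
}
hill_down <- function(x, n, theta) {
  tn <- theta^n
  tn / (tn + x^n)
}

#' Deterministic vector field
#'
#' Evaluates the drift `(dx1/dt, dx2/dt)` of the model at one or more states.
#'
#' @param model an [emt_model()].
#' @param state numeric vector `c(x1, x2)` or an n-by-2 matrix of states.
#' @return A matrix with columns `f1`, `f2` (one row per state).
#' @export
drift <- function(model, state) {
  s <- as_state(state)
  x1 <- s[, 1]; x2 <- s[, 2]
  f1 <- model$a * hill_up(x1, model$n1, model$theta) +
    model$c * hill_down(x2, model$n2, model$theta) - model$k1 * x1
  f2 <- model$b * hill_down(x1, model$n3, model$theta) - model$k2 * x2
  cbind(f1 = f1, f2 = f2)
}

# derivative of x^n/(theta^n + x^n): n theta^n x^(n-1) / (theta^n + x^n)^2
dhill_up <- function(x, n, theta) {
  tn <- theta^n
  n * tn * x^(n - 1) / (tn + x^n)^2
}

#' Analytic Jacobian of the vector field
#'
#' @inheritParams drift
#' @param state numeric vector `c(x1, x2)`.
#' @return A 2x2 matrix of partial derivatives. `J[2,2]` is always `-k2`;
#'   the off-diagonal entries are non-positive (mutual repression).
#' @export
jacobian <- function(model, state) {
  s <- as_state(state)
  if (nrow(s) != 1L) stop("jacobian() takes a single state", call. = FALSE)
  J <- jacobian_entries(model, s[, 1], s[, 2])
  matrix(c(J$j11, J$j21, J$j12, J$j22), 2, 2)
}

# vectorized Jacobian entries at (x1, x2)
jacobian_entries <- function(model, x1, x2) {
  list(
    j11 = model$a * dhill_up(x1, model$n1, model$theta) - model$k1,
    j12 = -model$c * dhill_up(x2, model$n2, model$theta),
    j21 = -model$b * dhill_up(x1, model$n3, model$theta),
    j22 = rep(-model$k2, length(x1))
  )
}

#' miR-200 nullcline
#'
#' The `dx2/dt = 0` locus is the explicit graph
#' `x2 = b theta^n3 / (k2 (theta^n3 + x1^n3))`.
#'
#' @inheritParams drift
#' @param x1 vector of ZEB levels, `>= 0`.
#' @return Vector of miR-200 levels on the nullcline.
#' @export
mirna_nullcline <- function(model, x1) {
  model$b * hill_down(x1, model$n3, model$theta) / model$k2
}

#' Scalar steady-state residual
#'
#' Substituting the miR-200 nullcline into the ZEB equation reduces the 2-D
#' fixed-point problem to one scalar equation `g(x1) = 0`; its roots, lifted by
#' [mirna_nullcline()], are exactly the fixed points of the full system.
#'
#' @inheritParams drift
#' @param x1 vector of ZEB levels, `>= 0`.
#' @return `g(x1)`, vectorized.
#' @export
steady_residual <- function(model, x1) {
  if (any(!is.finite(x1)) || any(x1 < 0))
    stop("'x1' must be finite and >= 0", call. = FALSE)
  x2 <- mirna_nullcline(model, x1)
  model$a * hill_up(x1, model$n1, model$theta) +
    model$c * hill_down(x2, model$n2, model$theta) - model$k1 * x1
}

# d g / d x1, used for Newton polish
steady_residual_deriv <- function(model, x1) {
  x2 <- mirna_nullcline(model, x1)
  dx2 <- -model$b * dhill_up(x1, model$n3, model$theta) / model$k2
  model$a * dhill_up(x1, model$n1, model$theta) -
    model$c * dhill_up(x2, model$n2, model$theta) * dx2 - model$k1
}

# upper end of the invariant box in x1: production <= a + c
x1_upper <- function(model) 1.5 * (model$a + model$c) / model$k1
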