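#' Simulate the model (ODE, Langevin, or delayed)
#'
#' Euler(-Maruyama) integration of the circuit. With `D > 0` each coordinate
#' receives independent Gaussian white noise of intensity `D` (autocorrelation
#' `2 D delta(t-s)`, i.e. increments `sqrt(2 D dt) z`). With `tau > 0` the ZEB
#' self-activation term is evaluated at the delayed value `x1(t - tau)`
#' (constant pre-history equal to the initial state). Both coordinates are
#' reflected at 0. With `D = 0` and `tau = 0` this is plain deterministic
#' Euler stepping.
#'
#' @param object an [emt_model()].
#' @param nsim number of trajectories.
#' @param seed optional integer passed to [set.seed()]; identical seeds give
#'   bit-identical trajectories.
#' @param x0 initial state `c(x1, x2)`.
#' @param t_end final time.
#' @param dt time step, in `(0, 0.01]`.
#' @param D noise intensity `>= 0` (homogeneous, `D1 = D2 = D`).
#' @param tau delay of the ZEB self-activation, `>= 0`; rounded to the nearest
#'   multiple of `dt` (with a message if that changes it).
#' @param thin keep every `thin`-th step.
#' @param ... unused.
#' @return For `nsim = 1` an `"emt_trajectory"` data frame with columns `t`,
#'   `x1`, `x2`; otherwise a list of them.
#' @examples
#' m <- emt_model(a = 1.1, b = 8)
#' tr <- simulate(m, x0 = c(0.05, 7), t_end = 50, D = 0)
#' tail(tr, 1)  # relaxes to the epithelial attractor
#' @export
simulate.emt_model <- function(object, nsim = 1, seed = NULL, x0,
                               t_end = 100, dt = 0.005, D = 0, tau = 0,
                               thin = 1L, ...) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.01)
    stop("'dt' must be in (0, 0.01]", call. = FALSE)
  if (D < 0) stop("'D' must be >= 0", call. = FALSE)
  if (tau < 0) stop("'tau' must be >= 0", call. = FALSE)
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  x0 <- as_state(x0)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- round(t_end / dt)
  tau_steps <- as.integer(round(tau / dt))
  if (tau > 0 && abs(tau_steps * dt - tau) > 1e-12)
    message("tau rounded to ", tau_steps * dt, " (= ", tau_steps, " steps)")
  one <- function() {
    m <- sim_path_cpp(par_vec(object), as.numeric(x0[1, ]), dt,
                      nsteps, D, as.integer(thin), tau_steps)
    out <- data.frame(t = seq(0, by = dt * thin, length.out = nrow(m)),
                      x1 = m[, 1], x2 = m[, 2])
    attr(out, "model") <- object
    attr(out, "config") <- list(dt = dt, t_end = t_end, D = D, tau = tau,
                                thin = thin, x0 = as.numeric(x0[1, ]))
    class(out) <- c("emt_trajectory", "data.frame")
    out
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
plot.emt_trajectory <- function(x, which = c("time", "phase"), ...) {
  which <- match.arg(which)
  if (which == "time") {
    graphics::matplot(x$t, cbind(x$x1, x$x2), type = "l", lty = 1,
                      col = c("firebrick", "steelblue"),
                      xlab = "t", ylab = "expression level", ...)
    graphics::legend("topright", c("x1 (ZEB)", "x2 (miR-200)"),
                     col = c("firebrick", "steelblue"), lty = 1)
  } else {
    plot(x$x1, x$x2, type = "l", xlab = "x1 (ZEB)", ylab = "x2 (miR-200)", ...)
  }
  invisible(x)
}

# stable attractors as a matrix with phenotype rownames
stable_attractors <- function(model) {
  fp <- fixed_points(model)
  st <- fp[fp$stability == "stable", ]
  m <- cbind(x1 = st$x1, x2 = st$x2)
  rownames(m) <- st$phenotype
  m
}
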