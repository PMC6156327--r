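#' Mean first-passage time by direct simulation
#'
#' Averages, over `n_traj` independent Langevin trajectories started at the
#' source attractor, the first time of entry into the capture ball around the
#' target attractor. Trajectories exceeding `t_max` are censored and counted.
#'
#' @param model an [emt_model()].
#' @param D noise intensity `> 0`.
#' @param from,to phenotype labels (`"E"`, `"HYBRID"`, `"M"`) of attractors of
#'   the model, or numeric states `c(x1, x2)`.
#' @param n_traj number of trajectories.
#' @param capture_radius radius of the target ball (reported with the result;
#'   "reaching" a state has no canonical definition).
#' @param dt time step, in `(0, 0.01]`.
#' @param t_max censoring time.
#' @param seed optional seed.
#' @param capture `"ball"` (Euclidean, default) or `"x1"` (threshold on the
#'   ZEB coordinate only, for 1-D reduction checks).
#' @return Object of class `"emt_mfpt"`: list with `mean`, `se`, `n`,
#'   `n_censored`, `times`, plus the configuration. A warning status is set
#'   when more than 10 percent of trajectories were censored.
#' @export
mfpt <- function(model, D, from, to, n_traj = 500L, capture_radius = 0.15,
                 dt = 0.01, t_max = 1e6, seed = NULL,
                 capture = c("ball", "x1")) {
  capture <- match.arg(capture)
  if (D <= 0) stop("'D' must be > 0", call. = FALSE)
  if (dt <= 0 || dt > 0.01) stop("'dt' must be in (0, 0.01]", call. = FALSE)
  resolve <- function(x, what) {
    if (is.character(x)) {
      att <- stable_attractors(model)
      if (!x %in% rownames(att))
        stop("no stable '", x, "' attractor at these parameters",
             call. = FALSE)
      att[x, ]
    } else as.numeric(as_state(x))
  }
  p0 <- resolve(from); p1 <- resolve(to)
  if (!is.null(seed)) set.seed(seed)
  times <- sim_fpt_cpp(par_vec(model), p0, p1, capture_radius, dt, D,
                       t_max, as.integer(n_traj),
                       if (capture == "x1") 1L else 0L)
  ok <- !is.na(times)
  n_cens <- sum(!ok)
  if (n_cens > 0.1 * n_traj)
    warning(n_cens, " of ", n_traj, " trajectories censored at t_max = ",
            t_max)
  structure(list(mean = mean(times[ok]),
                 se = stats::sd(times[ok]) / sqrt(sum(ok)),
                 n = sum(ok), n_censored = n_cens, times = times,
                 from = from, to = to, D = D,
                 capture_radius = capture_radius, dt = dt, t_max = t_max),
            class = "emt_mfpt")
}

#' @export
print.emt_mfpt <- function(x, ...) {
  cat(sprintf("MFPT %s -> %s at D = %g: %.4g (SE %.3g, n = %d%s)\n",
              paste(format(x$from), collapse = ","),
              paste(format(x$to), collapse = ","),
              x$D, x$mean, x$se, x$n,
              if (x$n_censored) paste0(", ", x$n_censored, " censored")
              else ""))
  invisible(x)
}

#' Mean first-passage time by 1-D quadrature
#'
#' For a one-dimensional diffusion with stationary density `Pst` on a grid and
#' constant noise intensity `D`, the passage time from `y1` to `y2 > y1` is
#' \deqn{\tau = \int_{y_1}^{y_2} \frac{dy}{D\,P_{st}(y)}
#'       \int_{0}^{y} P_{st}(q)\,dq,}
#' with the inner integral accumulated from the reflecting boundary (the lower
#' end of the grid) toward `y`. Trapezoidal rule throughout.
#'
#' @param y grid (increasing); the lower end is the reflecting boundary.
#' @param pst stationary density values on `y` (need not be normalized).
#' @param D noise intensity `> 0`.
#' @param y1,y2 start and target, `y1 <= y2`, both inside the grid.
#' @return The passage time (0 when `y1 == y2`).
#' @export
mfpt_quadrature <- function(y, pst, D, y1, y2) {
  if (D <= 0) stop("'D' must be > 0", call. = FALSE)
  if (is.unsorted(y, strictly = TRUE)) stop("'y' must be increasing",
                                            call. = FALSE)
  if (y1 > y2) stop("'y1' must be <= 'y2'", call. = FALSE)
  if (y1 < min(y) || y2 > max(y)) stop("'y1','y2' must lie inside the grid",
                                       call. = FALSE)
  if (y1 == y2) return(0)
  pst <- pst / trapz(y, pst)
  if (any(pst[y >= y1 & y <= y2] <= 0))
    stop("'pst' must be positive on [y1, y2]", call. = FALSE)
  # cumulative inner integral from the reflecting end
  inner <- cumtrapz(y, pst)
  innf <- stats::approxfun(y, inner)
  pstf <- stats::approxfun(y, pst)
  integrand <- function(v) innf(v) / (D * pstf(v))
  ys <- seq(y1, y2, length.out = 2001L)
  trapz(ys, integrand(ys))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
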