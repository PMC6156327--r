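#' Stationary distribution of the stochastic model
#'
#' Estimates the stationary probability `Pst(x1, x2)` of the Langevin system,
#' either by Monte Carlo occupancy of an ensemble of long trajectories
#' (`method = "mc"`) or by solving the stationary Fokker-Planck equation with
#' a positivity-preserving finite-volume scheme and no-flux boundaries
#' (`method = "fpe"`).
#'
#' The Monte Carlo route pools every post-burn-in step of `n_chains`
#' independent chains started (by default) cycling over the deterministic
#' attractors, so that all basins are visited even when `D` is small.
#'
#' @inheritParams simulate.emt_model
#' @param model an [emt_model()].
#' @param D noise intensity `> 0` (for `"mc"`, `D = 0` is allowed but
#'   degenerate).
#' @param method `"mc"` or `"fpe"`.
#' @param xlim,ylim grid window; defaults to `[0, 1.5 (a+c)/k1] x
#'   [0, 1.5 b/k2]`.
#' @param bins number of bins per axis, length 1 or 2.
#' @param t_end,burn_in,dt,n_chains Monte Carlo ensemble settings.
#' @param starts optional matrix of chain initial states.
#' @return Object of class `"emt_distribution"`: bin-edge vectors `x_edges`,
#'   `y_edges`, centers `x`, `y`, matrix `mass` (sums to 1), `method`, `D`.
#' @export
stationary_distribution <- function(model, D, method = c("mc", "fpe"),
                                    xlim = NULL, ylim = NULL, bins = 200L,
                                    t_end = 5000, burn_in = 500, dt = 0.005,
                                    n_chains = 50L, starts = NULL,
                                    seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "emt_model"))
  if (length(bins) == 1L) bins <- rep(bins, 2)
  if (is.null(xlim)) xlim <- c(0, x1_upper(model))
  if (is.null(ylim)) ylim <- c(0, 1.5 * model$b / model$k2)
  if (xlim[2] <= 0 || ylim[2] <= 0)
    stop("degenerate default grid window; supply 'xlim'/'ylim'", call. = FALSE)
  if (method == "fpe") {
    if (D <= 0) stop("FPE solve requires D > 0", call. = FALSE)
    mass <- fpe_stationary(model, D, xlim, ylim, bins[1], bins[2])
  } else {
    if (burn_in >= t_end) stop("'burn_in' must be < 't_end'", call. = FALSE)
    if (dt <= 0 || dt > 0.01) stop("'dt' must be in (0, 0.01]", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(starts)) {
      att <- stable_attractors(model)
      starts <- att[rep_len(seq_len(nrow(att)), n_chains), , drop = FALSE]
    }
    counts <- sim_hist_cpp(par_vec(model), as.matrix(starts), dt,
                           round(t_end / dt), round(burn_in / dt), D,
                           xlim[2], bins[1], ylim[2], bins[2])
    if (sum(counts) == 0) stop("no post-burn-in samples", call. = FALSE)
    mass <- counts / sum(counts)
  }
  xe <- seq(xlim[1], xlim[2], length.out = bins[1] + 1)
  ye <- seq(ylim[1], ylim[2], length.out = bins[2] + 1)
  structure(list(x_edges = xe, y_edges = ye,
                 x = (xe[-1] + xe[-length(xe)]) / 2,
                 y = (ye[-1] + ye[-length(ye)]) / 2,
                 mass = mass, method = method, D = D, model = model),
            class = "emt_distribution")
}

# Bernoulli function B(w) = w / (exp(w) - 1), stable for all w
bernoulli_fn <- function(w) {
  out <- numeric(length(w))
  small <- abs(w) < 1e-8
  out[small] <- 1 - w[small] / 2
  ws <- w[!small]
  out[!small] <- ws / expm1(ws)
  out
}

# Stationary FPE solve: finite-volume with Scharfetter-Gummel (exponential
# fitting) face fluxes and zero-flux boundaries. The discrete generator A is
# conservative by construction (column sums 0); the stationary density is its
# kernel, obtained by replacing one row with the normalization constraint.
fpe_stationary <- function(model, D, xlim, ylim, nx, ny) {
  dx <- diff(xlim) / nx; dy <- diff(ylim) / ny
  xc <- xlim[1] + (seq_len(nx) - 0.5) * dx
  yc <- ylim[1] + (seq_len(ny) - 0.5) * dy
  id <- function(i, j) i + (j - 1L) * nx
  N <- nx * ny
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  # vertical (x-direction) interior faces
  xf <- xlim[1] + seq_len(nx - 1) * dx
  fc <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny))
  # face flux J = (D/h) [B(-w) p_left - B(w) p_right], w = v h / D, so that
  # w -> +Inf gives the upwind value v p_left and w = 0 plain diffusion
  v <- drift(model, cbind(xf[fc$i], yc[fc$j]))[, "f1"]
  w <- v * dx / D
  Bp <- bernoulli_fn(w); Bm <- Bp + w  # B(-w) = B(w) + w
  L <- id(fc$i, fc$j); R <- id(fc$i + 1L, fc$j)
  cf <- D / dx^2
  add(L, L, -cf * Bm); add(L, R, cf * Bp)
  add(R, L, cf * Bm);  add(R, R, -cf * Bp)
  # horizontal (y-direction) interior faces
  yf <- ylim[1] + seq_len(ny - 1) * dy
  fc <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1))
  v <- drift(model, cbind(xc[fc$i], yf[fc$j]))[, "f2"]
  w <- v * dy / D
  Bp <- bernoulli_fn(w); Bm <- Bp + w
  Bo <- id(fc$i, fc$j); To <- id(fc$i, fc$j + 1L)
  cf <- D / dy^2
  add(Bo, Bo, -cf * Bm); add(Bo, To, cf * Bp)
  add(To, Bo, cf * Bm);  add(To, To, -cf * Bp)

  # replace the first equation by total-mass normalization
  keep <- ii != 1L
  A <- Matrix::sparseMatrix(
    i = c(ii[keep], rep(1L, N)),
    j = c(jj[keep], seq_len(N)),
    x = c(xx[keep], rep(dx * dy, N)),
    dims = c(N, N))
  rhs <- c(1, rep(0, N - 1))
  p <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e)
                  stop("stationary FPE solve failed: ",
                       conditionMessage(e), call. = FALSE))
  neg <- sum(p[p < 0])
  if (abs(neg) > 1e-8)
    warning("FPE solution had negative mass ", signif(neg, 3),
            "; clipped and renormalized")
  p[p < 0] <- 0
  mass <- matrix(p * dx * dy, nx, ny)
  mass / sum(mass)
}

#' @export
print.emt_distribution <- function(x, ...) {
  cat(sprintf("Stationary distribution (%s), D = %g, %d x %d bins\n",
              x$method, x$D, length(x$x), length(x$y)))
  md <- find_modes(x)
  if (nrow(md)) {
    cat("Modes:\n"); print(round(md, 4))
  }
  invisible(x)
}

#' @export
plot.emt_distribution <- function(x, ...) {
  graphics::image(x$x, x$y, x$mass, col = grDevices::hcl.colors(64, "YlOrRd",
                                                                rev = TRUE),
                  xlab = "x1 (ZEB)", ylab = "x2 (miR-200)", ...)
  invisible(x)
}

# 3x3 box smoothing (edge-padded), used to stabilize mode finding on MC
# histograms
smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[di + seq_len(nr), dj + seq_len(nc)]
  out / 9
}

#' Local modes of a stationary distribution
#'
#' Finds local maxima of the (optionally smoothed) bin-mass surface over an
#' 8-neighbourhood, keeping peaks above `rel_height` times the global maximum.
#'
#' @param dist an `"emt_distribution"`.
#' @param rel_height minimum peak height relative to the highest peak.
#' @param smooth apply a 3x3 box filter first (recommended for MC histograms).
#' @return Data frame with columns `x1`, `x2`, `mass`.
#' @export
find_modes <- function(dist, rel_height = 0.01, smooth = dist$method == "mc") {
  m <- if (smooth) smooth3(dist$mass) else dist$mass
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[1 + seq_len(nr), 1 + seq_len(nc)] <- m
  ismax <- matrix(TRUE, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    ismax <- ismax & m >= pad[di + seq_len(nr), dj + seq_len(nc)]
  }
  # strict on at least one side to drop flat zero plateaus
  ismax <- ismax & m > rel_height * max(m)
  idx <- which(ismax, arr.ind = TRUE)
  out <- data.frame(x1 = dist$x[idx[, 1]], x2 = dist$y[idx[, 2]],
                    mass = dist$mass[idx])
  out[order(-out$mass), , drop = FALSE]
}

#' Total-variation distance between two distributions on matched grids
#'
#' @param d1,d2 `"emt_distribution"` objects on identical grids.
#' @param block aggregate `block x block` bins before comparing (reduces
#'   Monte Carlo noise).
#' @return A number in `[0, 1]`.
#' @export
tv_distance <- function(d1, d2, block = 1L) {
  if (!isTRUE(all.equal(d1$x_edges, d2$x_edges)) ||
      !isTRUE(all.equal(d1$y_edges, d2$y_edges)))
    stop("distributions are not on matched grids", call. = FALSE)
  m1 <- d1$mass; m2 <- d2$mass
  if (block > 1L) {
    agg <- function(m) {
      nr <- nrow(m) %/% block * block
      nc <- ncol(m) %/% block * block
      m <- m[seq_len(nr), seq_len(nc)]
      g1 <- (seq_len(nr) - 1L) %/% block
      g2 <- (seq_len(nc) - 1L) %/% block
      rowsum(t(rowsum(m, g1)), g2)
    }
    m1 <- agg(m1); m2 <- agg(m2)
  }
  sum(abs(m1 / sum(m1) - m2 / sum(m2))) / 2
}

#' Potential landscape
#'
#' The quasi-potential `U = -ln(Pst)`, clipped below a probability floor so
#' that empty bins stay finite. Minima of `U` are the attractors.
#'
#' @param dist an `"emt_distribution"`.
#' @param floor probability floor; default is (smallest positive mass)/10.
#' @return Object of class `"emt_landscape"` with matrix `U` on the same grid.
#' @export
potential <- function(dist, floor = NULL) {
  stopifnot(inherits(dist, "emt_distribution"))
  if (!all(is.finite(dist$mass)))
    stop("distribution mass contains non-finite values", call. = FALSE)
  pos <- dist$mass[dist$mass > 0]
  if (!length(pos)) stop("all-zero distribution", call. = FALSE)
  if (is.null(floor)) floor <- min(pos) / 10
  U <- -log(pmax(dist$mass, floor))
  structure(list(x = dist$x, y = dist$y, U = U, floor = floor,
                 D = dist$D, method = dist$method, model = dist$model),
            class = "emt_landscape")
}

#' @export
print.emt_landscape <- function(x, ...) {
  cat(sprintf("Potential landscape U = -ln(Pst) (%s, D = %g), %d x %d bins\n",
              x$method, x$D, length(x$x), length(x$y)))
  invisible(x)
}

#' @export
plot.emt_landscape <- function(x, ...) {
  graphics::filled.contour(x$x, x$y, x$U,
                           color.palette = function(n)
                             grDevices::hcl.colors(n, "viridis"),
                           xlab = "x1 (ZEB)", ylab = "x2 (miR-200)", ...)
  invisible(x)
}
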