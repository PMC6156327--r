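PHENOTYPES <- c("E", "HYBRID", "M")

#' Phenotype label of a stable state
#'
#' Epithelial (E) when ZEB is repressed (`x1 < theta`), mesenchymal (M) when
#' miR-200 is repressed (`x2 < theta`), hybrid otherwise (both intermediate,
#' the (1/2, 1/2)-type state).
#'
#' @inheritParams drift
#' @param x1,x2 coordinates of a stable fixed point (vectorized).
#' @return Character vector of labels `"E"`, `"HYBRID"`, `"M"`.
#' @export
label_phenotype <- function(model, x1, x2) {
  ifelse(x1 < model$theta, "E", ifelse(x2 < model$theta, "M", "HYBRID"))
}

# eigenvalues + stability label from vectorized Jacobian entries.
# For this circuit j12*j21 >= 0, so the discriminant is non-negative and the
# eigenvalues are real; the complex branch is kept as a guard.
stability_at <- function(model, x1, x2, eps_eig = 1e-8) {
  J <- jacobian_entries(model, x1, x2)
  tr <- J$j11 + J$j22
  dt <- J$j11 * J$j22 - J$j12 * J$j21
  disc <- tr^2 - 4 * dt
  sq <- sqrt(pmax(disc, 0))
  l1 <- (tr + sq) / 2
  l2 <- (tr - sq) / 2
  re1 <- ifelse(disc >= 0, l1, tr / 2)
  re2 <- ifelse(disc >= 0, l2, tr / 2)
  marginal <- pmin(abs(re1), abs(re2)) < eps_eig
  lab <- ifelse(pmax(re1, re2) < -eps_eig, "stable",
         ifelse(re1 > eps_eig & re2 > eps_eig, "unstable", "saddle"))
  list(lambda1 = complex(real = re1,
                         imaginary = ifelse(disc >= 0, 0, sqrt(-pmin(disc, 0)) / 2)),
       lambda2 = complex(real = re2,
                         imaginary = ifelse(disc >= 0, 0, -sqrt(-pmin(disc, 0)) / 2)),
       stability = lab, marginal = marginal)
}

#' Linear stability of a fixed point
#'
#' Classifies a (polished) fixed point by the real parts of the Jacobian
#' eigenvalues: stable if both `< -eps_eig`, saddle if they straddle zero,
#' unstable otherwise.
#'
#' @inheritParams drift
#' @param state fixed-point location `c(x1, x2)`.
#' @param eps_eig tolerance on eigenvalue real parts.
#' @param marginal what to do when an eigenvalue is within `eps_eig` of zero:
#'   `"error"` (default) or `"label"` (return `"marginal"`).
#' @return One of `"stable"`, `"saddle"`, `"unstable"`, `"marginal"`.
#' @export
classify_stability <- function(model, state, eps_eig = 1e-8,
                               marginal = c("error", "label")) {
  marginal <- match.arg(marginal)
  s <- as_state(state)
  st <- stability_at(model, s[, 1], s[, 2], eps_eig)
  if (st$marginal) {
    if (marginal == "error")
      stop("eigenvalue within ", eps_eig, " of zero: near-bifurcation point",
           call. = FALSE)
    return("marginal")
  }
  st$stability
}

# Core root scan: for equal-length parameter vectors (a, b) sharing all other
# model constants, locate every root of the scalar steady-state residual on
# (0, 1.5 (a+c)/k1] by dense sign-change bracketing, polish by bisection +
# Newton, lift to 2-D and classify. Vectorized across parameter points and
# across brackets, so a 250-point sweep costs little more than one point.
# Returns a data.frame: point (index into a/b), x1, x2, re1, re2, im,
# stability, marginal, phenotype, residual.
scan_states <- function(model, a, b, n_grid = 2001L, dedup_tol = 1e-6,
                        newton_iter = 6L, bisect_iter = 60L) {
  stopifnot(length(a) == length(b))
  k <- length(a)
  th <- model$theta; c0 <- model$c; k1 <- model$k1; k2 <- model$k2
  xmax <- 1.5 * (max(a) + c0) / k1
  if (xmax <= 0) xmax <- 1e-6  # degenerate a = c = 0: only root is x1 = 0
  xs <- seq(0, xmax, length.out = n_grid)
  g_at <- function(x, aa, bb) {
    x2 <- bb * hill_down(x, model$n3, th) / k2
    aa * hill_up(x, model$n1, th) + c0 * hill_down(x2, model$n2, th) - k1 * x
  }
  h1 <- hill_up(xs, model$n1, th)
  r3 <- hill_down(xs, model$n3, th)
  X2 <- outer(r3, b) / k2
  G <- outer(h1, a) + c0 * hill_down(X2, model$n2, th) - k1 * xs

  # per-column sign-change brackets; a column with an even sign-change count
  # (g(0) >= 0 > g(xmax) forces an odd count) is rescanned at 10x resolution
  collect_brackets <- function(G, xs) {
    P <- G[-nrow(G), , drop = FALSE] * G[-1, , drop = FALSE]
    hit <- P < 0 | (G[-1, , drop = FALSE] == 0 & G[-nrow(G), , drop = FALSE] != 0)
    idx <- which(hit, arr.ind = TRUE)
    list(lo = xs[idx[, 1]], hi = xs[idx[, 1] + 1], col = idx[, 2],
         glo = G[cbind(idx[, 1], idx[, 2])])
  }
  br <- collect_brackets(G, xs)
  counts <- tabulate(br$col, nbins = k)
  bad <- which(counts %% 2L == 0L & G[1, ] > 0)
  if (length(bad)) {
    xs2 <- seq(0, xmax, length.out = 10L * n_grid)
    h1f <- hill_up(xs2, model$n1, th)
    r3f <- hill_down(xs2, model$n3, th)
    X2f <- outer(r3f, b[bad]) / k2
    Gf <- outer(h1f, a[bad]) + c0 * hill_down(X2f, model$n2, th) - k1 * xs2
    brf <- collect_brackets(Gf, xs2)
    keep <- !(br$col %in% bad)
    br <- list(lo = c(br$lo[keep], brf$lo),
               hi = c(br$hi[keep], brf$hi),
               col = c(br$col[keep], bad[brf$col]),
               glo = c(br$glo[keep], brf$glo))
  }

  roots <- numeric(0); rcol <- integer(0)
  if (length(br$lo)) {
    lo <- br$lo; hi <- br$hi; aa <- a[br$col]; bb <- b[br$col]; glo <- br$glo
    for (it in seq_len(bisect_iter)) {
      mid <- (lo + hi) / 2
      gm <- g_at(mid, aa, bb)
      same <- gm * glo > 0
      lo[same] <- mid[same]
      hi[!same] <- mid[!same]
    }
    x <- (lo + hi) / 2
    for (it in seq_len(newton_iter)) {
      gx <- g_at(x, aa, bb)
      dg <- steady_residual_deriv_vec(model, x, aa, bb)
      step <- gx / dg
      step[!is.finite(step)] <- 0
      xn <- pmin(pmax(x - step, lo), hi)
      x <- xn
    }
    roots <- x; rcol <- br$col
  }
  # exact roots sitting on the left edge (g(0) = 0, e.g. c = 0)
  zero_edge <- which(G[1, ] == 0)
  if (length(zero_edge)) {
    roots <- c(roots, rep(0, length(zero_edge)))
    rcol <- c(rcol, zero_edge)
  }
  if (!length(roots))
    return(data.frame(point = integer(0), x1 = numeric(0), x2 = numeric(0),
                      re1 = numeric(0), re2 = numeric(0), im = numeric(0),
                      stability = character(0), marginal = logical(0),
                      phenotype = character(0), residual = numeric(0)))
  ord <- order(rcol, roots)
  roots <- roots[ord]; rcol <- rcol[ord]
  # merge duplicates closer than dedup_tol within a parameter point
  keep <- c(TRUE, diff(rcol) != 0 | diff(roots) > dedup_tol)
  roots <- roots[keep]; rcol <- rcol[keep]

  x2r <- b[rcol] * hill_down(roots, model$n3, th) / k2
  st <- stability_at(model, roots, x2r)
  # stability labels use entries evaluated with per-point (a, b)
  res <- g_at(roots, a[rcol], b[rcol])
  data.frame(point = rcol, x1 = roots, x2 = x2r,
             re1 = Re(st$lambda1), re2 = Re(st$lambda2),
             im = abs(Im(st$lambda1)),
             stability = st$stability, marginal = st$marginal,
             phenotype = ifelse(st$stability == "stable",
                                label_phenotype(model, roots, x2r), NA),
             residual = res)
}

# vectorized g' with per-root (a, b)
steady_residual_deriv_vec <- function(model, x, aa, bb) {
  th <- model$theta
  x2 <- bb * hill_down(x, model$n3, th) / model$k2
  dx2 <- -bb * dhill_up(x, model$n3, th) / model$k2
  aa * dhill_up(x, model$n1, th) -
    model$c * dhill_up(x2, model$n2, th) * dx2 - model$k1
}

# N.B. stability_at above uses model$a/model$b through jacobian_entries; for
# scans with varying (a, b) the entries must come from the per-point values.
# scan_states therefore temporarily rebinds them:
scan_states_body <- scan_states
scan_states <- function(model, a, b, ...) {
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) {
    m <- model; m$a <- a[1]; m$b <- b[1]
    return(scan_states_body(m, a, b, ...))
  }
  out <- scan_states_body(model, a, b, ...)
  if (nrow(out)) {
    # reclassify with the correct per-point Jacobian (only j11/j21 depend on a, b)
    m <- model
    th <- model$theta
    j11 <- a[out$point] * dhill_up(out$x1, m$n1, th) - m$k1
    j12 <- -m$c * dhill_up(out$x2, m$n2, th)
    j21 <- -b[out$point] * dhill_up(out$x1, m$n3, th)
    j22 <- -m$k2
    tr <- j11 + j22; dt <- j11 * j22 - j12 * j21
    sq <- sqrt(pmax(tr^2 - 4 * dt, 0))
    re1 <- (tr + sq) / 2; re2 <- (tr - sq) / 2
    eps <- 1e-8
    out$re1 <- re1; out$re2 <- re2
    out$marginal <- pmin(abs(re1), abs(re2)) < eps
    out$stability <- ifelse(pmax(re1, re2) < -eps, "stable",
                     ifelse(re1 > eps & re2 > eps, "unstable", "saddle"))
    out$phenotype <- ifelse(out$stability == "stable",
                            label_phenotype(m, out$x1, out$x2), NA)
  }
  out
}

#' Fixed points of the model
#'
#' Finds all fixed points by dense sign-change bracketing of the scalar
#' steady-state reduction over `(0, 1.5 (a+c)/k1]` (default `1e5` grid points)
#' followed by bisection and Newton polish, lifts each root to 2-D via the
#' miR-200 nullcline, and classifies it by the analytic Jacobian.
#'
#' @inheritParams drift
#' @param n_grid number of bracketing grid points.
#' @param residual_tol maximum admissible `|g|` after polishing.
#' @return A data frame of class `"emt_fixed_points"` with columns `x1`, `x2`,
#'   `re1`, `re2` (eigenvalue real parts), `stability`, `phenotype` (for
#'   stable points), `residual`.
#' @examples
#' fixed_points(emt_model(a = 1.1, b = 8))
#' @export
fixed_points <- function(model, n_grid = 1e5L, residual_tol = 1e-9) {
  stopifnot(inherits(model, "emt_model"))
  out <- scan_states(model, model$a, model$b, n_grid = as.integer(n_grid))
  if (any(abs(out$residual) > residual_tol))
    stop("root polishing failed to reach residual ", residual_tol,
         " near x1 = ", out$x1[which.max(abs(out$residual))], call. = FALSE)
  out$point <- NULL
  attr(out, "model") <- model
  class(out) <- c("emt_fixed_points", "data.frame")
  out
}

#' @export
print.emt_fixed_points <- function(x, ...) {
  cols <- c("x1", "x2", "re1", "re2", "stability", "phenotype")
  if (!all(cols %in% names(x))) return(print.data.frame(x, ...))
  cat("Fixed points (", sum(x$stability == "stable"), " stable of ",
      nrow(x), "):\n", sep = "")
  print.data.frame(cbind(round(x[, c("x1", "x2", "re1", "re2")], 6),
                         x[, c("stability", "phenotype")]), ...)
  invisible(x)
}

# multiset of phenotypes of all stable fixed points, as a canonical string
# ("E", "E,M", "E,HYBRID,M", ...); "boundary" if any root is marginal
regime_of <- function(stability, phenotype, marginal) {
  if (any(marginal)) return("boundary")
  ph <- phenotype[stability == "stable"]
  if (!length(ph)) return("none")
  paste(PHENOTYPES[sort(match(ph, PHENOTYPES))], collapse = ",")
}

#' Regime (multiset of stable phenotypes) at a parameter point
#'
#' @inheritParams fixed_points
#' @return A string such as `"E"`, `"E,M"`, `"E,HYBRID,M"`.
#' @export
regime <- function(model, n_grid = 1e5L) {
  fp <- fixed_points(model, n_grid = n_grid)
  regime_of(fp$stability, fp$phenotype, fp$marginal)
}

#' @export
summary.emt_model <- function(object, ...) {
  fp <- fixed_points(object)
  out <- list(model = object, fixed_points = fp,
              regime = regime_of(fp$stability, fp$phenotype, fp$marginal))
  class(out) <- "summary.emt_model"
  out
}

#' @export
print.summary.emt_model <- function(x, ...) {
  print(x$model)
  cat("Regime:", x$regime, "\n")
  print(x$fixed_points)
  invisible(x)
}

#' Nullclines of the vector field
#'
#' The miR-200 nullcline is the explicit graph [mirna_nullcline()]; the ZEB
#' nullcline is extracted as the zero contour of `F1` on a grid.
#'
#' @inheritParams drift
#' @param n grid resolution per axis.
#' @param xlim,ylim plot window; defaults to the invariant box.
#' @return List of class `"emt_nullclines"` with elements `zeb` (list of
#'   polyline data frames) and `mirna` (one data frame).
#' @export
nullclines <- function(model, n = 400L, xlim = NULL, ylim = NULL) {
  if (is.null(xlim)) xlim <- c(0, x1_upper(model))
  if (is.null(ylim)) ylim <- c(0, max(1.5 * model$b / model$k2, 1))
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  F1 <- outer(xs, ys, function(x, y) drift(model, cbind(x, y))[, "f1"])
  cl <- grDevices::contourLines(xs, ys, F1, levels = 0)
  zeb <- lapply(cl, function(p) data.frame(x1 = p$x, x2 = p$y))
  mir <- data.frame(x1 = xs, x2 = mirna_nullcline(model, xs))
  structure(list(zeb = zeb, mirna = mir, xlim = xlim, ylim = ylim,
                 model = model),
            class = "emt_nullclines")
}

#' Phase-plane plot of the model
#'
#' Draws the nullclines and marks stable (filled) and unstable/saddle (open)
#' fixed points in the `(x1, x2)` plane.
#'
#' @param x an [emt_model()].
#' @param ... passed to [plot()].
#' @export
plot.emt_model <- function(x, ...) {
  nc <- nullclines(x)
  fp <- fixed_points(x)
  plot(NA, xlim = nc$xlim, ylim = nc$ylim,
       xlab = "x1 (ZEB)", ylab = "x2 (miR-200)", ...)
  for (p in nc$zeb) graphics::lines(p$x1, p$x2, col = "steelblue")
  graphics::lines(nc$mirna$x1, nc$mirna$x2, col = "seagreen")
  st <- fp$stability == "stable"
  graphics::points(fp$x1[!st], fp$x2[!st], pch = 1, col = "red")
  graphics::points(fp$x1[st], fp$x2[st], pch = 19, col = "red")
  if (any(st))
    graphics::text(fp$x1[st], fp$x2[st], fp$phenotype[st], pos = 4, col = "red")
  invisible(x)
}
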