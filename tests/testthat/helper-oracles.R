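# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the 2-D oracle works on the full vector field
# without the scalar reduction, and the reference steppers are plain R loops.

# Fixed points by dense 2-D sign analysis: candidate cells are those whose
# corners carry both signs of F1 AND both signs of F2 (both nullclines cross
# the cell); adjacent candidate cells are clustered, and each cluster is
# polished by a full 2-D Newton iteration on the vector field with a
# finite-difference Jacobian (independent of the package's scalar reduction
# and analytic derivatives). Clusters where the two nullclines merely pass
# close without crossing fail to converge locally and are dropped.
oracle_fixed_points_2d <- function(model, n = 400) {
  xmax <- 1.5 * (model$a + model$c) / model$k1
  ymax <- max(1.5 * model$b / model$k2, 1e-3)
  xs <- seq(0, xmax, length.out = n)
  ys <- seq(0, ymax, length.out = n)
  g <- expand.grid(x = xs, y = ys)
  F <- drift(model, cbind(g$x, g$y))
  F1 <- matrix(F[, 1], n, n)
  F2 <- matrix(F[, 2], n, n)
  corner_mix <- function(M) {
    s <- M >= 0
    a <- s[-n, -n]; b <- s[-1, -n]; c <- s[-n, -1]; d <- s[-1, -1]
    tot <- a + b + c + d
    tot > 0 & tot < 4
  }
  cand <- corner_mix(F1) & corner_mix(F2)
  if (!any(cand)) return(cbind(x1 = numeric(0), x2 = numeric(0)))
  idx <- which(cand, arr.ind = TRUE)
  hx <- diff(xs[1:2]); hy <- diff(ys[1:2])
  roots <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(idx))) {
    p <- c(xs[idx[k, 1]] + hx / 2, ys[idx[k, 2]] + hy / 2)
    ok <- FALSE
    for (it in 1:50) {
      f <- as.numeric(drift(model, rbind(pmax(p, 0))))
      if (max(abs(f)) < 1e-10) { ok <- TRUE; break }
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        e <- c(0, 0); e[j] <- 1e-7
        lo <- pmax(p - e, 0)
        J[, j] <- (drift(model, rbind(pmax(p + e, 0))) -
                     drift(model, rbind(lo))) / (p[j] + e[j] - lo[j])
      }
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      p <- pmax(p - step, 0)
    }
    if (ok) roots <- rbind(roots, pmax(p, 0))
  }
  if (!nrow(roots)) return(cbind(x1 = numeric(0), x2 = numeric(0)))
  # merge duplicates below grid resolution
  keep <- rep(TRUE, nrow(roots))
  for (i in seq_len(nrow(roots) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(roots)) {
      if (abs(roots[i, 1] - roots[j, 1]) < 2 * hx &&
          abs(roots[i, 2] - roots[j, 2]) < 2 * hy) keep[j] <- FALSE
    }
  }
  roots <- roots[keep, , drop = FALSE]
  colnames(roots) <- c("x1", "x2")
  roots
}

# 8-connected components of a logical matrix (small helper for the oracle)
oracle_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      cell <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[cell] > 0L) next
      lab[cell] <- cur
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- i + di; nj <- j + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        nb <- ni + (nj - 1L) * nr
        if (mask[nb] && lab[nb] == 0L) stack <- c(stack, nb)
      }
    }
  }
  lab
}

# Plain-R Euler(-Maruyama) reference, mirroring the C++ update order exactly
# (z1 then z2 per step, reflection after the full update). The delayed term
# reads an explicitly stored complete series instead of a ring buffer.
# Integer powers use the same square-and-multiply order as the compiled
# stepper so deterministic runs agree bit for bit.
pw <- function(x, n) {
  r <- 1
  while (n > 0) {
    if (n %% 2 == 1) r <- r * x
    x <- x * x
    n <- n %/% 2
  }
  r
}

reference_stepper <- function(model, x0, dt, nsteps, D = 0, tau_steps = 0L,
                              thin = 1L) {
  x1 <- numeric(nsteps + 1); x2 <- numeric(nsteps + 1)
  x1[1] <- x0[1]; x2[1] <- x0[2]
  s <- if (D > 0) sqrt(2 * D * dt) else 0
  th1 <- pw(model$theta, model$n1)
  th2 <- pw(model$theta, model$n2)
  th3 <- pw(model$theta, model$n3)
  for (k in seq_len(nsteps)) {
    x1act <- if (tau_steps > 0 && k - tau_steps >= 1) x1[k - tau_steps]
             else if (tau_steps > 0) x1[1] else x1[k]
    h1 <- pw(x1act, model$n1)
    h2 <- pw(x2[k], model$n2)
    h3 <- pw(x1[k], model$n3)
    f1 <- model$a * h1 / (th1 + h1) + model$c * th2 / (th2 + h2) -
      model$k1 * x1[k]
    f2 <- model$b * th3 / (th3 + h3) - model$k2 * x2[k]
    z1 <- 0; z2 <- 0
    if (D > 0) { z1 <- rnorm(1); z2 <- rnorm(1) }
    x1[k + 1] <- abs(x1[k] + f1 * dt + s * z1)
    x2[k + 1] <- abs(x2[k] + f2 * dt + s * z2)
  }
  keep <- seq(1, nsteps + 1, by = thin)
  cbind(x1 = x1[keep], x2 = x2[keep])
}

# deSolve wrapper: adaptive-step integration of the deterministic field
ode_endpoint <- function(model, x0, t_end) {
  f <- function(t, y, p) list(as.numeric(drift(model, rbind(y))))
  out <- deSolve::ode(y = c(x1 = x0[1], x2 = x0[2]),
                      times = c(0, t_end), func = f, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  out[nrow(out), c("x1", "x2")]
}

expect_close <- function(x, y, tol) testthat::expect_lt(max(abs(x - y)), tol)
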