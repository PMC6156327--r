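#' Phase diagram in the (a, b) signal plane
#'
#' Computes the regime (multiset of stable phenotypes) on a rectangular grid
#' of the ZEB-activation strength `a` and miR-200-inhibition strength `b`.
#' Cells where an eigenvalue is within tolerance of zero are labelled
#' `"boundary"` and excluded from connected-region counting.
#'
#' @param a,b strictly increasing grid vectors. Defaults cover the window
#'   `a` in `[0, 2.5]`, `b` in `[0, 45]` at 250 x 250.
#' @param ... further model parameters passed to [emt_model()] (`c`, `k1`,
#'   `k2`, `n1`, `n2`, `n3`, `theta`).
#' @param n_grid bracketing resolution of the per-cell root scan.
#' @return Object of class `"emt_phase_diagram"`: list with `a`, `b`, `regime`
#'   (character matrix, rows indexed by `a`), `n_stable`, and `states` (long
#'   data frame of all roots per cell).
#' @examples
#' pd <- phase_diagram(a = seq(0, 2.5, length.out = 40),
#'                     b = seq(0, 45, length.out = 40))
#' table(pd$regime)
#' @export
phase_diagram <- function(a = seq(0, 2.5, length.out = 250),
                          b = seq(0, 45, length.out = 250),
                          ..., n_grid = 2001L) {
  if (is.unsorted(a, strictly = TRUE) || is.unsorted(b, strictly = TRUE))
    stop("'a' and 'b' grids must be strictly increasing", call. = FALSE)
  model <- emt_model(a = a[1], b = b[1], ...)
  na <- length(a); nb <- length(b)
  reg <- matrix(NA_character_, na, nb)
  nst <- matrix(NA_integer_, na, nb)
  states <- vector("list", nb)
  for (j in seq_len(nb)) {
    sc <- scan_states(model, a, rep(b[j], na), n_grid = n_grid)
    sp <- split(sc, factor(sc$point, levels = seq_len(na)))
    reg[, j] <- vapply(sp, function(d)
      regime_of(d$stability, d$phenotype, d$marginal), character(1))
    nst[, j] <- vapply(sp, function(d) sum(d$stability == "stable"), integer(1))
    if (nrow(sc)) {
      sc$a <- a[sc$point]; sc$b <- b[j]
      sc$ia <- sc$point; sc$ib <- j
      states[[j]] <- sc[, c("ia", "ib", "a", "b", "x1", "x2",
                            "stability", "phenotype")]
    }
  }
  structure(list(a = a, b = b, regime = reg, n_stable = nst,
                 states = do.call(rbind, states), model = model),
            class = "emt_phase_diagram")
}

# 4-neighbour connected components of a logical matrix; 0 outside the mask
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  seen <- !mask
  cur <- 0L
  for (s in which(mask)) {
    if (seen[s]) next
    cur <- cur + 1L
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      lab[frontier] <- cur
      r <- (frontier - 1L) %% nr + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier - nr, frontier + nr)
      nb <- nb[nb >= 1L & nb <= nr * nc]
      nb <- nb[!seen[nb]]
      nb <- unique(nb)
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  lab
}

#' Connected regions of a phase diagram
#'
#' Counts 4-neighbour connected components per regime value; `"boundary"`
#' cells are excluded.
#'
#' @param pd an [phase_diagram()] result.
#' @return Data frame with columns `regime`, `n_regions`, `n_cells`.
#' @export
regime_regions <- function(pd) {
  stopifnot(inherits(pd, "emt_phase_diagram"))
  vals <- setdiff(sort(unique(as.vector(pd$regime))), c("boundary", "none"))
  out <- lapply(vals, function(v) {
    lab <- label_components(pd$regime == v)
    data.frame(regime = v, n_regions = max(lab), n_cells = sum(lab > 0))
  })
  do.call(rbind, out)
}

#' @export
print.emt_phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %d x %d cells, a in [%g, %g], b in [%g, %g]\n",
              length(x$a), length(x$b), min(x$a), max(x$a),
              min(x$b), max(x$b)))
  print(table(regime = as.vector(x$regime)))
  invisible(x)
}

#' @export
plot.emt_phase_diagram <- function(x, ...) {
  vals <- sort(unique(as.vector(x$regime)))
  z <- matrix(match(x$regime, vals), nrow(x$regime))
  cols <- grDevices::hcl.colors(length(vals), "Spectral")
  graphics::image(x$a, x$b, z, col = cols, xlab = "a (ZEB activation)",
                  ylab = "b (miR-200 inhibition)", ...)
  graphics::legend("topright", legend = vals, fill = cols, cex = 0.7,
                   bg = "white")
  invisible(x)
}

#' @export
as.data.frame.emt_phase_diagram <- function(x, ...) {
  grid <- expand.grid(ia = seq_along(x$a), ib = seq_along(x$b))
  out <- data.frame(a = x$a[grid$ia], b = x$b[grid$ib],
                    regime = as.vector(x$regime),
                    n_stable = as.vector(x$n_stable))
  # wide per-branch columns (up to the maximum root count over the grid)
  st <- x$states
  if (!is.null(st) && nrow(st)) {
    key <- paste(st$ia, st$ib)
    idx <- stats::ave(seq_len(nrow(st)), key, FUN = seq_along)
    kmax <- max(idx)
    gkey <- paste(grid$ia, grid$ib)
    for (k in seq_len(kmax)) {
      sk <- st[idx == k, ]
      m <- match(gkey, paste(sk$ia, sk$ib))
      out[[paste0("branch", k, "_x1")]] <- sk$x1[m]
      out[[paste0("branch", k, "_x2")]] <- sk$x2[m]
      out[[paste0("branch", k, "_stability")]] <- sk$stability[m]
      out[[paste0("branch", k, "_phenotype")]] <- sk$phenotype[m]
    }
  }
  out
}
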