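#' Attractor basins and barrier heights of a landscape
#'
#' Finds the local minima of `U` (8-neighbourhood) and, for every ordered pair
#' of minima `(A, B)`, the minimax saddle level `U(S)` — the lowest level at
#' which A and B become connected, computed by a sorted sweep with union-find
#' (the widest-path/minimax criterion on the grid graph). The barrier height
#' is `phi_SA = U(S) - U(A)`.
#'
#' When `attractors` (a matrix of reference locations, e.g. the deterministic
#' stable fixed points) is given, only the grid minimum nearest each reference
#' (within `match_radius`) is kept, which suppresses spurious shallow minima
#' of noisy Monte Carlo landscapes.
#'
#' @param landscape an [potential()] result.
#' @param attractors optional n-by-2 matrix of reference attractor locations;
#'   row names (phenotype labels) are carried through.
#' @param match_radius maximum distance between a reference attractor and its
#'   grid minimum.
#' @return Object of class `"emt_barriers"`: list with `minima` (data frame
#'   `x1`, `x2`, `U`, `label`) and `barriers` (data frame `from`, `to`,
#'   `saddle_U`, `phi` with `phi = U(S) - U(from)`).
#' @export
barrier_heights <- function(landscape, attractors = NULL, match_radius = 0.5) {
  stopifnot(inherits(landscape, "emt_landscape"))
  U <- landscape$U
  nr <- nrow(U); nc <- ncol(U)
  # strict local minima over the 8-neighbourhood
  pad <- matrix(Inf, nr + 2, nc + 2)
  pad[1 + seq_len(nr), 1 + seq_len(nc)] <- U
  ismin <- matrix(TRUE, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    ismin <- ismin & U < pad[di + seq_len(nr), dj + seq_len(nc)]
  }
  midx <- which(ismin)
  mi <- (midx - 1L) %% nr + 1L
  mj <- (midx - 1L) %/% nr + 1L
  minima <- data.frame(cell = midx, x1 = landscape$x[mi], x2 = landscape$y[mj],
                       U = U[midx], label = NA_character_)
  if (!is.null(attractors)) {
    attractors <- as.matrix(attractors)
    sel <- integer(0); lab <- character(0)
    for (r in seq_len(nrow(attractors))) {
      d <- sqrt((minima$x1 - attractors[r, 1])^2 +
                (minima$x2 - attractors[r, 2])^2)
      if (!length(d) || min(d) > match_radius) {
        warning("no grid minimum within ", match_radius, " of attractor ", r)
        next
      }
      sel <- c(sel, which.min(d))
      lab <- c(lab, if (!is.null(rownames(attractors)))
        rownames(attractors)[r] else as.character(r))
    }
    minima <- minima[sel, , drop = FALSE]
    minima$label <- lab
  } else if (nrow(minima)) {
    minima$label <- label_phenotype(landscape$model, minima$x1, minima$x2)
  }
  nmin <- nrow(minima)
  empty <- data.frame(from = character(0), to = character(0),
                      saddle_U = numeric(0), phi = numeric(0))
  if (nmin < 2)
    return(structure(list(minima = minima, barriers = empty,
                          landscape = landscape), class = "emt_barriers"))

  # sorted sweep: activate cells by increasing U, union with active
  # neighbours; the level at which two minima's components merge is the
  # minimax saddle between them.
  N <- nr * nc
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  minset <- vector("list", N)  # minima ids owned by each root
  for (k in seq_len(nmin)) minset[[minima$cell[k]]] <- k
  saddle <- matrix(NA_real_, nmin, nmin)
  active <- logical(N)
  ord <- order(as.vector(U))
  npair <- nmin * (nmin - 1) / 2
  found <- 0L
  for (cell in ord) {
    active[cell] <- TRUE
    i <- (cell - 1L) %% nr + 1L
    j <- (cell - 1L) %/% nr + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      nb <- ni + (nj - 1L) * nr
      if (!active[nb]) next
      r1 <- find(cell); r2 <- find(nb)
      if (r1 == r2) next
      s1 <- minset[[r1]]; s2 <- minset[[r2]]
      if (length(s1) && length(s2)) {
        for (m1 in s1) for (m2 in s2) {
          if (is.na(saddle[m1, m2])) {
            saddle[m1, m2] <- saddle[m2, m1] <- U[cell]
            found <- found + 1L
          }
        }
      }
      parent[r2] <- r1
      # as.integer: c(NULL, NULL) would otherwise delete the list element
      minset[[r1]] <- as.integer(c(s1, s2))
      minset[[r2]] <- integer(0)
    }
    if (found >= npair) break
  }
  pairs <- which(upper.tri(saddle), arr.ind = TRUE)
  bars <- data.frame(
    from = minima$label[c(pairs[, 1], pairs[, 2])],
    to = minima$label[c(pairs[, 2], pairs[, 1])],
    saddle_U = c(saddle[pairs], saddle[pairs]),
    phi = c(saddle[pairs] - minima$U[pairs[, 1]],
            saddle[pairs] - minima$U[pairs[, 2]]))
  structure(list(minima = minima[, c("x1", "x2", "U", "label")],
                 barriers = bars, landscape = landscape),
            class = "emt_barriers")
}

#' @export
print.emt_barriers <- function(x, ...) {
  cat("Landscape minima:\n")
  print(round_df(x$minima, 4))
  cat("Barrier heights phi_SA = U(saddle) - U(A):\n")
  print(round_df(x$barriers, 4))
  invisible(x)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits)
  d
}

#' Escape barrier of one attractor
#'
#' The smallest barrier separating the attractor labelled `label` from any
#' other minimum — the relevant height for noise-driven escape.
#'
#' @param barriers an [barrier_heights()] result.
#' @param label attractor label (e.g. `"HYBRID"`).
#' @return A number (or `NA` if the label is absent).
#' @export
escape_barrier <- function(barriers, label) {
  b <- barriers$barriers
  b <- b[b$from == label, , drop = FALSE]
  if (!nrow(b)) return(NA_real_)
  min(b$phi)
}

#' Barrier-height scan over noise intensity
#'
#' Recomputes the Fokker-Planck landscape at each noise intensity and reports
#' each attractor's escape barrier, plus the plateau onset of the hybrid
#' barrier: the smallest scanned `D` beyond which every successive decrement
#' falls below `rel_tol` times the largest decrement over the scan.
#'
#' @param model an [emt_model()].
#' @param D_values increasing vector of noise intensities.
#' @param bins FPE grid resolution per axis.
#' @param rel_tol plateau-detection tolerance (relative to the largest
#'   successive decrement).
#' @param labels attractor labels to track.
#' @param match_radius passed to [barrier_heights()]; the default is wider
#'   than there because shallow minima drift away from the deterministic
#'   attractor along their valley as the noise grows.
#' @return Object of class `"emt_barrier_scan"`: data frame `barriers`
#'   (columns `D` and one per label) and `plateau_onset` (named, per label).
#' @export
barrier_scan <- function(model, D_values, bins = 200L, rel_tol = 0.1,
                         labels = c("E", "HYBRID", "M"), match_radius = 1.0) {
  stopifnot(!is.unsorted(D_values, strictly = TRUE))
  att <- stable_attractors(model)
  rows <- lapply(D_values, function(D) {
    ds <- stationary_distribution(model, D, method = "fpe", bins = bins)
    bh <- suppressWarnings(
      barrier_heights(potential(ds), attractors = att,
                      match_radius = match_radius))
    vapply(labels, function(l) escape_barrier(bh, l), numeric(1))
  })
  tab <- data.frame(D = D_values, do.call(rbind, rows))
  onset <- vapply(labels, function(l) plateau_onset(D_values, tab[[l]],
                                                    rel_tol), numeric(1))
  structure(list(barriers = tab, plateau_onset = onset, rel_tol = rel_tol,
                 model = model),
            class = "emt_barrier_scan")
}

# smallest scanned D such that all subsequent successive decrements are below
# rel_tol * max decrement; NA if the curve never settles within the scan.
# A well that has vanished from the landscape (phi = NA) has stopped
# decreasing, so its undefined decrements count as zero.
plateau_onset <- function(D, phi, rel_tol = 0.1) {
  d <- -diff(phi)  # decrements (positive while decreasing)
  if (!length(d) || all(!is.finite(d))) return(NA_real_)
  d[!is.finite(d)] <- 0
  tol <- rel_tol * max(d, na.rm = TRUE)
  for (i in seq_along(d)) {
    if (all(d[i:length(d)] < tol)) return(D[i])
  }
  NA_real_
}

#' @export
print.emt_barrier_scan <- function(x, ...) {
  cat("Escape barriers vs noise intensity:\n")
  print(round_df(x$barriers, 4))
  cat("Plateau onset (rel_tol =", x$rel_tol, "):\n")
  print(x$plateau_onset)
  invisible(x)
}
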