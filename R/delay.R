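#' Classify the outcome of a trajectory
#'
#' Summarizes a (possibly delayed, possibly noisy) trajectory: the final
#' phenotype from the late-window mean state (mapped to the nearest stable
#' attractor when within `capture_radius`, else `"UNSETTLED"`), oscillation
#' flags from the `x1` amplitude, and the dwell-filtered sequence of visited
#' phenotypes.
#'
#' @param traj an `"emt_trajectory"` (from [simulate.emt_model()]).
#' @param model the model that produced it (defaults to the one stored in the
#'   trajectory).
#' @param window_fraction fraction of the trajectory forming the late window.
#' @param osc_tol amplitude (half peak-to-peak of `x1`) above which the
#'   oscillation flags are set.
#' @param dwell_min minimum dwell time (time units) for a phenotype to enter
#'   the visited sequence.
#' @param capture_radius radius for attractor membership.
#' @return Object of class `"emt_outcome"`: list with `final` (label),
#'   `oscillating` (sustained, late window), `transient_oscillation` (before
#'   the late window), `late_mean` (state), `late_amplitude`, `visited`
#'   (label sequence).
#' @export
classify_trajectory <- function(traj, model = attr(traj, "model"),
                                window_fraction = 0.2, osc_tol = 0.1,
                                dwell_min = 20, capture_radius = 0.15) {
  stopifnot(inherits(traj, "emt_trajectory"))
  n <- nrow(traj)
  nw <- max(2L, floor(window_fraction * n))
  if (n < 2L * nw)
    stop("trajectory shorter than twice the analysis window", call. = FALSE)
  late <- traj[(n - nw + 1L):n, ]
  att <- stable_attractors(model)
  late_mean <- c(x1 = mean(late$x1), x2 = mean(late$x2))
  d <- sqrt((att[, 1] - late_mean[1])^2 + (att[, 2] - late_mean[2])^2)
  final <- if (min(d) <= capture_radius) rownames(att)[which.min(d)]
           else "UNSETTLED"
  amp_late <- (max(late$x1) - min(late$x1)) / 2
  early <- traj[seq_len(n - nw), ]
  amp_early <- (max(early$x1) - min(early$x1)) / 2

  # dwell-filtered visited sequence: nearest-attractor label per sample
  D2 <- outer(traj$x1, att[, 1], "-")^2 + outer(traj$x2, att[, 2], "-")^2
  near <- max.col(-D2)
  inball <- D2[cbind(seq_len(n), near)] <= capture_radius^2
  lab <- ifelse(inball, rownames(att)[near], NA)
  r <- rle(lab)
  dt_samp <- traj$t[2] - traj$t[1]
  keep <- !is.na(r$values) & r$lengths * dt_samp >= dwell_min
  visited <- rle(r$values[keep])$values

  structure(list(final = final,
                 oscillating = amp_late > osc_tol,
                 transient_oscillation = amp_early > osc_tol,
                 late_mean = late_mean, late_amplitude = amp_late,
                 visited = visited),
            class = "emt_outcome")
}

#' @export
print.emt_outcome <- function(x, ...) {
  cat(sprintf("Outcome: %s (late mean x1 = %.3f, amplitude %.3f%s)\n",
              x$final, x$late_mean[1], x$late_amplitude,
              if (x$oscillating) ", oscillating" else ""))
  if (length(x$visited))
    cat("Visited:", paste(x$visited, collapse = " -> "), "\n")
  invisible(x)
}

#' Delay scan of trajectory outcomes
#'
#' For each delay in `tau_values`, runs `n_reps` seeded simulations from the
#' deterministic attractor of phenotype `start` and reports the distribution
#' of final labels and the majority label.
#'
#' @param model an [emt_model()].
#' @param D noise intensity `>= 0`.
#' @param start phenotype label of the starting attractor.
#' @param tau_values delays to scan (monotone ordering preserved in output).
#' @param n_reps replicates per delay (use `>= 20` when `D > 0`).
#' @param seed integer seed; replicate `r` of delay index `i` uses the
#'   derived stream `split_seed(seed, i, r)`.
#' @param t_end,dt simulation settings.
#' @param ... passed to [classify_trajectory()].
#' @return Object of class `"emt_tau_scan"`: data frame `summary` (per tau:
#'   majority label, mean late `x1`) and `reps` (per tau x rep: final label,
#'   oscillation, late mean `x1`, seed).
#' @export
tau_scan <- function(model, D, start, tau_values = c(0, 0.5, 1, 2, 5, 10, 20),
                     n_reps = if (D > 0) 20L else 1L, seed = 1L,
                     t_end = 200, dt = 0.005, ...) {
  att <- stable_attractors(model)
  if (!start %in% rownames(att))
    stop("no stable '", start, "' attractor at these parameters",
         call. = FALSE)
  x0 <- att[start, ]
  reps <- list()
  for (i in seq_along(tau_values)) {
    for (r in seq_len(n_reps)) {
      s <- split_seed(seed, i, r)
      tr <- simulate(model, seed = s, x0 = x0, t_end = t_end, dt = dt,
                     D = D, tau = tau_values[i], thin = 10L)
      oc <- classify_trajectory(tr, model, ...)
      reps[[length(reps) + 1L]] <- data.frame(
        tau = tau_values[i], rep = r, seed = s, final = oc$final,
        oscillating = oc$oscillating, late_mean_x1 = oc$late_mean[1])
    }
  }
  reps <- do.call(rbind, reps)
  rownames(reps) <- NULL
  summ <- do.call(rbind, lapply(split(reps, factor(reps$tau,
                                                   levels = tau_values)),
    function(d) {
      tb <- sort(table(d$final), decreasing = TRUE)
      data.frame(tau = d$tau[1], majority = names(tb)[1],
                 majority_frac = as.numeric(tb[1]) / nrow(d),
                 mean_late_x1 = mean(d$late_mean_x1))
    }))
  rownames(summ) <- NULL
  structure(list(summary = summ, reps = reps, model = model, D = D,
                 start = start, n_reps = n_reps),
            class = "emt_tau_scan")
}

#' @export
print.emt_tau_scan <- function(x, ...) {
  cat(sprintf("Delay scan from %s, D = %g, %d reps per tau\n",
              x$start, x$D, x$n_reps))
  print(round_df(x$summary, 4))
  invisible(x)
}

#' Majority-label transition sequence of a delay scan
#'
#' @param scan an [tau_scan()] result.
#' @return Majority labels with consecutive duplicates collapsed, in tau
#'   order.
#' @export
transition_sequence <- function(scan) {
  stopifnot(inherits(scan, "emt_tau_scan"))
  rle(scan$summary$majority)$values
}
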