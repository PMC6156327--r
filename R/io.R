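#' Derived random streams from one global seed
#'
#' Expands a single run seed into independent per-component seeds by a fixed
#' counter scheme, so adding a new analysis never perturbs existing streams.
#'
#' @param seed integer global seed.
#' @param ... integer counters identifying the component (any number).
#' @return An integer seed below `2^31`.
#' @export
split_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(x)
}

#' Write / read a model parameter configuration
#'
#' Flat plain-text `key = value` format with keys `a`, `b`, `c`, `k1`, `k2`,
#' `n1`, `n2`, `n3`, `theta`.
#'
#' @param model an [emt_model()].
#' @param path file path.
#' @return `read_model_config` returns an [emt_model()];
#'   `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  p <- coef(model)
  writeLines(sprintf("%s = %s", names(p),
                     vapply(p, format, character(1), digits = 17)),
             path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed config line: ", ln[lengths(kv) != 2][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  names(vals) <- keys
  do.call(emt_model, as.list(vals))
}

# fixed float formatting: full round-trip precision, plain notation
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Write an analysis artifact as CSV
#'
#' Deterministic output: stable column order, round-trip float formatting, LF
#' line endings. Methods exist for phase diagrams (one row per cell with
#' per-branch columns), bifurcation scans, trajectories, distributions and
#' landscapes (long format), and plain data frames.
#'
#' @param x the artifact.
#' @param path output file.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(x, path, ...) UseMethod("write_grid_csv")

write_csv_plain <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], fmt_num)
  con <- file(path, open = "wb")
  on.exit(close(con))
  # quote only the original character columns (regime strings contain commas)
  utils::write.csv(d, con, row.names = FALSE, quote = which(!num),
                   eol = "\n", na = "")
  invisible(path)
}

#' @export
write_grid_csv.data.frame <- function(x, path, ...) write_csv_plain(x, path)

#' @export
write_grid_csv.emt_phase_diagram <- function(x, path, ...)
  write_csv_plain(as.data.frame(x), path)

#' @export
write_grid_csv.emt_bifurcation <- function(x, path, ...) {
  d <- merge(x$points, x$branches, by = c("a", "b"), all.x = TRUE,
             sort = FALSE)
  d <- d[order(d$point, d$x1, na.last = TRUE), ]
  d$point <- NULL
  write_csv_plain(d, path)
}

#' @export
write_grid_csv.emt_trajectory <- function(x, path, ...)
  write_csv_plain(as.data.frame(x), path)

#' @export
write_grid_csv.emt_distribution <- function(x, path, ...) {
  d <- expand.grid(x1_bin_center = x$x, x2_bin_center = x$y)
  d$mass <- as.vector(x$mass)
  write_csv_plain(d, path)
}

#' @export
write_grid_csv.emt_landscape <- function(x, path, ...) {
  d <- expand.grid(x1_bin_center = x$x, x2_bin_center = x$y)
  d$U <- as.vector(x$U)
  write_csv_plain(d, path)
}

#' Write a JSON summary of an artifact
#'
#' Keys are sorted and numbers written at full precision, so identical runs
#' produce byte-identical files.
#'
#' @param x a summary-able object (list or any package artifact).
#' @param path output file.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path, ...) UseMethod("write_json_summary")

json_out <- function(lst, path) {
  txt <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

#' @export
write_json_summary.list <- function(x, path, ...) json_out(x, path)

#' @export
write_json_summary.emt_phase_diagram <- function(x, path, ...) {
  rr <- regime_regions(x)
  json_out(list(window = list(a = range(x$a), b = range(x$b)),
                grid = c(length(x$a), length(x$b)),
                regimes = as.list(stats::setNames(rr$n_cells, rr$regime)),
                regions = as.list(stats::setNames(rr$n_regions, rr$regime))),
           path)
}

#' @export
write_json_summary.emt_bifurcation <- function(x, path, ...) {
  json_out(list(alpha = x$pathway$alpha, beta = x$pathway$beta,
                a_from = x$pathway$a_from, a_to = x$pathway$a_to,
                n_points = nrow(x$points),
                regime_sequence = as.list(regime_sequence(x))), path)
}

#' @export
write_json_summary.emt_mfpt <- function(x, path, ...) {
  json_out(list(from = x$from, to = x$to, D = x$D, mean = x$mean, se = x$se,
                n = x$n, n_censored = x$n_censored,
                capture_radius = x$capture_radius, dt = x$dt,
                t_max = x$t_max), path)
}

#' @export
write_json_summary.emt_tau_scan <- function(x, path, ...) {
  json_out(list(start = x$start, D = x$D, n_reps = x$n_reps,
                tau = x$summary$tau,
                majority = as.list(x$summary$majority),
                transition_sequence = as.list(transition_sequence(x))), path)
}

#' @export
write_json_summary.emt_fixed_points <- function(x, path, ...) {
  json_out(list(n = nrow(x), n_stable = sum(x$stability == "stable"),
                fixed_points = lapply(seq_len(nrow(x)), function(i)
                  list(x1 = x$x1[i], x2 = x$x2[i],
                       eigenvalues = c(x$re1[i], x$re2[i]),
                       stability = x$stability[i],
                       phenotype = if (is.na(x$phenotype[i])) NULL
                                   else x$phenotype[i]))), path)
}
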