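#' SNAIL-signal pathway in the (a, b) plane
#'
#' Under a limited pool of SNAIL molecules the signal raises the ZEB
#' activation `a` while lowering the miR-200 inhibition `b`; a pathway is the
#' line `b = -alpha a + beta` traversed from `a_from` to `a_to`. Points where
#' the line would give `b < 0` are excluded.
#'
#' @param alpha,beta positive constants of the line.
#' @param a_from,a_to scan end points; `a_from > a_to` scans with decreasing
#'   `a` (an MET-type path).
#' @return Object of class `"emt_pathway"`.
#' @examples
#' emt_pathway(alpha = 10, beta = 20, a_from = 0, a_to = 2)
#' @export
emt_pathway <- function(alpha, beta, a_from, a_to) {
  if (alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be positive", call. = FALSE)
  if (a_from < 0 || a_to < 0 || a_from == a_to)
    stop("'a_from' and 'a_to' must be distinct and >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, a_from = a_from, a_to = a_to,
                 direction = if (a_to > a_from) "increasing" else "decreasing"),
            class = "emt_pathway")
}

#' @export
print.emt_pathway <- function(x, ...) {
  cat(sprintf("Pathway b = -%g a + %g, a: %g -> %g (%s a)\n",
              x$alpha, x$beta, x$a_from, x$a_to, x$direction))
  invisible(x)
}

#' Bifurcation scan along a pathway
#'
#' Tracks all fixed points (stable and unstable) at `n_points` parameter
#' points along a pathway and records the regime at each.
#'
#' @param pathway an [emt_pathway()].
#' @param n_points number of scan points (>= 200 recommended for the printed
#'   pathways).
#' @param ... further model parameters passed to [emt_model()].
#' @param n_grid bracketing resolution of the root scan.
#' @return Object of class `"emt_bifurcation"`: list with `points` (data
#'   frame: `a`, `b`, `regime`, `n_stable`) and `branches` (long data frame of
#'   roots).
#' @export
pathway_scan <- function(pathway, n_points = 300L, ..., n_grid = 2001L) {
  stopifnot(inherits(pathway, "emt_pathway"))
  a <- seq(pathway$a_from, pathway$a_to, length.out = n_points)
  b <- -pathway$alpha * a + pathway$beta
  ok <- b >= 0
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("pathway has no points with b >= 0", call. = FALSE)
  model <- emt_model(a = a[1], b = b[1], ...)
  sc <- scan_states(model, a, b, n_grid = n_grid)
  sp <- split(sc, factor(sc$point, levels = seq_along(a)))
  pts <- data.frame(
    a = a, b = b,
    regime = vapply(sp, function(d)
      regime_of(d$stability, d$phenotype, d$marginal), character(1)),
    n_stable = vapply(sp, function(d) sum(d$stability == "stable"), integer(1))
  )
  sc$a <- a[sc$point]; sc$b <- b[sc$point]
  structure(list(points = pts,
                 branches = sc[, c("point", "a", "b", "x1", "x2",
                                   "stability", "phenotype")],
                 pathway = pathway, model = model),
            class = "emt_bifurcation")
}

#' Collapsed regime sequence of a scan
#'
#' Removes consecutive duplicate regimes along the pathway direction.
#' `"boundary"` points (marginal eigenvalues, i.e. the scan landed on a
#' bifurcation) are dropped before collapsing.
#'
#' @param scan an [pathway_scan()] result.
#' @return Character vector of distinct successive regimes.
#' @examples
#' sc <- pathway_scan(emt_pathway(13.33, 10, 0.75, 0), n_points = 200)
#' regime_sequence(sc)
#' @export
regime_sequence <- function(scan) {
  stopifnot(inherits(scan, "emt_bifurcation"))
  r <- scan$points$regime
  r <- r[r != "boundary"]
  if (!length(r)) return(character(0))
  rle(r)$values
}

#' @export
print.emt_bifurcation <- function(x, ...) {
  print(x$pathway)
  cat(sprintf("%d scan points; regime sequence: %s\n", nrow(x$points),
              paste(sprintf("{%s}", regime_sequence(x)), collapse = " -> ")))
  invisible(x)
}

#' @export
plot.emt_bifurcation <- function(x, ...) {
  br <- x$branches
  plot(NA, xlim = range(x$points$a), ylim = range(br$x1),
       xlab = "a", ylab = "x1 (ZEB)", ...)
  st <- br$stability == "stable"
  graphics::points(br$a[st], br$x1[st], pch = 16, cex = 0.3, col = "black")
  graphics::points(br$a[!st], br$x1[!st], pch = 16, cex = 0.3, col = "grey60")
  invisible(x)
}
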