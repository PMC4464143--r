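# Cusp-of-change dynamics for the order parameter.
#
# The order parameter xi relaxes under the cusp normal form
#   dxi/dt = c_int + c_ext * xi - xi^3
# (gradient flow of V(xi) = xi^4/4 - c_ext xi^2/2 - c_int xi), oriented so
# that the c_int = 0 section shows a pitchfork bifurcation at c_ext = 0
# and, for c_ext > 0, folds ("tipping points") at c_int = -a and +a.
# Equilibria are the real roots of xi^3 - c_ext xi - c_int = 0; an
# equilibrium is stable iff the flow derivative c_ext - 3 xi^2 < 0.

#' Control parameters of the cusp model
#'
#' @param c_ext Opportunity/risk tension (external control parameter).
#' @param c_int Proto-community potential (internal control parameter).
#' @return An object of class `cusp_params`.
#' @export
cusp_params <- function(c_ext, c_int) {
  if (!is.finite(c_ext) || !is.finite(c_int))
    stop("'c_ext' and 'c_int' must be finite")
  structure(list(c_ext = c_ext, c_int = c_int), class = "cusp_params")
}

.cusp_discriminant <- function(c_ext, c_int) 4 * c_ext^3 - 27 * c_int^2

# Real roots of xi^3 - c_ext xi - c_int = 0 with multiplicities. Closed
# forms are used at (near-)zero discriminant so double roots come out
# exact; elsewhere polyroot is reliable.
.cusp_roots <- function(c_ext, c_int) {
  disc <- .cusp_discriminant(c_ext, c_int)
  scale <- max(1, abs(c_ext)^1.5, abs(c_int))
  if (abs(disc) < 1e-9 * scale^2) {
    p <- -c_ext; q <- -c_int
    if (abs(p) < 1e-12 && abs(q) < 1e-12)
      return(data.frame(xi = 0, multiplicity = 3L))
    double_root <- -3 * q / (2 * p)
    simple_root <- 3 * q / p
    return(data.frame(xi = sort(c(double_root, simple_root)),
                      multiplicity = c(2L, 1L)[order(c(double_root,
                                                       simple_root))]))
  }
  z <- polyroot(c(-c_int, -c_ext, 0, 1))
  re <- Re(z)[abs(Im(z)) < 1e-8 * max(1, abs(z))]
  re <- sort(re)
  data.frame(xi = re, multiplicity = rep(1L, length(re)))
}

#' Equilibria of the cusp dynamics
#'
#' All real equilibria of dxi/dt = c_int + c_ext xi - xi^3 with stability
#' flags: `"stable"` when c_ext - 3 xi^2 < 0, `"unstable"` when > 0, and
#' `"marginal"` for double roots at a fold, where the flow derivative
#' vanishes. When three distinct equilibria exist they are, in increasing
#' xi, stable / unstable / stable.
#'
#' @param params A [cusp_params()], or `c_ext` when `c_int` is given.
#' @param c_int Used when `params` is a bare `c_ext` value.
#' @return A data frame of class `cusp_equilibria` with columns `xi` and
#'   `stability`, sorted by `xi`; control parameters kept as attributes.
#' @examples
#' cusp_equilibria(cusp_params(c_ext = 1, c_int = 0))  # -1, 0, 1
#' @export
cusp_equilibria <- function(params, c_int = NULL) {
  if (!inherits(params, "cusp_params"))
    params <- cusp_params(params, c_int)
  roots <- .cusp_roots(params$c_ext, params$c_int)
  fprime <- params$c_ext - 3 * roots$xi^2
  stability <- ifelse(roots$multiplicity > 1L, "marginal",
                      ifelse(fprime < 0, "stable", "unstable"))
  # triple root at the cusp tip has zero flow derivative
  stability[roots$multiplicity == 3L] <- "marginal"
  structure(data.frame(xi = roots$xi, stability = stability),
            class = c("cusp_equilibria", "data.frame"),
            c_ext = params$c_ext, c_int = params$c_int)
}

#' @export
print.cusp_equilibria <- function(x, ...) {
  cat(sprintf("<cusp_equilibria> c_ext = %g, c_int = %g\n",
              attr(x, "c_ext"), attr(x, "c_int")))
  print(data.frame(xi = round(x$xi, 6), stability = x$stability))
  invisible(x)
}

#' Is the cusp bi-stable at these controls?
#'
#' Bi-stability (two coexisting stable equilibria) holds exactly when the
#' equilibrium cubic has three distinct real roots, i.e. when the
#' discriminant 4 c_ext^3 - 27 c_int^2 is strictly positive. The boundary
#' (discriminant zero) is the fold set and is not bi-stable.
#'
#' @inheritParams cusp_equilibria
#' @return `TRUE` or `FALSE`.
#' @export
bistable <- function(params, c_int = NULL) {
  if (!inherits(params, "cusp_params"))
    params <- cusp_params(params, c_int)
  .cusp_discriminant(params$c_ext, params$c_int) > 0
}

#' Fold thresholds of the internal control parameter
#'
#' For c_ext >= 0, bi-stability is confined to |c_int| < a with
#' a = 2 (c_ext / 3)^(3/2), obtained from the vanishing of the cubic
#' discriminant. At c_int = -a and +a a stable branch is annihilated in a
#' fold (tipping point). For c_ext < 0 there is no fold and `NA` is
#' returned.
#'
#' @param c_ext External control parameter.
#' @return a >= 0, or `NA` when c_ext < 0.
#' @examples
#' fold_thresholds(3)  # 2
#' @export
fold_thresholds <- function(c_ext) {
  if (!is.finite(c_ext)) stop("'c_ext' must be finite")
  if (c_ext < 0) return(NA_real_)
  2 * (c_ext / 3)^1.5
}

#' Pitchfork section of the cusp at c_int = 0
#'
#' Sweeps c_ext along a grid at c_int = 0 and tabulates the stable
#' equilibria: a single stable equilibrium at 0 for c_ext < 0, two stable
#' equilibria at +/- sqrt(c_ext) beyond the pitchfork bifurcation at
#' c_ext = 0. The change point of the stable-equilibrium count is located
#' as the midpoint between the last grid value with one stable
#' equilibrium and the first with two.
#'
#' @param c_ext_grid Grid of c_ext values (non-empty, increasing).
#' @return A data frame with columns `c_ext`, `n_stable`, `stable_lo`,
#'   `stable_hi`; the estimated bifurcation location is attached as
#'   attribute `changepoint`.
#' @export
pitchfork_section <- function(c_ext_grid) {
  if (length(c_ext_grid) == 0L) stop("'c_ext_grid' must be non-empty")
  rows <- lapply(c_ext_grid, function(ce) {
    eq <- cusp_equilibria(cusp_params(ce, 0))
    st <- eq$xi[eq$stability == "stable"]
    data.frame(c_ext = ce, n_stable = length(st),
               stable_lo = if (length(st)) min(st) else NA_real_,
               stable_hi = if (length(st)) max(st) else NA_real_)
  })
  out <- do.call(rbind, rows)
  change <- NA_real_
  i2 <- which(out$n_stable >= 2L)
  if (length(i2)) {
    first2 <- min(i2)
    i1 <- which(out$n_stable == 1L & seq_len(nrow(out)) < first2)
    if (length(i1))
      change <- (out$c_ext[max(i1)] + out$c_ext[first2]) / 2
  }
  structure(out, changepoint = change)
}

#' Hysteresis sweep of the cusp order parameter
#'
#' Relaxes xi by explicit Euler steps of the cusp flow at each value of a
#' c_int path (typically up then down), carrying the relaxed xi forward to
#' the next path value. Jumps are detected where |delta xi| between
#' consecutive path values exceeds 0.5 — well above relaxation noise and
#' well below the inter-branch gap near the folds for c_ext >= 1. For
#' c_ext > 0 the up- and down-sweep jumps bracket the fold thresholds
#' +/- a; for c_ext < 0 the response is single-valued and no jumps occur.
#'
#' @param c_ext External control parameter, held fixed.
#' @param c_int_path Vector of c_int values visited in order.
#' @param h Euler step size (default 0.01).
#' @param steps_per_value Relaxation steps at each path value (default
#'   500).
#' @param xi0 Starting value of xi (default: the most negative stable
#'   equilibrium at the first path value).
#' @param jump Jump detection threshold on |delta xi| (default 0.5).
#' @return A data frame of class `hysteresis_sweep` with columns `index`,
#'   `c_int`, `xi`, `jump`; detected jump locations (c_int at which the
#'   jump lands) as attribute `jumps`.
#' @examples
#' path <- c(seq(-3, 3, by = 0.05), seq(3, -3, by = -0.05))
#' hs <- hysteresis_sweep(3, path)
#' attr(hs, "jumps")  # near +2 (up sweep) and -2 (down sweep)
#' @export
hysteresis_sweep <- function(c_ext, c_int_path, h = 0.01,
                             steps_per_value = 500L, xi0 = NULL,
                             jump = 0.5) {
  if (length(c_int_path) == 0L) stop("'c_int_path' must be non-empty")
  if (is.null(xi0)) {
    eq <- cusp_equilibria(cusp_params(c_ext, c_int_path[1L]))
    st <- eq$xi[eq$stability != "unstable"]
    xi0 <- if (length(st)) min(st) else eq$xi[1L]
  }
  xi <- xi0
  rel <- numeric(length(c_int_path))
  for (i in seq_along(c_int_path)) {
    ci <- c_int_path[i]
    for (s in seq_len(steps_per_value)) {
      xi <- xi + h * (ci + c_ext * xi - xi^3)
      if (abs(xi) > 10)
        stop("relaxation diverged (|xi| > 10); reduce 'h'")
    }
    rel[i] <- xi
  }
  jumped <- c(FALSE, abs(diff(rel)) > jump)
  # passage through a fold can spread one transition over consecutive
  # path values; a run of flagged values is a single jump event
  run_start <- jumped & !c(FALSE, jumped[-length(jumped)])
  structure(data.frame(index = seq_along(c_int_path), c_int = c_int_path,
                       xi = rel, jump = jumped),
            class = c("hysteresis_sweep", "data.frame"),
            c_ext = c_ext, jumps = c_int_path[run_start])
}
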