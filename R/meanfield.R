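# Mean-field analytics for the r = rho = 1 contagion.
#
# P_k is the probability that an individual is infected after k doses:
# P_k = E_g[ Pr(sum of k iid draws from f  >  d*) ], with the strict
# inequality of the infection rule. Under "all" dosing, with exposure
# probability p and infected fraction phi, the number of dosed slots in a
# memory window of length T is Binomial(T, p * phi), so the expected next
# infected fraction is
#   phi' = sum_{k=1..T} C(T,k) (p phi)^k (1 - p phi)^(T-k) P_k .

# --- survival function of the sum of k iid doses -------------------------

# Irwin-Hall CDF: sum of k iid U(0,1) at s, exact alternating sum.
.irwin_hall_cdf <- function(s, k) {
  vapply(s, function(si) {
    if (si <= 0) return(0)
    if (si >= k) return(1)
    j <- 0:floor(si)
    sum((-1)^j * choose(k, j) * (si - j)^k) / factorial(k)
  }, numeric(1))
}

# P(S_k > x) for S_k the sum of k iid draws from `model`, vectorized in x.
# Exact for delta and uniform families; discretized convolution for
# lognormal (grid resolution driven by `tol`).
.sum_survival <- function(model, k, tol = 1e-6) {
  p <- model$params
  switch(model$family,
    delta = function(x) as.numeric(k * p$value > x),
    uniform = function(x) {
      # affine map to Irwin-Hall: S_k = k*low + (high-low) * IH_k
      s <- (x - k * p$low) / (p$high - p$low)
      1 - .irwin_hall_cdf(s, k)
    },
    lognormal = {
      m <- 2^13
      upper <- k * qlnorm(1 - min(tol, 1e-6) / 10, p$meanlog, p$sdlog)
      edges <- seq(0, upper, length.out = m + 1L)
      pmf <- diff(plnorm(edges, p$meanlog, p$sdlog))
      pmf <- c(pmf, 1 - sum(pmf))                 # tail mass in last cell
      centers <- c((edges[-1L] + edges[-(m + 1L)]) / 2, upper)
      conv <- pmf
      cc <- centers
      if (k > 1L) {
        for (i in seq_len(k - 1L)) conv <- convolve(conv, rev(pmf),
                                                    type = "open")
        conv[conv < 0] <- 0
        cc <- seq(0, k * upper, length.out = length(conv))
      }
      surv_tail <- rev(cumsum(rev(conv)))
      function(x) {
        idx <- findInterval(x, cc) + 1L
        out <- numeric(length(x))
        inside <- idx <= length(cc)
        out[inside] <- surv_tail[idx[inside]]
        out
      }
    })
}

#' Probability of infection after k doses
#'
#' Computes P_k, the probability that the sum of `k` independent doses
#' drawn from the dose distribution f strictly exceeds a threshold drawn
#' from g. Dispatches between an exact closed form (available whenever the
#' dose model is `delta`, or the pair is `uniform` dose with `delta`
#' threshold), numerical quadrature (survival of the dose sum integrated
#' against the threshold density), and plain Monte Carlo.
#'
#' @param dose_model A [dose_model()].
#' @param threshold_model A [threshold_model()].
#' @param k Number of doses (positive integer).
#' @param method `"auto"` (closed form when available, else quadrature),
#'   `"closed_form"`, `"quadrature"`, or `"monte_carlo"`.
#' @param tol Numerical tolerance for quadrature (> 0).
#' @param n_rep Monte Carlo replicates (method `"monte_carlo"`), using the
#'   current RNG stream.
#' @return P_k in \[0, 1\].
#' @examples
#' infection_probability(dose_model("uniform", low = 0, high = 1),
#'                       threshold_model("delta", value = 0.5), k = 1)
#' @export
infection_probability <- function(dose_model, threshold_model, k,
                                  method = c("auto", "closed_form",
                                             "quadrature", "monte_carlo"),
                                  tol = 1e-6, n_rep = 1e5) {
  method <- match.arg(method)
  stopifnot(inherits(dose_model, "dist_model"),
            inherits(threshold_model, "dist_model"))
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (tol <= 0) stop("'tol' must be > 0")
  k <- as.integer(k)

  closed_ok <- dose_model$family == "delta" ||
    (dose_model$family == "uniform" && threshold_model$family == "delta" &&
       k <= 25L)
  if (method == "auto") method <- if (closed_ok) "closed_form" else
    "quadrature"

  val <- switch(method,
    closed_form = {
      if (!closed_ok)
        stop(sprintf("no closed form for %s dose with %s threshold",
                     dose_model$family, threshold_model$family))
      if (dose_model$family == "delta") {
        s <- k * dose_model$params$value
        if (threshold_model$family == "delta") {
          as.numeric(s > threshold_model$params$value)
        } else {
          .dist_cdf(threshold_model, s)   # P(d* < s), continuous g
        }
      } else {
        .sum_survival(dose_model, k)(threshold_model$params$value)
      }
    },
    quadrature = {
      surv <- .sum_survival(dose_model, k, tol)
      if (threshold_model$family == "delta") {
        surv(threshold_model$params$value)
      } else {
        # E_g[surv(d*)] by discretizing g: the survival of the dose sum
        # is step-like, so adaptive quadrature is ill-suited; cell masses
        # from CDF differences keep the expectation exact up to the grid
        # resolution
        m <- 2^12
        lo <- .dist_quantile(threshold_model, 0)
        hi <- .dist_quantile(threshold_model, 1 - 1e-9)
        edges <- seq(lo, hi, length.out = m + 1L)
        mass <- diff(.dist_cdf(threshold_model, edges))
        mass <- c(mass, 1 - sum(mass))
        mids <- c((edges[-1L] + edges[-(m + 1L)]) / 2, hi)
        sum(mass * surv(mids))
      }
    },
    monte_carlo = {
      sums <- rowSums(matrix(draw_dose(dose_model, n_rep * k),
                             nrow = n_rep, ncol = k))
      mean(sums > draw_dose(threshold_model, n_rep))
    })
  min(max(val, 0), 1)
}

#' The vector of infection probabilities P_1..P_T
#'
#' @inheritParams infection_probability
#' @param T_mem Memory length T; P_k is computed for k = 1..T.
#' @return An object of class `infection_probabilities`: the numeric
#'   vector (P_1, ..., P_T) with the models and T attached. Entries are
#'   non-decreasing in k (doses are nonnegative); tiny numerical
#'   decreases from quadrature are smoothed by a running maximum.
#' @examples
#' infection_probabilities(dose_model("delta", value = 1),
#'                         threshold_model("delta", value = 3.5), T_mem = 12)
#' @export
infection_probabilities <- function(dose_model, threshold_model, T_mem,
                                    method = "auto", tol = 1e-6,
                                    n_rep = 1e5) {
  if (T_mem < 1 || T_mem != round(T_mem))
    stop("'T_mem' must be a positive integer")
  vals <- vapply(seq_len(T_mem), function(k)
    infection_probability(dose_model, threshold_model, k, method, tol,
                          n_rep), numeric(1))
  vals <- cummax(pmin(pmax(vals, 0), 1))
  structure(vals, class = "infection_probabilities", T_mem = as.integer(T_mem),
            dose_model = dose_model, threshold_model = threshold_model)
}

#' @export
print.infection_probabilities <- function(x, ...) {
  cat(sprintf("<infection_probabilities> T = %d\n", attr(x, "T_mem")))
  print(round(as.numeric(x), 6))
  invisible(x)
}

.as_P <- function(P) {
  v <- as.numeric(P)
  if (any(v < 0 | v > 1)) stop("P_k entries must lie in [0, 1]")
  v
}

#' One step of the mean-field infected-fraction map
#'
#' Expected next infected fraction under "all" dosing with r = rho = 1:
#' the number of dosed memory slots is Binomial(T, p * phi) and each count
#' k infects with probability P_k.
#'
#' @param phi Current infected fraction(s) in \[0, 1\]; vectorized.
#' @param p_exposure Exposure probability p.
#' @param P An [infection_probabilities()] vector (length T).
#' @return phi', in \[0, 1\].
#' @examples
#' P <- infection_probabilities(dose_model("delta", value = 1),
#'                              threshold_model("delta", value = 0.5), 1)
#' meanfield_map(0.6, 0.5, P)  # 0.3
#' @export
meanfield_map <- function(phi, p_exposure, P) {
  if (any(!is.finite(phi)) || any(phi < 0 | phi > 1))
    stop("'phi' must lie in [0, 1]")
  v <- .as_P(P)
  T_mem <- length(v)
  vapply(phi, function(f)
    sum(dbinom(seq_len(T_mem), T_mem, p_exposure * f) * v), numeric(1))
}

#' Fixed points of the mean-field map
#'
#' Iterates the mean-field map to convergence from a grid of initial
#' infected fractions, deduplicates the limits, flags stability from the
#' numerical derivative of the map, and locates unstable basin-boundary
#' points by bisection between initial conditions that converge to
#' different limits (the map is monotone in phi, so a basin boundary is
#' itself a fixed point).
#'
#' @param p_exposure Exposure probability p.
#' @param P An [infection_probabilities()] vector.
#' @param grid_size Number of initial conditions on \[0, 1\] (>= 2).
#' @param tol Convergence tolerance on |delta phi| per iteration.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param starts Optional explicit initial conditions (overrides
#'   `grid_size`).
#' @return A data frame of class `steady_states` with columns `phi` and
#'   `stability` (`"stable"`, `"unstable"`, `"marginal"`), sorted by phi.
#'   Fixed points closer than 1e-6 are merged.
#' @examples
#' P <- infection_probabilities(dose_model("delta", value = 1),
#'                              threshold_model("delta", value = 3.5), 12)
#' steady_states(0.6, P)   # bistable: stable 0, unstable, stable high
#' @export
steady_states <- function(p_exposure, P, grid_size = 21L, tol = 1e-10,
                          max_iter = 10000L, starts = NULL) {
  if (is.null(starts)) {
    if (grid_size < 2) stop("'grid_size' must be >= 2")
    starts <- seq(0, 1, length.out = grid_size)
  }
  v <- .as_P(P)
  dedup_tol <- 1e-6    # documented merge tolerance for fixed points
  h <- 1e-5            # stability derivative step

  iterate <- function(phi0) {
    phi <- phi0
    for (i in seq_len(max_iter)) {
      nxt <- meanfield_map(phi, p_exposure, v)
      if (abs(nxt - phi) < tol) return(nxt)
      phi <- nxt
    }
    stop("mean-field iteration did not converge within 'max_iter'")
  }

  limits <- vapply(starts, iterate, numeric(1))
  fps <- limits[1L]
  for (x in limits[-1L]) if (all(abs(fps - x) > dedup_tol))
    fps <- c(fps, x)

  # basin boundaries between adjacent starts with different limits
  for (i in seq_len(length(starts) - 1L)) {
    if (abs(limits[i] - limits[i + 1L]) > dedup_tol) {
      lo <- starts[i]; hi <- starts[i + 1L]
      target <- limits[i]
      while (hi - lo > max(tol, 1e-12)) {
        mid <- (lo + hi) / 2
        if (abs(iterate(mid) - target) <= dedup_tol) lo <- mid else
          hi <- mid
      }
      b <- (lo + hi) / 2
      if (all(abs(fps - b) > dedup_tol)) fps <- c(fps, b)
    }
  }

  deriv <- function(x) {
    a <- max(0, x - h); b <- min(1, x + h)
    (meanfield_map(b, p_exposure, v) - meanfield_map(a, p_exposure, v)) /
      (b - a)
  }
  d <- vapply(fps, deriv, numeric(1))
  stability <- ifelse(abs(abs(d) - 1) < 1e-4, "marginal",
                      ifelse(abs(d) < 1, "stable", "unstable"))
  ord <- order(fps)
  structure(data.frame(phi = fps[ord], stability = stability[ord]),
            class = c("steady_states", "data.frame"),
            p_exposure = p_exposure, P = v)
}

#' Classify the contagion regime from P_1 and P_2
#'
#' Single-encounter contagion (no social reinforcement needed) when
#' P_1 >= P_2 / 2 and a single encounter can actually infect (P_1 > 0);
#' reinforcement-required contagion otherwise. The degenerate case
#' P_1 = P_2 = 0 satisfies the inequality vacuously yet describes a
#' process in which no first encounter ever infects, so it is labelled
#' reinforcement_required. The secondary inequality P_2 > P_1/2 >= 1/T is
#' evaluated and reported as an informational diagnostic only; it never
#' gates the label.
#'
#' @param P An [infection_probabilities()] vector of length >= 2.
#' @param T_mem Memory length (defaults to `length(P)`).
#' @return An object of class `regime_label` with elements `label`
#'   (`"single_encounter"` or `"reinforcement_required"`), `P1`, `P2`, and
#'   `diagnostics` (the compared quantities and the secondary flag).
#' @export
classify_regime <- function(P, T_mem = length(P)) {
  v <- .as_P(P)
  if (T_mem < 2 || length(v) < 2)
    stop("regime classification needs T >= 2 (P_2 must exist)")
  P1 <- v[1L]; P2 <- v[2L]
  label <- if (P1 >= P2 / 2 && P1 > 0) "single_encounter" else
    "reinforcement_required"
  structure(list(
    label = label, P1 = P1, P2 = P2,
    diagnostics = list(P1_vs_half_P2 = c(P1 = P1, half_P2 = P2 / 2),
                       secondary_condition =
                         (P2 > P1 / 2) && (P1 / 2 >= 1 / T_mem))),
    class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (P1 = %.4f, P2/2 = %.4f)\n",
              x$label, x$P1, x$P2 / 2))
  invisible(x)
}

#' Mean-field phase diagram over exposure probability
#'
#' For each exposure probability in `p_grid`, finds the fixed points of
#' the mean-field map and the contagion regime, and flags bi-stability
#' (two or more stable fixed points).
#'
#' @inheritParams infection_probabilities
#' @param p_grid Exposure probabilities to scan.
#' @param init_grid Initial infected fractions used as iteration starts.
#' @return A data frame with columns `p_exposure`, `n_stable`, `fp_1`,
#'   `fp_2`, `fp_unstable`, `bistable`, `regime`.
#' @export
phase_diagram <- function(dose_model, threshold_model, T_mem, p_grid,
                          init_grid = seq(0, 1, length.out = 21L),
                          method = "auto", tol = 1e-6) {
  if (length(p_grid) == 0L || length(init_grid) == 0L)
    stop("'p_grid' and 'init_grid' must be non-empty")
  P <- infection_probabilities(dose_model, threshold_model, T_mem,
                               method = method, tol = tol)
  regime <- if (T_mem >= 2) classify_regime(P)$label else NA_character_
  rows <- lapply(p_grid, function(p) {
    ss <- steady_states(p, P, starts = init_grid)
    st <- ss$phi[ss$stability == "stable"]
    un <- ss$phi[ss$stability == "unstable"]
    data.frame(p_exposure = p, n_stable = length(st),
               fp_1 = if (length(st) >= 1) st[1L] else NA_real_,
               fp_2 = if (length(st) >= 2) st[2L] else NA_real_,
               fp_unstable = if (length(un) >= 1) un[1L] else NA_real_,
               bistable = length(st) >= 2, regime = regime)
  })
  do.call(rbind, rows)
}
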