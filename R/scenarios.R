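# Coupling the cusp control parameters to contagion configurations, and
# trajectory-level diagnostics: phase-transition detection and
# proto-community persistence scoring.

#' Mapping from control parameters to contagion parameters
#'
#' The theory assigns the control parameters roles (proto-community
#' potential drives contagion speed; opportunity/risk tension moves the
#' system in and out of the reinforcement regime) but no functional link
#' to the dose model, so the link is an explicit, overridable layer. The
#' defaults are monotone: `p_exposure = logistic(c_int)` (increasing in
#' c_int) and threshold-model mean rescaled to `softplus(1 - c_ext)`
#' (decreasing in c_ext: higher tension, lower resistance). Either map can
#' be replaced or disabled with `NULL`.
#'
#' @param p_exposure `function(c_ext, c_int)` returning a probability, or
#'   `NULL` to leave the base value untouched.
#' @param threshold_scale `function(c_ext, c_int)` returning the target
#'   mean of the threshold model, or `NULL`.
#' @return An object of class `scenario_mapping`.
#' @examples
#' m <- scenario_mapping()
#' m$p_exposure(0, 0)  # 0.5 at the c_int = 0 anchor
#' @export
scenario_mapping <- function(
    p_exposure = function(c_ext, c_int) stats::plogis(c_int),
    threshold_scale = function(c_ext, c_int) log1p(exp(1 - c_ext))) {
  structure(list(p_exposure = p_exposure,
                 threshold_scale = threshold_scale),
            class = "scenario_mapping")
}

#' Apply a control-parameter mapping to contagion parameters
#'
#' Pure function: returns `base` with the mapped fields replaced according
#' to `mapping` evaluated at (c_ext, c_int).
#'
#' @param c_ext,c_int Control parameter values (finite).
#' @param mapping A [scenario_mapping()].
#' @param base A [contagion_params()] supplying all unmapped fields.
#' @return A [contagion_params()].
#' @export
map_controls <- function(c_ext, c_int, mapping = scenario_mapping(), base) {
  if (!is.finite(c_ext) || !is.finite(c_int))
    stop("control parameters must be finite")
  stopifnot(inherits(mapping, "scenario_mapping"),
            inherits(base, "contagion_params"))
  out <- base
  if (!is.null(mapping$p_exposure)) {
    p <- mapping$p_exposure(c_ext, c_int)
    if (!is.finite(p) || p < 0 || p > 1)
      stop("mapping produced p_exposure outside [0, 1]")
    out$p_exposure <- p
  }
  if (!is.null(mapping$threshold_scale)) {
    s <- mapping$threshold_scale(c_ext, c_int)
    if (!is.finite(s) || s <= 0)
      stop("mapping produced a non-positive threshold scale")
    out$threshold_model <- .dist_rescale(base$threshold_model, s)
  }
  out
}

#' Detect phase transitions in an order-parameter series
#'
#' A phase transition is a change of the order parameter from one stable
#' level to another ("nearly -1 to nearly 1"): an event is emitted where
#' the mean xi over the trailing window and the mean over the leading
#' window differ by more than `jump` while each window is internally
#' stable (standard deviation below `stability_tol`). Events are at least
#' `window` steps apart.
#'
#' @param traj A `contagion_trajectory`, or a bare numeric xi series
#'   (assumed to start at t = 0).
#' @param jump Minimum |difference of window means| in xi units (default
#'   1.0).
#' @param window Window length in steps (default 20).
#' @param stability_tol Maximum within-window standard deviation (default
#'   0.2).
#' @return A data frame with one row per event: `t` (first step of the
#'   leading window), `xi_before`, `xi_after`, `magnitude`.
#' @examples
#' x <- c(rep(-0.9, 50), rep(0.9, 150))
#' detect_phase_transitions(x)  # one event at t = 50, magnitude 1.8
#' @export
detect_phase_transitions <- function(traj, jump = 1.0, window = 20L,
                                     stability_tol = 0.2) {
  xi <- if (inherits(traj, "contagion_trajectory")) traj$xi else
    as.numeric(traj)
  tt <- if (inherits(traj, "contagion_trajectory")) traj$t else
    seq_along(xi) - 1L
  L <- length(xi)
  if (L <= 2L * window) stop("trajectory too short for the chosen window")
  events <- list()
  last_i <- -Inf
  for (i in (window + 1L):(L - window + 1L)) {
    if (i - last_i < window) next
    before <- xi[(i - window):(i - 1L)]
    after <- xi[i:(i + window - 1L)]
    mb <- mean(before); ma <- mean(after)
    if (abs(ma - mb) > jump && sd(before) < stability_tol &&
        sd(after) < stability_tol) {
      events[[length(events) + 1L]] <-
        data.frame(t = tt[i], xi_before = mb, xi_after = ma,
                   magnitude = abs(ma - mb))
      last_i <- i
    }
  }
  if (length(events) == 0L)
    return(data.frame(t = integer(), xi_before = numeric(),
                      xi_after = numeric(), magnitude = numeric()))
  do.call(rbind, events)
}

#' Proto-community persistence score
#'
#' A proto-community persists when the order parameter keeps its sign and
#' stays close to its recent level while membership turns over. The score
#' is the fraction of post-burn-in steps at which sign(xi) matches
#' `target_xi_sign` and |xi - trailing window mean| < `tol`; 1 means fully
#' persistent.
#'
#' @param traj A `contagion_trajectory` (typically from [turnover_run()]),
#'   or a bare numeric xi series.
#' @param target_xi_sign +1 or -1: the ordered state whose persistence is
#'   scored.
#' @param window Trailing window length for the local level (default 20).
#' @param tol Allowed deviation of xi from its windowed mean (default
#'   0.2).
#' @param burn_in Fraction of initial steps excluded (default 0.25).
#' @return A persistence score in \[0, 1\].
#' @export
proto_community_persistence <- function(traj, target_xi_sign,
                                        window = 20L, tol = 0.2,
                                        burn_in = 0.25) {
  if (!target_xi_sign %in% c(-1, 1))
    stop("'target_xi_sign' must be +1 or -1")
  xi <- if (inherits(traj, "contagion_trajectory")) traj$xi else
    as.numeric(traj)
  L <- length(xi)
  if (window > L) stop("'window' exceeds the trajectory length")
  start <- floor(burn_in * L) + 1L
  ok <- logical(0)
  for (i in start:L) {
    wm <- mean(xi[max(1L, i - window + 1L):i])
    ok <- c(ok, sign(xi[i]) == target_xi_sign && abs(xi[i] - wm) < tol)
  }
  mean(ok)
}
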