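# S3 methods and writers for contagion trajectories.

#' @export
print.contagion_trajectory <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("<contagion_trajectory> n = %d, %d steps (t = %d .. %d)\n",
              n, nrow(x) - 1L, min(x$t), max(x$t)))
  rr <- attr(x, "replacement_rate")
  if (!is.null(rr)) cat(sprintf("  turnover: replacement_rate = %g\n", rr))
  cat(sprintf("  final: I = %d (%.3f), xi = %.3f\n",
              x$I[nrow(x)], x$infected_fraction[nrow(x)], x$xi[nrow(x)]))
  invisible(x)
}

#' @export
summary.contagion_trajectory <- function(object, last = 50L, ...) {
  idx <- seq.int(max(1L, nrow(object) - last + 1L), nrow(object))
  out <- list(
    n = attr(object, "n"), steps = nrow(object) - 1L,
    seed = attr(object, "seed"),
    final_infected_fraction = object$infected_fraction[nrow(object)],
    mean_infected_fraction_tail = mean(object$infected_fraction[idx]),
    mean_xi_tail = mean(object$xi[idx]),
    max_R = max(object$R))
  class(out) <- "summary.contagion_trajectory"
  out
}

#' @export
print.summary.contagion_trajectory <- function(x, ...) {
  cat(sprintf("contagion trajectory: n = %d, %d steps\n", x$n, x$steps))
  cat(sprintf("  final infected fraction: %.4f\n",
              x$final_infected_fraction))
  cat(sprintf("  tail mean infected fraction: %.4f (xi = %.4f)\n",
              x$mean_infected_fraction_tail, x$mean_xi_tail))
  cat(sprintf("  max R over run: %d\n", x$max_R))
  invisible(x)
}

#' @export
plot.contagion_trajectory <- function(x, which = c("xi", "compartments"),
                                      ...) {
  which <- match.arg(which)
  if (which == "xi") {
    plot(x$t, x$xi, type = "l", ylim = c(-1, 1),
         xlab = "t", ylab = expression(xi), ...)
    abline(h = 0, lty = 3)
  } else {
    plot(x$t, x$S, type = "l", ylim = c(0, attr(x, "n")),
         xlab = "t", ylab = "individuals", ...)
    lines(x$t, x$I, lty = 2)
    lines(x$t, x$R, lty = 3)
    legend("topright", c("S", "I", "R"), lty = 1:3, bty = "n")
  }
  invisible(x)
}

.params_to_list <- function(params) {
  list(p_exposure = params$p_exposure, T_mem = params$T_mem,
       r = params$r, rho = params$rho,
       dose = c(list(family = params$dose_model$family),
                params$dose_model$params),
       threshold = c(list(family = params$threshold_model$family),
                     params$threshold_model$params),
       contagious_state = params$contagious_state,
       dosing_mode = params$dosing_mode,
       redraw_threshold_on_resusceptibility =
         params$redraw_threshold_on_resusceptibility)
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' Writes the per-step records as CSV (columns
#' `t,S,I,R,infected_fraction,xi` plus `replacements` for turnover runs)
#' and the full resolved parameter set and seed as a JSON sidecar next to
#' it (`<path>.json`). Floating-point columns are rounded to 10
#' significant digits so repeated runs with one seed are byte-identical.
#'
#' @param traj A `contagion_trajectory`.
#' @param path Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "contagion_trajectory"))
  df <- as.data.frame(traj)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 10)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(params = .params_to_list(attr(traj, "params")),
               n = attr(traj, "n"), seed = attr(traj, "seed"))
  rr <- attr(traj, "replacement_rate")
  if (!is.null(rr)) meta$replacement_rate <- rr
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}
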