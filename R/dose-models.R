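# Dose and threshold distributions f(d) and g(d*).
# Three supported families, all with nonnegative support:
#   delta(value)            - point mass
#   uniform(low, high)      - continuous uniform, 0 <= low < high
#   lognormal(meanlog, sdlog)
# A dose model describes the per-contact emotional "dose"; a threshold
# model describes the individual infection thresholds drawn once at t0.

.new_dist_model <- function(family, params, class) {
  family <- match.arg(family, c("delta", "uniform", "lognormal"))
  p <- switch(family,
    delta = {
      stopifnot("delta needs 'value'" = !is.null(params$value))
      if (params$value < 0) stop("delta value must be >= 0")
      list(value = params$value)
    },
    uniform = {
      stopifnot(!is.null(params$low), !is.null(params$high))
      if (params$low < 0 || params$high <= params$low)
        stop("uniform needs 0 <= low < high")
      list(low = params$low, high = params$high)
    },
    lognormal = {
      stopifnot(!is.null(params$meanlog), !is.null(params$sdlog))
      if (params$sdlog <= 0) stop("lognormal needs sdlog > 0")
      list(meanlog = params$meanlog, sdlog = params$sdlog)
    })
  structure(list(family = family, params = p),
            class = c(class, "dist_model"))
}

#' Dose distribution f(d)
#'
#' Constructs the distribution of the emotional dose received from a single
#' infected contact. All families have nonnegative support.
#'
#' @param family One of `"delta"`, `"uniform"`, `"lognormal"`.
#' @param value Point mass for `delta`.
#' @param low,high Bounds for `uniform` (0 <= low < high).
#' @param meanlog,sdlog Log-scale parameters for `lognormal`.
#' @return An object of class `dose_model`.
#' @examples
#' dose_model("delta", value = 1)
#' dose_model("uniform", low = 0, high = 1)
#' @export
dose_model <- function(family, value = NULL, low = NULL, high = NULL,
                       meanlog = NULL, sdlog = NULL) {
  .new_dist_model(family, list(value = value, low = low, high = high,
                               meanlog = meanlog, sdlog = sdlog),
                  "dose_model")
}

#' Threshold distribution g(d*)
#'
#' Constructs the distribution from which individual infection thresholds
#' d* are drawn once at initialization (and optionally re-drawn on
#' re-susceptibility). Same families as [dose_model()].
#'
#' @inheritParams dose_model
#' @return An object of class `threshold_model`.
#' @export
threshold_model <- function(family, value = NULL, low = NULL, high = NULL,
                            meanlog = NULL, sdlog = NULL) {
  .new_dist_model(family, list(value = value, low = low, high = high,
                               meanlog = meanlog, sdlog = sdlog),
                  "threshold_model")
}

#' @export
print.dist_model <- function(x, ...) {
  cat(sprintf("<%s> %s(%s)\n", class(x)[1L], x$family,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Draw samples from a dose or threshold model
#'
#' @param model A [dose_model()] or [threshold_model()].
#' @param n Number of draws.
#' @return Numeric vector of `n` nonnegative samples, using the current
#'   RNG stream.
#' @export
draw_dose <- function(model, n = 1L) {
  stopifnot(inherits(model, "dist_model"))
  p <- model$params
  switch(model$family,
    delta = rep.int(p$value, n),
    uniform = runif(n, p$low, p$high),
    lognormal = rlnorm(n, p$meanlog, p$sdlog))
}

# CDF P(X <= x), vectorized over x
.dist_cdf <- function(model, x) {
  p <- model$params
  switch(model$family,
    delta = as.numeric(x >= p$value),
    uniform = punif(x, p$low, p$high),
    lognormal = plnorm(x, p$meanlog, p$sdlog))
}

.dist_quantile <- function(model, q) {
  p <- model$params
  switch(model$family,
    delta = rep.int(p$value, length(q)),
    uniform = qunif(q, p$low, p$high),
    lognormal = qlnorm(q, p$meanlog, p$sdlog))
}

.dist_mean <- function(model) {
  p <- model$params
  switch(model$family,
    delta = p$value,
    uniform = (p$low + p$high) / 2,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2))
}

# Rescale a model so its mean becomes `target` (shape preserved).
# Used by the scenario mapping layer.
.dist_rescale <- function(model, target) {
  stopifnot(target > 0)
  p <- model$params
  cls <- class(model)[1L]
  switch(model$family,
    delta = .new_dist_model("delta", list(value = target), cls),
    uniform = {
      s <- target / .dist_mean(model)
      .new_dist_model("uniform", list(low = p$low * s, high = p$high * s),
                      cls)
    },
    lognormal = .new_dist_model(
      "lognormal",
      list(meanlog = log(target) - p$sdlog^2 / 2, sdlog = p$sdlog), cls))
}

#' Sum of doses in a memory window
#'
#' The cumulative dose D(t) is the plain sum of the dose memory buffer,
#' i.e. of the doses received over the last T time steps.
#'
#' @param memory Numeric vector of nonnegative doses (the buffer), or a
#'   matrix with one row per individual.
#' @return The sum per buffer (vector if `memory` is a matrix).
#' @examples
#' cumulative_dose(c(1, 0, 2))  # 3
#' @export
cumulative_dose <- function(memory) {
  if (is.matrix(memory)) return(rowSums(memory))
  if (length(memory) == 0L) stop("empty memory buffer")
  sum(memory)
}
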