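# Plain-text run configuration (YAML key/value schema).
#
# Recognized keys (all others are rejected):
#   n, p_pea, seed, p_exposure, T_mem, r, rho, dose, threshold,
#   contagious_state, dosing_mode, redraw_threshold_on_resusceptibility,
#   init_infected_fraction, t_max, replacement_rate, c_ext, c_int,
#   out, log_level
# `dose` and `threshold` are nested maps: family plus family parameters,
# e.g. dose: {family: delta, value: 1}.

.config_keys <- c("n", "p_pea", "seed", "p_exposure", "T_mem", "r", "rho",
                  "dose", "threshold", "contagious_state", "dosing_mode",
                  "redraw_threshold_on_resusceptibility",
                  "init_infected_fraction", "t_max", "replacement_rate",
                  "c_ext", "c_int", "out", "log_level")

.config_defaults <- list(r = 1, rho = 1, p_pea = 0.5,
                         dosing_mode = "susceptible_only", log_level = "info")

.check_prob <- function(cfg, key) {
  v <- cfg[[key]]
  if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1))
    stop(sprintf("config field '%s' must be a probability in [0, 1], got %s",
                 key, format(v)))
}

.config_dist <- function(x, key, class_fn) {
  if (is.null(x)) return(NULL)
  if (is.null(x$family))
    stop(sprintf("config field '%s' needs a 'family' entry", key))
  do.call(class_fn, x)
}

#' Validate and normalize a run configuration
#'
#' Checks the key set and field ranges of a configuration list, optionally
#' fills the documented defaults (r = 1, rho = 1, p_pea = 0.5,
#' dosing_mode = "susceptible_only", log_level = "info"; each applied default is
#' logged), and returns the normalized `run_config`.
#'
#' @param cfg A named list of configuration values.
#' @param fill_defaults Apply and log defaults for missing keys.
#' @return An object of class `run_config` with keys in canonical order.
#' @export
validate_config <- function(cfg, fill_defaults = TRUE) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  if (fill_defaults) {
    for (key in names(.config_defaults)) {
      if (is.null(cfg[[key]])) {
        cfg[[key]] <- .config_defaults[[key]]
        message(sprintf("config default applied: %s = %s", key,
                        format(.config_defaults[[key]])))
      }
    }
  }
  for (key in c("p_pea", "p_exposure", "r", "rho",
                "init_infected_fraction", "replacement_rate"))
    .check_prob(cfg, key)
  if (!is.null(cfg$n) && (cfg$n < 1 || cfg$n != round(cfg$n)))
    stop("config field 'n' must be a positive integer")
  if (!is.null(cfg$T_mem) && (cfg$T_mem < 1 || cfg$T_mem != round(cfg$T_mem)))
    stop("config field 'T_mem' must be a positive integer")
  if (!is.null(cfg$t_max) && cfg$t_max < 1)
    stop("config field 't_max' must be >= 1")
  if (!is.null(cfg$contagious_state) &&
      !cfg$contagious_state %in% c("PEA", "NEA"))
    stop("config field 'contagious_state' must be 'PEA' or 'NEA'")
  if (!is.null(cfg$dosing_mode) && !cfg$dosing_mode %in% c("susceptible_only", "all"))
    stop("config field 'dosing_mode' must be 'susceptible_only' or 'all'")
  # validate nested distribution specs by constructing them
  .config_dist(cfg$dose, "dose", dose_model)
  .config_dist(cfg$threshold, "threshold", threshold_model)
  cfg <- cfg[intersect(.config_keys, names(cfg))]  # canonical order
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration file
#'
#' Parses a YAML configuration, rejects unknown keys with a field-level
#' message, validates ranges, and fills the documented defaults (each one
#' logged).
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 treats a bare `n` key as boolean; restore the field name
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  validate_config(cfg)
}

#' Write a run configuration file
#'
#' Writes the normalized configuration as YAML with keys in canonical
#' order, so `write_config(read_config(path))` reproduces an identical
#' normalized file.
#'
#' @param cfg A `run_config` (or plain list; it is validated first
#'   without default filling).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "run_config"))
    cfg <- validate_config(cfg, fill_defaults = FALSE)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build contagion parameters from a run configuration
#'
#' @param cfg A `run_config` containing at least `p_exposure`, `T_mem`,
#'   `dose` and `threshold`.
#' @return A [contagion_params()].
#' @export
config_contagion_params <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  need <- c("p_exposure", "T_mem", "dose", "threshold")
  miss <- need[vapply(need, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(miss))
    stop(sprintf("config is missing field(s): %s",
                 paste(miss, collapse = ", ")))
  contagion_params(
    p_exposure = cfg$p_exposure, T_mem = cfg$T_mem,
    r = if (is.null(cfg$r)) 1 else cfg$r,
    rho = if (is.null(cfg$rho)) 1 else cfg$rho,
    dose_model = .config_dist(cfg$dose, "dose", dose_model),
    threshold_model = .config_dist(cfg$threshold, "threshold",
                                   threshold_model),
    contagious_state = if (is.null(cfg$contagious_state)) "PEA" else
      cfg$contagious_state,
    dosing_mode = if (is.null(cfg$dosing_mode)) "susceptible_only" else
      cfg$dosing_mode,
    redraw_threshold_on_resusceptibility =
      isTRUE(cfg$redraw_threshold_on_resusceptibility))
}
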