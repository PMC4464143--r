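# Seeded scenario presets. Every test and example input regenerates from
# (name, seed); nothing is downloaded. Numeric values are chosen for
# clean analytic oracles: unit doses against a delta(3.5) threshold make
# P_k a step function at k = 4, and a delta(0.5) threshold makes P_1 = 1.

.fixture_names <- c("substrate_iid", "fire_in_theater",
                    "bistable_syndicate", "turnover_community",
                    "cusp_grid")

#' Generate a named scenario fixture
#'
#' Returns the full, reproducible parameter bundle for one of the
#' built-in scenario presets and optionally materializes it on disk
#' (config YAML, plus a lattice CSV for `cusp_grid`).
#'
#' * `substrate_iid` — the baseline iid substrate: n = 10000,
#'   p_pea = 0.5 (mean order parameter 0).
#' * `fire_in_theater` — single-encounter contagion: one dose suffices
#'   (dose delta(1) vs threshold delta(0.5), T = 1, so P_1 = 1),
#'   p_exposure = 0.9, all-receive dosing. The mean-field map is subcritical and
#'   decays to 0.
#' * `bistable_syndicate` — reinforcement-required contagion: four unit
#'   doses within a 12-step memory needed (threshold delta(3.5)),
#'   p_exposure = 0.6, all-receive dosing, started at infected fraction 0.9. The
#'   mean-field map is bi-stable.
#' * `turnover_community` — the bi-stable scenario at n = 2000 with 1%
#'   membership turnover per step.
#' * `cusp_grid` — a (c_ext, c_int) lattice over \[-3, 3\]^2 (step 0.25)
#'   with the bi-stability flag of the cusp at each node.
#'
#' @param name One of the preset names above.
#' @param seed Integer seed stored in the bundle and used for any
#'   materialized randomness.
#' @param dir Optional directory; when given, config/CSV files are
#'   written there (byte-identical for identical `(name, seed)`).
#' @return An object of class `fixture_spec`: a list with `name`,
#'   `description`, `seed`, and the relevant parameter objects
#'   (`substrate`, `contagion`, `n`, `t_max`, `init_infected_fraction`,
#'   `replacement_rate`, `cusp_lattice`, `files`).
#' @examples
#' fx <- generate_fixture("bistable_syndicate", seed = 1)
#' fx$contagion
#' @export
generate_fixture <- function(name, seed = 1L, dir = NULL) {
  if (!name %in% .fixture_names)
    stop(sprintf("unknown fixture '%s'; known: %s", name,
                 paste(.fixture_names, collapse = ", ")))
  seed <- as.integer(seed)
  fx <- switch(name,
    substrate_iid = list(
      description = "iid bi-state substrate, mean order parameter 0",
      substrate = substrate_params(10000L, p_pea = 0.5, seed = seed)),
    fire_in_theater = list(
      description = paste("single-encounter contagion: P_1 = 1,",
                          "one dose infects"),
      n = 10000L, t_max = 300L, init_infected_fraction = 0.5,
      contagion = contagion_params(
        p_exposure = 0.9, T_mem = 1L,
        dose_model = dose_model("delta", value = 1),
        threshold_model = threshold_model("delta", value = 0.5),
        dosing_mode = "all")),
    bistable_syndicate = list(
      description = paste("reinforcement-required contagion: 4 unit",
                          "doses in a 12-step memory needed; bi-stable",
                          "mean-field map"),
      n = 10000L, t_max = 300L, init_infected_fraction = 0.9,
      contagion = contagion_params(
        p_exposure = 0.6, T_mem = 12L,
        dose_model = dose_model("delta", value = 1),
        threshold_model = threshold_model("delta", value = 3.5),
        dosing_mode = "all")),
    turnover_community = list(
      description = "bi-stable scenario with 1% membership turnover",
      n = 2000L, t_max = 300L, init_infected_fraction = 0.9,
      replacement_rate = 0.01,
      contagion = contagion_params(
        p_exposure = 0.6, T_mem = 12L,
        dose_model = dose_model("delta", value = 1),
        threshold_model = threshold_model("delta", value = 3.5),
        dosing_mode = "all")),
    cusp_grid = {
      g <- seq(-12L, 12L) / 4
      lattice <- expand.grid(c_ext = g, c_int = g)
      lattice$bistable <- mapply(function(ce, ci)
        bistable(cusp_params(ce, ci)), lattice$c_ext, lattice$c_int)
      list(description = "cusp control-parameter lattice over [-3,3]^2",
           cusp_lattice = lattice)
    })
  fx$name <- name
  fx$seed <- seed
  fx$files <- character(0)
  class(fx) <- "fixture_spec"
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (name == "cusp_grid") {
      path <- file.path(dir, "cusp_grid.csv")
      write.csv(fx$cusp_lattice, path, row.names = FALSE, quote = FALSE)
      fx$files <- path
    } else {
      path <- file.path(dir, paste0(name, ".yaml"))
      write_config(as_run_config(fx), path)
      fx$files <- path
    }
  }
  fx
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("<fixture_spec> %s (seed %d)\n  %s\n", x$name, x$seed,
              x$description))
  invisible(x)
}

# Flatten a fixture into a run_config list (contagion fixtures only).
as_run_config <- function(fx) {
  stopifnot(inherits(fx, "fixture_spec"))
  if (fx$name == "substrate_iid") {
    cfg <- list(n = fx$substrate$n, p_pea = fx$substrate$p_pea,
                seed = fx$seed)
  } else if (!is.null(fx$contagion)) {
    p <- fx$contagion
    cfg <- list(n = fx$n, seed = fx$seed,
                p_exposure = p$p_exposure, T_mem = p$T_mem,
                r = p$r, rho = p$rho,
                dose = c(list(family = p$dose_model$family),
                         p$dose_model$params),
                threshold = c(list(family = p$threshold_model$family),
                              p$threshold_model$params),
                contagious_state = p$contagious_state,
                dosing_mode = p$dosing_mode,
                init_infected_fraction = fx$init_infected_fraction,
                t_max = fx$t_max)
    if (!is.null(fx$replacement_rate))
      cfg$replacement_rate <- fx$replacement_rate
  } else {
    stop("fixture has no run configuration")
  }
  validate_config(cfg, fill_defaults = FALSE)
}
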