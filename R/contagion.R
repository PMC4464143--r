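# Generalized dose-memory-threshold contagion.
#
# Each step, every individual contacts one uniformly random other (no
# self-contact). If the contact is infected and the receiver is eligible,
# a dose drawn from f(d) lands with probability p_exposure. Each
# individual remembers the doses of the last T steps; a susceptible whose
# cumulative dose D(t) strictly exceeds its threshold d* becomes infected.
# Infected individuals whose D(t) has fallen to or below d* recover with
# probability r (directly to S when rho = 1, otherwise to R); removed
# individuals become susceptible again with probability rho. All updates
# are synchronous against the time-t state.

#' Parameters of the contagion engine
#'
#' @param p_exposure Probability that a contact with an infected individual
#'   delivers a dose, in \[0, 1\].
#' @param T_mem Memory length T: number of past steps whose doses are
#'   accumulated (positive integer).
#' @param r Per-step recovery probability for infected individuals whose
#'   cumulative dose no longer exceeds their threshold. Default 1.
#' @param rho Per-step re-susceptibility probability for removed
#'   individuals. Default 1. With r = rho = 1 the removed compartment is
#'   always empty and the dynamics are analytically solvable.
#' @param dose_model A [dose_model()]; dose distribution f(d).
#' @param threshold_model A [threshold_model()]; threshold distribution
#'   g(d*).
#' @param contagious_state Which emotional state spreads, `"PEA"` (default)
#'   or `"NEA"`. Non-infected individuals carry the opposite state.
#' @param dosing_mode `"susceptible_only"` (default): only susceptibles receive doses
#'   and infected memories drain passively; `"all"`: every individual
#'   receives doses and compartment status is a pure function of the
#'   memory window. `"all"` is the mode matched by the mean-field map.
#' @param redraw_threshold_on_resusceptibility If `TRUE`, an individual
#'   re-entering S draws a fresh threshold from g. Default `FALSE`.
#' @return An object of class `contagion_params`.
#' @examples
#' contagion_params(p_exposure = 0.6, T_mem = 12,
#'                  dose_model = dose_model("delta", value = 1),
#'                  threshold_model = threshold_model("delta", value = 3.5),
#'                  dosing_mode = "all")
#' @export
contagion_params <- function(p_exposure, T_mem, r = 1, rho = 1,
                             dose_model, threshold_model,
                             contagious_state = c("PEA", "NEA"),
                             dosing_mode = c("susceptible_only", "all"),
                             redraw_threshold_on_resusceptibility = FALSE) {
  for (nm in c("p_exposure", "r", "rho")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  if (length(T_mem) != 1L || !is.finite(T_mem) || T_mem < 1 ||
      T_mem != round(T_mem))
    stop("'T_mem' must be a positive integer")
  stopifnot(inherits(dose_model, "dist_model"),
            inherits(threshold_model, "dist_model"))
  structure(list(p_exposure = p_exposure, T_mem = as.integer(T_mem),
                 r = r, rho = rho,
                 dose_model = dose_model, threshold_model = threshold_model,
                 contagious_state = match.arg(contagious_state),
                 dosing_mode = match.arg(dosing_mode),
                 redraw_threshold_on_resusceptibility =
                   isTRUE(redraw_threshold_on_resusceptibility)),
            class = "contagion_params")
}

#' @export
print.contagion_params <- function(x, ...) {
  cat(sprintf(paste0("<contagion_params> p_exposure = %g, T = %d, ",
                     "r = %g, rho = %g, mode = %s, contagious = %s\n"),
              x$p_exposure, x$T_mem, x$r, x$rho, x$dosing_mode,
              x$contagious_state))
  print(x$dose_model); print(x$threshold_model)
  invisible(x)
}

# Seed a population for a contagion run: thresholds from g, floor(n * f0)
# random infected whose newest memory slot is pre-loaded just above their
# threshold so that status follows memory from step one.
init_contagion <- function(n, params, init_infected_fraction) {
  if (init_infected_fraction < 0 || init_infected_fraction > 1)
    stop("'init_infected_fraction' must be in [0, 1]")
  contagious <- .state_code(params$contagious_state)
  threshold <- draw_dose(params$threshold_model, n)
  memory <- matrix(0, nrow = n, ncol = params$T_mem)
  comp <- integer(n)
  n_inf <- floor(n * init_infected_fraction)
  if (n_inf > 0) {
    idx <- sample.int(n, n_inf)
    comp[idx] <- 1L
    memory[idx, params$T_mem] <- threshold[idx] * (1 + 1e-6)
  }
  state <- ifelse(comp == 1L, contagious, -contagious)
  new_population(state = as.integer(state), compartment = comp,
                 threshold = threshold, memory = memory)
}

#' Advance a contagion population by one step
#'
#' Performs one synchronous update: random pairwise contacts, probabilistic
#' dosing, memory shift, threshold-triggered infection, recovery and
#' re-susceptibility. Uses the current RNG stream; seed control belongs to
#' [run_contagion()].
#'
#' @param pop An initialized `population` (thresholds drawn, memory sized
#'   T).
#' @param params A [contagion_params()].
#' @return A list with the updated `population` and the new compartment
#'   `counts` (see [compartment_counts()]).
#' @export
contagion_step <- function(pop, params) {
  n <- pop$n
  if (n < 2L) stop("contagion requires at least 2 individuals")
  if (anyNA(pop$threshold))
    stop("population not initialized for contagion (thresholds unset)")
  if (ncol(pop$memory) != params$T_mem)
    stop("memory buffer width does not match T_mem")
  comp <- pop$compartment
  infected <- comp == 1L

  # one uniformly random partner per individual, self excluded
  partner <- sample.int(n - 1L, n, replace = TRUE)
  partner <- partner + (partner >= seq_len(n))

  eligible <- if (params$dosing_mode == "susceptible_only") comp == 0L else rep(TRUE, n)
  dosed <- eligible & infected[partner] & (runif(n) < params$p_exposure)
  dose <- numeric(n)
  nd <- sum(dosed)
  if (nd > 0L) dose[dosed] <- draw_dose(params$dose_model, nd)

  mem <- pop$memory
  if (ncol(mem) > 1L) {
    mem <- cbind(mem[, -1L, drop = FALSE], dose, deparse.level = 0L)
  } else {
    mem[, 1L] <- dose
  }
  D <- rowSums(mem)

  newcomp <- comp
  newcomp[comp == 0L & D > pop$threshold] <- 1L   # strict exceedance
  recovering <- comp == 1L & D <= pop$threshold & (runif(n) < params$r)
  newcomp[recovering] <- if (params$rho == 1) 0L else 2L
  resusc <- comp == 2L & (runif(n) < params$rho)
  newcomp[resusc] <- 0L

  threshold <- pop$threshold
  if (params$redraw_threshold_on_resusceptibility) {
    entering_s <- newcomp == 0L & comp != 0L
    ns <- sum(entering_s)
    if (ns > 0L) threshold[entering_s] <- draw_dose(params$threshold_model, ns)
  }

  contagious <- .state_code(params$contagious_state)
  state <- ifelse(newcomp == 1L, contagious, -contagious)
  out <- new_population(state = as.integer(state), compartment = newcomp,
                        threshold = threshold, memory = mem,
                        t = pop$t + 1L)
  list(population = out, counts = compartment_counts(out))
}

.traj_row <- function(pop, contagious_code) {
  cnt <- compartment_counts(pop)
  xi <- if (contagious_code == .PEA) 2 * cnt$infected_fraction - 1
        else 1 - 2 * cnt$infected_fraction
  data.frame(t = pop$t, S = cnt$S, I = cnt$I, R = cnt$R,
             infected_fraction = cnt$infected_fraction, xi = xi)
}

.new_trajectory <- function(records, params, n, seed, replacement_rate = NULL) {
  structure(records, class = c("contagion_trajectory", "data.frame"),
            params = params, n = n, seed = seed,
            replacement_rate = replacement_rate)
}

#' Run a seeded contagion simulation
#'
#' Initializes a population of `n` individuals (thresholds drawn from g,
#' `floor(n * init_infected_fraction)` infected with pre-loaded memories),
#' then iterates [contagion_step()] `t_max` times. The trajectory records
#' compartment counts, infected fraction, and the order parameter xi at
#' every step, including the initial state at t = 0.
#'
#' @param params A [contagion_params()].
#' @param n Population size (>= 2).
#' @param t_max Number of steps (>= 1).
#' @param init_infected_fraction Initial infected fraction in \[0, 1\].
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A `contagion_trajectory`: a data frame with columns
#'   `t, S, I, R, infected_fraction, xi` and the run parameters and seed
#'   stored as attributes.
#' @examples
#' tr <- run_contagion(
#'   contagion_params(0.6, T_mem = 12,
#'                    dose_model = dose_model("delta", value = 1),
#'                    threshold_model = threshold_model("delta", value = 3.5),
#'                    dosing_mode = "all"),
#'   n = 500, t_max = 50, init_infected_fraction = 0.9, seed = 1)
#' summary(tr)
#' @export
run_contagion <- function(params, n, t_max, init_infected_fraction,
                          seed = NULL) {
  stopifnot(inherits(params, "contagion_params"))
  if (t_max < 1) stop("'t_max' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  contagious <- .state_code(params$contagious_state)
  pop <- init_contagion(n, params, init_infected_fraction)
  records <- vector("list", t_max + 1L)
  records[[1L]] <- .traj_row(pop, contagious)
  for (k in seq_len(t_max)) {
    pop <- contagion_step(pop, params)$population
    records[[k + 1L]] <- .traj_row(pop, contagious)
  }
  .new_trajectory(do.call(rbind, records), params, n, seed)
}

#' Run a contagion simulation with membership turnover
#'
#' As [run_contagion()], but after every step a binomially sampled number
#' of individuals (each independently with probability `replacement_rate`)
#' leaves and is replaced by a fresh susceptible newcomer: zero dose
#' memory, new threshold from g, non-contagious state. This is the
#' experiment behind the proto-community definition: a proto-community
#' persists when the order parameter stays stable under such turnover.
#'
#' @inheritParams run_contagion
#' @param replacement_rate Per-individual per-step replacement probability
#'   in \[0, 1\]. With `replacement_rate = 0` the trajectory is identical
#'   to [run_contagion()] under the same seed.
#' @return A `contagion_trajectory` with an extra `replacements` column.
#' @export
turnover_run <- function(params, n, t_max, init_infected_fraction,
                         replacement_rate, seed = NULL) {
  stopifnot(inherits(params, "contagion_params"))
  if (replacement_rate < 0 || replacement_rate > 1)
    stop("'replacement_rate' must be in [0, 1]")
  if (t_max < 1) stop("'t_max' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  contagious <- .state_code(params$contagious_state)
  pop <- init_contagion(n, params, init_infected_fraction)
  records <- vector("list", t_max + 1L)
  records[[1L]] <- cbind(.traj_row(pop, contagious), replacements = 0L)
  for (k in seq_len(t_max)) {
    pop <- contagion_step(pop, params)$population
    n_rep <- 0L
    if (replacement_rate > 0) {
      n_rep <- rbinom(1L, n, replacement_rate)
      if (n_rep > 0L) {
        idx <- sample.int(n, n_rep)
        pop$compartment[idx] <- 0L
        pop$state[idx] <- -contagious
        pop$memory[idx, ] <- 0
        pop$threshold[idx] <- draw_dose(params$threshold_model, n_rep)
      }
    }
    records[[k + 1L]] <- cbind(.traj_row(pop, contagious),
                               replacements = n_rep)
  }
  .new_trajectory(do.call(rbind, records), params, n, seed,
                  replacement_rate = replacement_rate)
}
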