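#' @importFrom stats runif rbinom sd punif plnorm qunif qlnorm
#'   rlnorm dbinom convolve
#' @importFrom utils write.csv read.csv head tail modifyList
#' @importFrom graphics lines legend abline par
NULL

# Emotional states are encoded numerically: PEA = +1, NEA = -1.
# Compartments are integer codes: 0 = S, 1 = I, 2 = R.
.PEA <- 1L
.NEA <- -1L

.state_code <- function(state) {
  if (is.numeric(state)) {
    if (!all(state %in% c(1, -1))) stop("numeric state must be +1 or -1")
    return(as.integer(state))
  }
  code <- c(PEA = .PEA, NEA = .NEA)[toupper(as.character(state))]
  if (anyNA(code)) stop("state must be 'PEA' or 'NEA'")
  unname(code)
}

.state_label <- function(code) c("NEA", "PEA")[(code + 3L) / 2L]

#' Parameters of the iid emotional substrate
#'
#' Bundles the size, PEA probability and seed of the baseline population of
#' autonomous individuals whose emotional states are independent and
#' identically distributed: PEA (+1) with probability `p_pea`, NEA (-1)
#' otherwise.
#'
#' @param n Population size (positive integer).
#' @param p_pea Probability that an individual starts in the PEA state,
#'   in \[0, 1\]. The default 0.5 normalizes the substrate mean to 0.
#' @param seed Optional integer seed for reproducible generation.
#' @return An object of class `substrate_params`.
#' @export
substrate_params <- function(n, p_pea = 0.5, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (length(p_pea) != 1L || !is.finite(p_pea) || p_pea < 0 || p_pea > 1)
    stop("'p_pea' must be a probability in [0, 1]")
  structure(list(n = as.integer(n), p_pea = p_pea, seed = seed),
            class = "substrate_params")
}

#' Generate an iid bi-state population substrate
#'
#' Draws `n` individuals whose emotional states are independent: PEA (+1)
#' with probability `p_pea`, NEA (-1) otherwise. All individuals start
#' susceptible with an all-zero dose memory of length `T_mem`; infection
#' thresholds are left unset until a contagion run initializes them.
#'
#' @param params A [substrate_params()] object, or a population size `n`
#'   (in which case `p_pea` and `seed` are read from the remaining
#'   arguments).
#' @param p_pea,seed Used only when `params` is a bare population size.
#' @param T_mem Dose-memory length allocated per individual (columns of the
#'   memory matrix); defaults to 1 and is re-sized by the contagion engine.
#' @return An object of class `population`: a list with elements `n`, `t`,
#'   `state` (+1/-1 vector), `compartment` (0 = S, 1 = I, 2 = R),
#'   `threshold` (NA until initialized), and `memory` (n x T matrix).
#' @examples
#' pop <- generate_substrate(substrate_params(1000, p_pea = 0.5, seed = 1))
#' order_parameter(pop)
#' @export
generate_substrate <- function(params, p_pea = 0.5, seed = NULL, T_mem = 1L) {
  if (!inherits(params, "substrate_params"))
    params <- substrate_params(params, p_pea, seed)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  state <- ifelse(runif(n) < params$p_pea, .PEA, .NEA)
  new_population(state = as.integer(state),
                 compartment = integer(n),
                 threshold = rep(NA_real_, n),
                 memory = matrix(0, nrow = n, ncol = max(1L, T_mem)))
}

new_population <- function(state, compartment, threshold, memory, t = 0L) {
  n <- length(state)
  stopifnot(length(compartment) == n, length(threshold) == n,
            nrow(memory) == n)
  structure(list(n = n, t = as.integer(t), state = state,
                 compartment = compartment, threshold = threshold,
                 memory = memory),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cnt <- compartment_counts(x)
  cat(sprintf("<population> n = %d, t = %d\n", x$n, x$t))
  cat(sprintf("  S = %d, I = %d, R = %d; xi = %.4f\n",
              cnt$S, cnt$I, cnt$R, order_parameter(x)))
  invisible(x)
}

#' @export
as.data.frame.population <- function(x, ...) {
  data.frame(id = seq_len(x$n),
             state = .state_label(x$state),
             compartment = c("S", "I", "R")[x$compartment + 1L],
             threshold = x$threshold,
             cumulative_dose = rowSums(x$memory))
}

#' Compartment counts of a population
#'
#' Tallies the susceptible, infected and removed compartments. The counts
#' always satisfy S + I + R = N.
#'
#' @param pop A `population`.
#' @return A list with integer `S`, `I`, `R` and `infected_fraction` = I/N.
#' @export
compartment_counts <- function(pop) {
  tab <- tabulate(pop$compartment + 1L, nbins = 3L)
  list(S = tab[1L], I = tab[2L], R = tab[3L],
       infected_fraction = tab[2L] / pop$n)
}

#' Order parameter of a bi-state population
#'
#' The order parameter xi in \[-1, 1\] measures the degree of emotional
#' ordering: xi = (count(PEA) - count(NEA)) / N, i.e. the mean of the
#' +1/-1 state encoding. xi = +1 for an all-PEA population, -1 for all-NEA,
#' 0 for a balanced mix. A sudden, stable change of xi from near one
#' extreme to the other is the signature of a phase transition.
#'
#' @param pop A `population`, or a bare numeric vector of +1/-1 states.
#' @return xi, a single number in \[-1, 1\].
#' @examples
#' order_parameter(rep(1, 10))   #  1: all PEA
#' order_parameter(rep(-1, 10))  # -1: all NEA
#' @export
order_parameter <- function(pop) {
  state <- if (inherits(pop, "population")) pop$state else .state_code(pop)
  if (length(state) == 0L) stop("population is empty")
  mean(state)
}

#' Sampling distribution of the order parameter
#'
#' Emulates an observer estimating xi by repeatedly observing random
#' subsets of a substrate population: generates the substrate, draws
#' `n_samples` subsets of `sample_size` individuals without replacement,
#' and summarizes the per-subset order parameters.
#'
#' @param params A [substrate_params()] object.
#' @param n_samples Number of subsets to draw (>= 1).
#' @param sample_size Individuals per subset; must not exceed `params$n`.
#' @param seed Integer seed controlling both substrate generation and
#'   subset sampling.
#' @return A list with `mean`, `sd`, `min`, `max` of the xi estimates and
#'   the vector `xi` itself.
#' @export
sample_order_parameter <- function(params, n_samples, sample_size,
                                   seed = NULL) {
  stopifnot(inherits(params, "substrate_params"))
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  if (sample_size > params$n)
    stop("'sample_size' exceeds the population size")
  if (sample_size < 1) stop("'sample_size' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pop <- generate_substrate(substrate_params(params$n, params$p_pea))
  xi <- vapply(seq_len(n_samples), function(i) {
    idx <- sample.int(pop$n, sample_size)
    mean(pop$state[idx])
  }, numeric(1))
  list(mean = mean(xi), sd = if (n_samples > 1) sd(xi) else 0,
       min = min(xi), max = max(xi), xi = xi)
}
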