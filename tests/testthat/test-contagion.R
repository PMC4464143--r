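# Helper: two-individual population with one infected, delta models.
two_person_pop <- function(threshold, T_mem = 1L) {
  params <- contagion_params(p_exposure = 1, T_mem = T_mem, r = 0,
                             dose_model = unit_dose(),
                             threshold_model = delta_threshold(threshold))
  set.seed(1)
  pop <- init_contagion(2, params, 0)
  pop$compartment[1L] <- 1L
  pop$state[1L] <- 1L
  pop$memory[1L, T_mem] <- threshold * 2  # keep 1 infected
  list(pop = pop, params = params)
}

test_that("a dose strictly above the threshold infects on contact", {
  tp <- two_person_pop(threshold = 0.5)
  out <- contagion_step(tp$pop, tp$params)
  expect_identical(out$population$compartment[2L], 1L)
})

test_that("a cumulative dose exactly equal to the threshold never infects", {
  tp <- two_person_pop(threshold = 1.0)  # dose 1 == threshold 1
  for (i in 1:5) tp$pop <- contagion_step(tp$pop, tp$params)$population
  expect_identical(tp$pop$compartment[2L], 0L)
})

test_that("without dosing, infected recover once the memory drains", {
  # p_exposure = 0, r = rho = 1, susceptible-only dosing: memory drains in T steps
  params <- contagion_params(p_exposure = 0, T_mem = 3L,
                             dose_model = unit_dose(),
                             threshold_model = delta_threshold(1.5))
  set.seed(4)
  pop <- init_contagion(50, params, 1)
  for (i in 1:3) pop <- contagion_step(pop, params)$population
  expect_identical(compartment_counts(pop)$I, 0L)
})

test_that("compartments always partition the population; r = rho = 1 keeps R empty", {
  params <- bistable_params()
  tr <- run_contagion(params, n = 400, t_max = 60,
                      init_infected_fraction = 0.5, seed = 5)
  expect_true(all(tr$S + tr$I + tr$R == 400))
  expect_true(all(tr$R == 0))
  expect_true(all(tr$infected_fraction >= 0 & tr$infected_fraction <= 1))
  expect_true(all(abs(tr$xi - (2 * tr$infected_fraction - 1)) < 1e-12))
})

test_that("the removed compartment fills and drains when r, rho < 1", {
  params <- contagion_params(p_exposure = 0.5, T_mem = 2L, r = 0.5,
                             rho = 0.3, dose_model = unit_dose(),
                             threshold_model = delta_threshold(0.5),
                             dosing_mode = "susceptible_only")
  tr <- run_contagion(params, n = 300, t_max = 80,
                      init_infected_fraction = 0.3, seed = 6)
  expect_true(all(tr$S + tr$I + tr$R == 300))
  expect_gt(max(tr$R), 0)
})

test_that("each step drops the oldest memory entry and appends the new dose", {
  params <- contagion_params(p_exposure = 0, T_mem = 3L,
                             dose_model = unit_dose(),
                             threshold_model = delta_threshold(10))
  set.seed(7)
  pop <- init_contagion(5, params, 0)
  pop$memory <- matrix(runif(15), 5, 3)
  before <- pop$memory
  after <- contagion_step(pop, params)$population$memory
  expect_equal(after[, 1:2], before[, 2:3], ignore_attr = TRUE)
  expect_true(all(after[, 3] == 0))  # p_exposure = 0: no new doses
})

test_that("no initial infection means no contagion ever", {
  tr <- run_contagion(bistable_params(), n = 200, t_max = 30,
                      init_infected_fraction = 0, seed = 8)
  expect_true(all(tr$I == 0))
})

test_that("saturated single-encounter dosing keeps everyone infected", {
  params <- single_encounter_params(p_exposure = 1)
  tr <- run_contagion(params, n = 200, t_max = 30,
                      init_infected_fraction = 1, seed = 9)
  expect_true(all(tr$infected_fraction == 1))
})

test_that("time-averaged infection is monotone in exposure probability", {
  p_grid <- c(0.3, 0.55, 0.8)
  params <- contagion_params(p_exposure = 0.5, T_mem = 3L,
                             dose_model = unit_dose(),
                             threshold_model = delta_threshold(1.5),
                             dosing_mode = "all")
  means <- sapply(p_grid, function(p) {
    params$p_exposure <- p
    per_seed <- vapply(1:20, function(s) {
      tr <- run_contagion(params, n = 400, t_max = 40,
                          init_infected_fraction = 0.5, seed = s)
      mean(tr$infected_fraction)
    }, numeric(1))
    c(mean(per_seed), sd(per_seed) / sqrt(20))
  })
  # non-decreasing within Monte-Carlo error
  expect_gt(means[1, 2] - means[1, 1],
            -3 * sqrt(means[2, 1]^2 + means[2, 2]^2))
  expect_gt(means[1, 3] - means[1, 2],
            -3 * sqrt(means[2, 2]^2 + means[2, 3]^2))
})

test_that("equal seeds reproduce trajectories exactly", {
  a <- run_contagion(bistable_params(), 300, 40, 0.7, seed = 10)
  b <- run_contagion(bistable_params(), 300, 40, 0.7, seed = 10)
  expect_identical(a, b)
})

test_that("zero turnover reproduces the plain run exactly", {
  a <- run_contagion(bistable_params(), 300, 40, 0.9, seed = 11)
  b <- turnover_run(bistable_params(), 300, 40, 0.9,
                    replacement_rate = 0, seed = 11)
  expect_identical(a$I, b$I)
  expect_true(all(b$replacements == 0))
})

test_that("full replacement extinguishes subcritical contagion within T+1 steps", {
  params <- contagion_params(p_exposure = 0.2, T_mem = 3L,
                             dose_model = unit_dose(),
                             threshold_model = delta_threshold(1.5),
                             dosing_mode = "all")
  tr <- turnover_run(params, 400, 10, 0.5, replacement_rate = 1, seed = 12)
  expect_true(all(tr$I[tr$t >= 4] == 0))
})

test_that("moderate turnover keeps the bi-stable community above the unstable point", {
  P <- infection_probabilities(unit_dose(), delta_threshold(3.5), 12)
  ss <- steady_states(0.6, P)
  phi_unstable <- ss$phi[ss$stability == "unstable"]
  expect_length(phi_unstable, 1L)
  for (s in 1:3) {
    tr <- turnover_run(bistable_params(), 2000, 200, 0.9,
                       replacement_rate = 0.01, seed = s)
    expect_gt(mean(tr$infected_fraction[tr$t >= 100 & tr$t <= 200]),
              phi_unstable)
  }
})

test_that("NEA can be the contagious state, with the xi identity flipped", {
  params <- contagion_params(p_exposure = 1, T_mem = 1L,
                             dose_model = unit_dose(),
                             threshold_model = delta_threshold(0.5),
                             contagious_state = "NEA",
                             dosing_mode = "all")
  tr <- run_contagion(params, 200, 20, 1, seed = 13)
  expect_true(all(abs(tr$xi - (1 - 2 * tr$infected_fraction)) < 1e-12))
  expect_identical(tr$xi[nrow(tr)], -1)
})
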