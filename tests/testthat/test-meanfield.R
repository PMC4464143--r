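test_that("infection probability closed forms match first principles", {
  # every unit dose beats a 0.5 threshold
  for (k in 1:4)
    expect_identical(infection_probability(unit_dose(),
                                           delta_threshold(0.5), k), 1)
  # one unit dose cannot beat 1.5; two can
  expect_identical(infection_probability(unit_dose(),
                                         delta_threshold(1.5), 1), 0)
  expect_identical(infection_probability(unit_dose(),
                                         delta_threshold(1.5), 2), 1)
  # P(U(0,1) > 0.5) = 0.5
  expect_equal(infection_probability(dose_model("uniform", low = 0,
                                                high = 1),
                                     delta_threshold(0.5), 1), 0.5)
  # ties never infect: k*value == threshold exactly
  expect_identical(infection_probability(unit_dose(),
                                         delta_threshold(2), 2), 0)
})

test_that("P_k is non-decreasing in k across random model pairs", {
  set.seed(31)
  for (i in 1:20) {
    dm <- switch(sample(3, 1),
                 dose_model("delta", value = runif(1, 0.1, 2)),
                 dose_model("uniform", low = 0, high = runif(1, 0.5, 2)),
                 dose_model("lognormal", meanlog = runif(1, -1, 0.5),
                            sdlog = runif(1, 0.2, 0.8)))
    tm <- switch(sample(3, 1),
                 threshold_model("delta", value = runif(1, 0.5, 4)),
                 threshold_model("uniform", low = 0,
                                 high = runif(1, 1, 4)),
                 threshold_model("lognormal", meanlog = runif(1, 0, 1),
                                 sdlog = runif(1, 0.2, 0.8)))
    P <- infection_probabilities(dm, tm, 6)
    expect_true(all(diff(as.numeric(P)) >= 0))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("quadrature and Monte Carlo estimates of P_k agree", {
  set.seed(32)
  for (i in 1:20) {
    dm <- switch(sample(2, 1),
                 dose_model("uniform", low = 0, high = runif(1, 0.5, 2)),
                 dose_model("lognormal", meanlog = runif(1, -1, 0),
                            sdlog = runif(1, 0.2, 0.7)))
    tm <- switch(sample(3, 1),
                 threshold_model("delta", value = runif(1, 0.5, 3)),
                 threshold_model("uniform", low = 0,
                                 high = runif(1, 1, 4)),
                 threshold_model("lognormal", meanlog = runif(1, 0, 0.7),
                                 sdlog = runif(1, 0.2, 0.7)))
    k <- sample(1:4, 1)
    q <- infection_probability(dm, tm, k, method = "quadrature",
                               tol = 1e-6)
    mc <- infection_probability(dm, tm, k, method = "monte_carlo",
                                n_rep = 2e4)
    se <- sqrt(max(q * (1 - q), 1e-6) / 2e4)
    expect_lt(abs(q - mc), 4 * se + 0.005)
  }
})

test_that("the mean-field map reduces to its analytic special cases", {
  # T = 1, P_1 = 1: phi' = p * phi
  P1 <- infection_probabilities(unit_dose(), delta_threshold(0.5), 1)
  expect_equal(meanfield_map(0.6, 0.5, P1), 0.3)
  # T = 2, P = (0, 1), p = 1: phi' = phi^2
  P2 <- infection_probabilities(unit_dose(), delta_threshold(1.5), 2)
  phis <- seq(0, 1, by = 0.1)
  expect_equal(meanfield_map(phis, 1, P2), phis^2)
  # the map stays inside [0, 1]
  set.seed(33)
  for (i in 1:50) {
    P <- sort(runif(sample(1:8, 1)))
    out <- meanfield_map(runif(1), runif(1), P)
    expect_gte(out, 0); expect_lte(out, 1)
  }
  expect_error(meanfield_map(1.2, 0.5, P1), "0, 1")
})

test_that("fixed-point search matches exhaustive cobweb iteration", {
  cases <- list(
    list(p = 0.5, P = c(1)),                 # contraction to 0
    list(p = 1,   P = c(0, 1)),              # phi^2: 0 stable, 1 unstable
    list(p = 0.6, P = c(rep(0, 3), rep(1, 9))))  # bi-stable step at k=4
  for (cs in cases) {
    ss <- steady_states(cs$p, cs$P)
    oracle <- oracle_fixed_points(cs$p, cs$P)
    stable <- ss$phi[ss$stability == "stable"]
    # every cobweb limit is one of the reported fixed points
    for (fp in oracle)
      expect_true(min(abs(ss$phi - fp)) < 1e-4)
    # every reported stable point is a cobweb limit
    for (fp in stable)
      expect_true(min(abs(oracle - fp)) < 1e-4)
  }
})

test_that("the bi-stable configuration has two stable states and a separatrix", {
  P <- infection_probabilities(unit_dose(), delta_threshold(3.5), 12)
  ss <- steady_states(0.6, P)
  stable <- ss$phi[ss$stability == "stable"]
  unstable <- ss$phi[ss$stability == "unstable"]
  expect_length(stable, 2L)
  expect_length(unstable, 1L)
  expect_equal(stable[1], 0)
  expect_gt(stable[2], unstable)
  expect_gt(unstable, stable[1])
})

test_that("regime classification follows the P1 vs P2/2 rule", {
  expect_identical(classify_regime(c(0.6, 1.0))$label, "single_encounter")
  expect_identical(classify_regime(c(0.1, 0.9))$label,
                   "reinforcement_required")
  # boundary resolved toward single encounter
  expect_identical(classify_regime(c(0.5, 1.0))$label, "single_encounter")
  # degenerate all-zero head: no first-encounter infection is possible
  expect_identical(classify_regime(c(0, 0, 0, 1))$label,
                   "reinforcement_required")
  expect_error(classify_regime(c(0.5)), "T >= 2")
  diag <- classify_regime(c(0.3, 0.8, 1, 1))$diagnostics
  expect_true(is.logical(diag$secondary_condition))
})

test_that("the phase diagram flags bi-stability only under reinforcement", {
  pd <- phase_diagram(unit_dose(), delta_threshold(3.5), 12,
                      p_grid = c(0.3, 0.6, 0.9))
  expect_identical(unique(pd$regime), "reinforcement_required")
  expect_true(pd$bistable[pd$p_exposure == 0.6])
  # single-encounter linear map: never bistable below p = 1
  pd1 <- phase_diagram(unit_dose(), delta_threshold(0.5), 1,
                       p_grid = c(0.2, 0.5, 0.9))
  expect_true(all(!pd1$bistable))
  expect_true(all(pd1$n_stable == 1L))
  expect_equal(pd1$fp_1, c(0, 0, 0))
  # p = 0: unique fixed point at 0
  pd0 <- phase_diagram(unit_dose(), delta_threshold(3.5), 12, p_grid = 0)
  expect_equal(pd0$fp_1, 0)
  expect_false(pd0$bistable)
})

test_that("simulated steady states land on stable mean-field fixed points", {
  # scaled-down version of the full agreement experiment: one seed each
  for (mk in list(bistable_params(), single_encounter_params())) {
    P <- infection_probabilities(mk$dose_model, mk$threshold_model,
                                 mk$T_mem)
    ss <- steady_states(mk$p_exposure, P)
    stable <- ss$phi[ss$stability == "stable"]
    tr <- run_contagion(mk, n = 4000, t_max = 200,
                        init_infected_fraction = 0.9, seed = 34)
    phi_sim <- mean(tr$infected_fraction[(nrow(tr) - 49):nrow(tr)])
    fp <- stable[which.min(abs(stable - phi_sim))]
    expect_lt(abs(phi_sim - fp),
              3 * sqrt(max(fp * (1 - fp), 1e-12) / 4000) + 0.01)
  }
})
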