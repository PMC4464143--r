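test_that("cusp equilibria match known factorizations", {
  eq <- cusp_equilibria(cusp_params(-1, 0))
  expect_equal(eq$xi, 0)
  expect_identical(eq$stability, "stable")

  eq <- cusp_equilibria(cusp_params(1, 0))
  expect_equal(eq$xi, c(-1, 0, 1))
  expect_identical(eq$stability, c("stable", "unstable", "stable"))

  # fold point: (xi+1)^2 (xi-2) = xi^3 - 3 xi - 2
  eq <- cusp_equilibria(cusp_params(3, 2))
  expect_equal(eq$xi, c(-1, 2))
  expect_identical(eq$stability, c("marginal", "stable"))
})

test_that("discriminant sign predicts the root structure on random parameters", {
  set.seed(41)
  for (i in 1:1000) {
    ce <- runif(1, -3, 3); ci <- runif(1, -3, 3)
    disc <- 4 * ce^3 - 27 * ci^2
    br <- brute_roots(ce, ci)
    eq <- cusp_equilibria(cusp_params(ce, ci))
    expect_identical(length(br) == 3L, disc > 0)
    expect_identical(nrow(eq), length(br))
    expect_equal(eq$xi, br, tolerance = 1e-6)
    expect_identical(bistable(cusp_params(ce, ci)), disc > 0)
    if (nrow(eq) == 3L)
      expect_identical(eq$stability, c("stable", "unstable", "stable"))
  }
})

test_that("equilibria obey the cusp symmetries", {
  set.seed(42)
  for (i in 1:50) {
    ce <- runif(1, -2, 2); ci <- runif(1, -2, 2)
    a <- cusp_equilibria(cusp_params(ce, ci))
    b <- cusp_equilibria(cusp_params(ce, -ci))
    expect_equal(sort(a$xi), sort(-b$xi), tolerance = 1e-8)
    s <- cusp_equilibria(cusp_params(ce, 0))
    expect_equal(sort(s$xi), sort(-s$xi), tolerance = 1e-8)
  }
})

test_that("fold thresholds come from the vanishing discriminant", {
  expect_equal(fold_thresholds(3), 2)
  expect_identical(fold_thresholds(0), 0)
  expect_true(is.na(fold_thresholds(-1)))
  # bistable <=> |c_int| < a for c_ext > 0
  set.seed(43)
  for (i in 1:50) {
    ce <- runif(1, 0.1, 3); ci <- runif(1, -3, 3)
    a <- fold_thresholds(ce)
    expect_identical(bistable(cusp_params(ce, ci)), abs(ci) < a)
  }
})

test_that("the pitchfork section changes stable count exactly at zero tension", {
  grid <- seq(-100L, 100L) / 100
  sect <- pitchfork_section(grid)
  expect_equal(attr(sect, "changepoint"), 0)
  expect_true(all(sect$n_stable[sect$c_ext < 0] == 1L))
  expect_true(all(sect$n_stable[sect$c_ext > 0] == 2L))
  row <- sect[sect$c_ext == 1, ]
  expect_equal(c(row$stable_lo, row$stable_hi), c(-1, 1))
  row <- sect[sect$c_ext == -1, ]
  expect_equal(c(row$stable_lo, row$stable_hi), c(0, 0))
})

test_that("hysteresis jumps bracket the fold thresholds", {
  step <- 0.05
  path <- c(seq(-3, 3, by = step), seq(3, -3, by = -step))
  hs <- hysteresis_sweep(3, path, steps_per_value = 2000L)
  jumps <- attr(hs, "jumps")
  expect_length(jumps, 2L)
  a <- fold_thresholds(3)
  expect_lt(abs(jumps[1] - a), step + 1e-9)
  expect_lt(abs(jumps[2] - (-a)), step + 1e-9)
})

test_that("a single-valued response shows no hysteresis", {
  up <- seq(-1, 1, by = 0.05)
  hs <- hysteresis_sweep(-1, c(up, rev(up)))
  expect_length(attr(hs, "jumps"), 0L)
  n <- length(up)
  up_branch <- hs$xi[seq_len(n)]
  down_branch <- rev(hs$xi[n + seq_len(n)])
  expect_lt(max(abs(up_branch - down_branch)), 1e-3)
})

test_that("stable equilibria are relaxation fixed points", {
  set.seed(44)
  for (i in 1:10) {
    ce <- runif(1, -2, 3); ci <- runif(1, -1.5, 1.5)
    eq <- cusp_equilibria(cusp_params(ce, ci))
    for (xi_star in eq$xi[eq$stability == "stable"]) {
      hs <- hysteresis_sweep(ce, rep(ci, 2), xi0 = xi_star + 0.009)
      expect_lt(abs(hs$xi[2] - xi_star), 0.01)
    }
  }
})

test_that("relaxation from a positive start finds the positive stable root", {
  hs <- hysteresis_sweep(3, c(0, 0), xi0 = 0.9)
  expect_equal(hs$xi[2], sqrt(3), tolerance = 1e-6)
})
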