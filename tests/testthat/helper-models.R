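# Shared builders for the standard test scenarios.

unit_dose <- function() dose_model("delta", value = 1)

delta_threshold <- function(value) threshold_model("delta", value = value)

# reinforcement-required, bi-stable configuration: 4 unit doses within a
# 12-step memory needed, p_exposure = 0.6, all-receive dosing
bistable_params <- function() {
  contagion_params(p_exposure = 0.6, T_mem = 12L,
                   dose_model = unit_dose(),
                   threshold_model = delta_threshold(3.5),
                   dosing_mode = "all")
}

# single-encounter configuration: one dose infects, memory length 1
single_encounter_params <- function(p_exposure = 0.9) {
  contagion_params(p_exposure = p_exposure, T_mem = 1L,
                   dose_model = unit_dose(),
                   threshold_model = delta_threshold(0.5),
                   dosing_mode = "all")
}

# the mean-field map written out independently of the package
# implementation (vectorized over phi), for oracle checks
oracle_map <- function(phi, p, P) {
  T_mem <- length(P)
  out <- numeric(length(phi))
  for (k in seq_len(T_mem))
    out <- out + choose(T_mem, k) * (p * phi)^k *
      (1 - p * phi)^(T_mem - k) * P[k]
  out
}

# Brute-force real-root finder for xi^3 - c_ext*xi - c_int = 0, used as
# the independent oracle: sign changes on a dense grid + uniroot.
brute_roots <- function(c_ext, c_int) {
  f <- function(x) x^3 - c_ext * x - c_int
  bound <- 1 + max(abs(c_ext), abs(c_int))  # Cauchy bound
  xs <- seq(-bound, bound, length.out = 4001)
  ys <- f(xs)
  roots <- xs[ys == 0]
  idx <- which(ys[-1] * ys[-length(ys)] < 0)
  for (i in idx)
    roots <- c(roots, stats::uniroot(f, c(xs[i], xs[i + 1]),
                                     tol = 1e-12)$root)
  sort(roots)
}

# exhaustive cobweb iteration of the oracle map from dense initial points
oracle_fixed_points <- function(p, P, n_starts = 1e4, iters = 2000,
                                dedup = 1e-5) {
  phi <- seq(0, 1, length.out = n_starts)
  for (i in seq_len(iters)) {
    nxt <- oracle_map(phi, p, P)
    if (max(abs(nxt - phi)) < 1e-12) break
    phi <- nxt
  }
  sort(unique(round(phi / dedup) * dedup))
}
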