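# Shared fixtures for the test suite.  Everything is generated in code;
# seeds are fixed per test for reproducibility.

sig_varied <- function() cue_sigmas(7, 6, 3)
sig_equal <- function() cue_sigmas(4, 4, 4)
sig_exceptional <- function() cue_sigmas(8, 8, 2)

# Small MCS design (the standard small-disk set) with adjustable budget.
quick_design <- function(trials_per_level = 20L, ...)
  experiment_design(trials_per_level = trials_per_level, ...)

quick_conflict_design <- function(trials_per_level = 20L, ...)
  conflict_design(trials_per_level = trials_per_level, ...)

# Random positive sigma triplets for property-style loops.
random_sigmas <- function(n, lo = 0.5, hi = 12) {
  replicate(n, cue_sigmas(runif(1, lo, hi), runif(1, lo, hi),
                          runif(1, lo, hi)),
            simplify = FALSE)
}

# Brute-force binomial likelihood oracle, coded independently of
# condition_likelihood(): direct product over levels on the natural scale.
oracle_likelihood <- function(data, sigma_psy, mu = 0) {
  out <- 1
  for (i in seq_len(nrow(data))) {
    p <- pnorm((data$delta[i] - mu) / sigma_psy)
    out <- out * p^data$k[i] * (1 - p)^(data$n[i] - data$k[i])
  }
  out
}

# Condition data simulated directly from the closed-form 2IFC probability
# (independent of run_experiment's percept machinery).
closed_form_data <- function(deltas, n_per, sigma_single, mu = 0) {
  p <- pnorm((deltas - mu) / (sqrt(2) * sigma_single))
  condition_data(deltas, rbinom(length(deltas), n_per, p), rep(n_per,
                                                               length(deltas)))
}

expect_prob_vector <- function(p, tol = 1e-10) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = tol)
}
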