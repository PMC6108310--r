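# Shared fixtures, built once per test run. Everything is generated in
# code; seeds are fixed constants.

std_stimuli <- exp1_stimulus_set()

std_drift_map <- function(k = 8, s0 = 0.5, mu_ext = 2.6) {
  drift_map_reduced(k, s0, -mu_ext, mu_ext, std_stimuli)
}

std_params <- function(B = 1, dB = 0, T0 = 0.3, ...) {
  ddm_params(bound_mean = B, bound_offset = dB, nd_mean = T0,
             drift = std_drift_map(...))
}

# small multi-purpose simulated table: 11 stimuli x 120 trials
std_table_small <- simulate_trials(std_params(), std_stimuli, 120,
                                   seed = 901, condition = "unadapted")

# pooled-scale table (6,600 trials) with asymmetric bounds, used by the
# heavier fitting tests
std_table_asym <- simulate_trials(std_params(dB = 0.1), std_stimuli, 600,
                                  seed = 902, condition = "unadapted")

# Bernoulli draws from the simple logistic model (fast psychometric data)
logistic_table <- function(beta0, beta1, n_per_stim, seed,
                           strengths = std_stimuli$strengths,
                           condition = "unadapted", subject_id = "s1") {
  old <- adaptddm:::local_seed(seed)
  on.exit(adaptddm:::restore_seed(old))
  rows <- lapply(strengths, function(s) {
    p <- stats::plogis(beta0 * (s + beta1))
    data.frame(subject_id = subject_id, condition = condition,
               stimulus_strength = s,
               choice = ifelse(stats::rbinom(n_per_stim, 1, p) == 1,
                               "sad", "happy"),
               rt = 1)
  })
  trial_table(do.call(rbind, rows))
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", x, tol, target))
}
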