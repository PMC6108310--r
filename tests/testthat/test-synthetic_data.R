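test_that("simulation is deterministic, bit-for-bit after serialization", {
  a <- simulate_trials(std_params(), std_stimuli, 30, seed = 101)
  b <- simulate_trials(std_params(), std_stimuli, 30, seed = 101)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_trials(a, fa); write_trials(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  c_ <- simulate_trials(std_params(), std_stimuli, 30, seed = 102)
  expect_false(identical(a$trials$rt, c_$trials$rt))
})

test_that("simulated choices and RTs match the closed forms (n = 20,000)", {
  one <- stimulus_set(c(0, 0.5, 1))
  dm <- drift_map_per_stimulus(c(0, 0.5, 1), c(-1, 0, 1))
  p <- ddm_params(1, 0, 0.3, drift = dm)
  tab <- simulate_trials(p, one, 20000, seed = 103)
  cs <- summarize_cells(tab)
  # drift 0, symmetric bounds: sad fraction within 3 binomial SEs of 0.5
  expect_within(cs$p_sad[cs$stimulus_strength == 0.5], 0.5,
                3 * sqrt(0.25 / 20000))
  # drift 1: Eq-3 fraction ~0.8808 and Eq-4 mean RT ~1.0616 at T0 = 0.3
  p_th <- choice_prob_analytic(1, 1, 0)
  i <- which(cs$stimulus_strength == 1)
  expect_within(cs$p_sad[i], p_th, 3 * sqrt(p_th * (1 - p_th) / 20000))
  expect_within(cs$mean_rt[i], mean_rt_analytic(1, 1, 0, 0.3),
                3 * sqrt(cs$var_rt[i] / 20000))
})

test_that("halving the simulation step leaves choice fractions in place", {
  one <- stimulus_set(c(0.25, 0.5, 0.75))
  dm <- drift_map_per_stimulus(c(0.25, 0.5, 0.75), c(-1, 0.5, 2))
  p <- ddm_params(1, 0.15, 0.3, drift = dm)
  coarse <- simulate_trials(p, one, 20000, seed = 104, dt_sim = 5e-4)
  fine <- simulate_trials(p, one, 20000, seed = 105, dt_sim = 2.5e-4)
  pc <- summarize_cells(coarse)$p_sad
  pf <- summarize_cells(fine)$p_sad
  # independent draws: difference within 3 * sqrt(2) * MC SE
  se <- sqrt(pc * (1 - pc) / 20000)
  expect_true(all(abs(pc - pf) < 3 * sqrt(2) * se + 1e-9))
})

test_that("make_experiment: null effects leave conditions exchangeable", {
  subs <- default_subject_specs(1, seed = 106,
                                effects = list(drift_shift = 0,
                                               bound_scale = 1,
                                               bound_offset = 0,
                                               nd_change = 0),
                                between_subject = FALSE)
  sim <- make_experiment(experiment_design("fixed_range",
                                           n_per_stimulus = 60),
                         subs, master_seed = 107)
  tab <- sim$tables[[1]]
  f <- lapply(c("unadapted", "happy_adapted", "sad_adapted"),
              function(cn) fit_simple_logistic(tab, cn, n_boot = 100,
                                               seed = 108))
  pses <- vapply(f, `[[`, 0, "pse")
  ses <- vapply(f, `[[`, 0, "se_pse")
  expect_lt(max(pses) - min(pses), 3 * sqrt(sum(ses^2)))
})

test_that("make_experiment: drift shift toward sad lowers the pooled PSE", {
  subs <- default_subject_specs(6, seed = 109,
                                effects = list(drift_shift = 0.32,
                                               bound_scale = 1,
                                               bound_offset = 0,
                                               nd_change = 0))
  sim <- make_experiment(experiment_design("fixed_range",
                                           n_per_stimulus = 35),
                         subs, master_seed = 110)
  pooled <- pool_participants(sim$tables)
  f_un <- fit_simple_logistic(pooled, "unadapted")
  f_ha <- fit_simple_logistic(pooled, "happy_adapted")
  expect_lt(f_ha$pse, f_un$pse)
  # manifest carries the generating truth
  man <- sim$manifest$subjects[[1]]
  expect_equal(man$unadapted$params$bound_mean,
               subs[[1]]$params$unadapted$bound_mean)
})

test_that("balanced designs recentre each subject near 50% sad", {
  subs <- default_subject_specs(3, seed = 111)
  sim <- make_experiment(experiment_design("balanced",
                                           n_per_stimulus = 100),
                         subs, master_seed = 112)
  for (tab in sim$tables) {
    frac <- tapply(tab$trials$choice == "sad", tab$trials$condition, mean)
    expect_true(all(frac > 0.45 & frac < 0.55),
                label = paste("sad fractions", paste(round(frac, 3),
                                                     collapse = "/")))
  }
})

test_that("balanced_stimulus_selection recentres on the model PSE", {
  sym <- std_params()                               # PSE exactly 0.5
  base <- stimulus_set(c(0.125, seq(0.4, 0.6, by = 0.05), 0.875))
  expect_equal(balanced_stimulus_selection(sym, base)$strengths,
               base$strengths, tolerance = 1e-7)

  shifted <- std_params(s0 = 0.55)                  # zero-crossing 0.55
  centered <- stimulus_set(c(0.125, seq(0.4, 0.6, by = 0.025), 0.875))
  out <- balanced_stimulus_selection(shifted, centered)
  expect_equal(out$strengths[2:10], centered$strengths[2:10] + 0.05,
               tolerance = 1e-6)
  expect_equal(out$strengths[c(1, 11)], c(0.125, 0.875))

  # dB > 0 lowers the sad bound: the 0.5-crossing moves below 0.5
  asym <- std_params(dB = 0.2)
  out2 <- balanced_stimulus_selection(asym, std_stimuli)
  expect_lt(mean(out2$strengths[2:10]), 0.475)
})
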