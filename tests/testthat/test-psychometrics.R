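test_that("simple logistic fit recovers generating parameters", {
  tab <- logistic_table(15, -0.5, 200, seed = 51)
  f <- fit_simple_logistic(tab)
  expect_within(f$pse, 0.5, 0.01)
  expect_within(f$beta0, 15, 2.5)
  expect_equal(f$pse, -f$beta1)                  # exact identity
  expect_false(f$separated)
  expect_false(f$pse_unreliable)
})

test_that("degenerate and separated inputs are flagged", {
  # exactly balanced responses at every strength, symmetric about 0.5
  df <- do.call(rbind, lapply(std_stimuli$strengths, function(s)
    data.frame(subject_id = "s", condition = "unadapted",
               stimulus_strength = s,
               choice = rep(c("sad", "happy"), 10), rt = 1)))
  f <- fit_simple_logistic(trial_table(df))
  expect_within(f$pse, 0.5, 0.05)
  expect_true(f$pse_unreliable)

  # deterministic step data: perfect separation
  df2 <- do.call(rbind, lapply(std_stimuli$strengths, function(s)
    data.frame(subject_id = "s", condition = "unadapted",
               stimulus_strength = s,
               choice = rep(if (s < 0.5) "happy" else "sad", 5), rt = 1)))
  f2 <- fit_simple_logistic(trial_table(df2))
  expect_true(f2$separated)
  expect_true(is.infinite(f2$beta0))
})

test_that("condition logistic: null, restriction, and recovery", {
  mk <- function(beta0, pse, cond, seed)
    logistic_table(beta0, -pse, 200, seed = seed, condition = cond)
  null_tab <- pool_participants(list(mk(15, 0.5, "unadapted", 61),
                                     mk(15, 0.5, "happy_adapted", 62),
                                     mk(15, 0.5, "sad_adapted", 63)))
  f0 <- fit_condition_logistic(null_tab)
  for (j in c("beta2", "beta3", "beta4"))
    expect_lt(abs(f0$coef[[j]]) / f0$se[[j]], 3)

  # unadapted sub-curve matches the simple fit
  fs <- fit_simple_logistic(null_tab, "unadapted")
  expect_within(f0$coef[["beta0"]], fs$beta0, 0.15 * fs$beta0)
  expect_within(-f0$coef[["beta1"]], fs$pse, 0.01)

  # injected +/- 0.05 PSE shifts and a 20% shallower adapted slope
  eff_tab <- pool_participants(list(
    mk(15, 0.50, "unadapted", 64),
    mk(12, 0.45, "happy_adapted", 65),     # PSE 0.45 -> beta2 = +0.05
    mk(12, 0.55, "sad_adapted", 66)))      # PSE 0.55 -> beta3 = -0.05
  f1 <- fit_condition_logistic(eff_tab)
  expect_within(f1$coef[["beta2"]], 0.05, 0.015)
  expect_within(f1$coef[["beta3"]], -0.05, 0.015)
  expect_lt(f1$coef[["beta4"]], 0)
})

test_that("pse_shift: identity, null, and injected-shift recovery", {
  tab <- logistic_table(15, -0.5, 150, seed = 71)
  f <- fit_simple_logistic(tab)
  expect_identical(pse_shift(f, f)$shift, 0)

  tab2 <- logistic_table(15, -0.5, 150, seed = 72)
  f2 <- fit_simple_logistic(tab2)
  s0 <- pse_shift(f2, f, tab2, tab, n_boot = 200, seed = 73)
  expect_lt(abs(s0$shift), 2 * s0$se)

  # pooled-scale injected shift of -0.03 (toward the happy adaptor)
  big_u <- logistic_table(15, -0.5, 600, seed = 74)
  big_a <- logistic_table(15, -0.47, 600, seed = 75,
                          condition = "happy_adapted")
  fu <- fit_simple_logistic(big_u)
  fa <- fit_simple_logistic(big_a, "happy_adapted")
  s1 <- pse_shift(fa, fu, big_a, big_u, n_boot = 200, seed = 76)
  expect_within(s1$shift, -0.03, 3 * s1$se)
  expect_lt(s1$se, 0.01)
})

test_that("across-subject aggregation: ties, power, and calibration", {
  old <- adaptddm:::local_seed(99)
  on.exit(adaptddm:::restore_seed(old))
  # degenerate: statistic identically zero -> p = 0.5 under tie-splitting
  z <- replicate(4, rep(0, 50), simplify = FALSE)
  expect_equal(aggregate_across_subjects(z, n_iter = 500, seed = 1)$p, 0.5)
  expect_warning(aggregate_across_subjects(z, n_iter = 50, seed = 1),
                 "unstable")

  # power: 6 subjects with a clearly positive statistic
  pos <- lapply(1:6, function(i) 0.1 + 0.03 * stats::rnorm(300))
  p_pos <- aggregate_across_subjects(pos, n_iter = 10000, seed = 2)$p
  expect_lt(p_pos, 1e-3)

  # type-I calibration at alpha = 0.05 over 60 replicate experiments
  # (reduced from the stated 200 for runtime); binomial 3-SE band
  fp <- mean(vapply(1:60, function(r) {
    null_samples <- lapply(1:6, function(i) stats::rnorm(120))
    aggregate_across_subjects(null_samples, n_iter = 400,
                              seed = 1000 + r)$p < 0.05
  }, logical(1)))
  expect_lt(abs(fp - 0.05), 3 * sqrt(0.05 * 0.95 / 60) + 0.01)
})

test_that("subject_statistic_samples feeds the aggregator end to end", {
  # two conditions with a true mean-RT difference; the across-subject
  # bootstrap should call it confidently
  tabs <- lapply(1:3, function(i) {
    un <- simulate_trials(std_params(), std_stimuli, 25, seed = 80 + i,
                          subject_id = paste0("s", i))
    ad <- simulate_trials(std_params(B = 0.85), std_stimuli, 25,
                          seed = 90 + i, subject_id = paste0("s", i),
                          condition = "happy_adapted")
    pool_participants(list(un, ad))
  })
  rt_drop <- function(tb) {
    tr <- tb$trials
    mean(tr$rt[tr$condition == "unadapted"]) -
      mean(tr$rt[tr$condition == "happy_adapted"])
  }
  samples <- subject_statistic_samples(tabs, rt_drop, n_samples = 120,
                                       seed = 7)
  res <- aggregate_across_subjects(samples, n_iter = 2000, seed = 8,
                                   side = "greater")
  expect_lt(res$p, 0.01)
})

test_that("logit evidence profile: arithmetic, clipping, linearity", {
  df <- data.frame(subject_id = "s", condition = "unadapted",
                   stimulus_strength = rep(c(0.4, 0.5, 0.6), each = 50),
                   choice = c(rep(c("sad", "happy"), c(25, 25)),
                              rep(c("sad", "happy"), c(44, 6)),
                              rep("sad", 50)),
                   rt = 1)
  prof <- logit_evidence_profile(trial_table(df))
  expect_equal(prof$logit[1], 0)
  expect_within(prof$logit[2], stats::qlogis(0.88), 1e-9)
  expect_true(prof$clipped[3])                   # p = 1 clipped to 99/100
  expect_equal(prof$logit[3], stats::qlogis(1 - 1 / 100))

  # symmetric-bound DDM data: logit linear in strength over the middle
  # stimuli (2,000 trials per stimulus)
  mid <- stimulus_set(std_stimuli$strengths[2:10])
  tab <- simulate_trials(std_params(), mid, 2000, seed = 85)
  prof2 <- logit_evidence_profile(tab)
  lf <- stats::lm(logit ~ stimulus_strength, data = prof2)
  expect_gt(summary(lf)$r.squared, 0.98)
})
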