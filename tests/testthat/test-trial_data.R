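test_that("trial tables round-trip through CSV and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(std_table_small, path)
  back <- load_trials(path, experiment_id = std_table_small$experiment_id)
  expect_equal(back$trials$choice, std_table_small$trials$choice)
  expect_equal(back$trials$rt, std_table_small$trials$rt, tolerance = 1e-12)
  expect_equal(back$trials$stimulus_strength,
               std_table_small$trials$stimulus_strength)

  writeLines(c("subject_id,condition,stimulus_strength,choice,rt",
               "s1,unadapted,0.5,sad,0.8",
               "s1,unadapted,0.5,happy,-0.2",
               "s1,unadapted,1.5,sad,0.9"), path)
  expect_error(load_trials(path), "row 2")
  expect_error(load_trials(path), "row 3")

  writeLines(c("subject_id,condition,strength,choice,rt",
               "s1,unadapted,0.5,sad,0.8"), path)
  expect_error(load_trials(path), "missing column")
})

test_that("outlier filter applies the 5-s cut, reports, and is idempotent", {
  df <- data.frame(subject_id = "s1", condition = "unadapted",
                   stimulus_strength = 0.5,
                   choice = c("sad", "happy", "sad"),
                   rt = c(0.6, 1.2, 5.5))
  tab <- trial_table(df)
  out <- filter_outliers(tab)
  expect_equal(nrow(out$trials), 2L)
  rep <- attr(out, "removal_report")
  expect_equal(rep$fraction_removed, 1 / 3)

  fast <- filter_outliers(std_table_small)      # drop any slow tails first
  unchanged <- filter_outliers(fast)
  expect_equal(unchanged$trials, fast$trials)
  expect_equal(attr(unchanged, "removal_report")$fraction_removed, 0)

  twice <- filter_outliers(filter_outliers(tab))
  expect_equal(twice$trials, out$trials)

  all_slow <- trial_table(transform(df, rt = rt + 10))
  expect_error(filter_outliers(all_slow), "all trials removed")
})

test_that("simulated removal fraction at realistic parameters is tiny", {
  # generous drift/bound config: almost no first passages beyond 5 s
  tab <- simulate_trials(std_params(), std_stimuli, 900, seed = 11)
  out <- filter_outliers(tab)
  rep <- attr(out, "removal_report")
  expect_lt(rep$n_removed / rep$n_before, 0.01)
})

test_that("pooling concatenates and preserves per-cell counts", {
  t1 <- trial_table(std_table_small$trials[1:5, ], "e")
  t2 <- trial_table(std_table_small$trials[6:12, ], "e")
  expect_equal(nrow(pool_participants(list(t1, t2))$trials), 12L)
  expect_equal(pool_participants(list(t1))$trials, t1$trials)

  t2$experiment_id <- "other"
  expect_error(pool_participants(list(t1, t2)), "across experiments")

  tabs <- lapply(1:3, function(i) {
    tb <- std_table_small
    tb$trials$subject_id <- paste0("s", i)
    tb
  })
  counts <- function(tt) table(tt$trials$condition,
                               tt$trials$stimulus_strength)
  p1 <- pool_participants(tabs)
  p2 <- pool_participants(rev(tabs))
  expect_equal(counts(p1), counts(p2))           # order-invariant counts
  expect_equal(as.vector(counts(p1)),
               3L * as.vector(counts(tabs[[1]])))
})

test_that("align_and_bin: single subject is binning only", {
  tab <- logistic_table(15, -0.5, 40, seed = 21)
  out <- align_and_bin(list(tab), n_bins = 19)
  expect_lte(length(unique(out$trials$stimulus_strength)), 19L)
  rep <- attr(out, "bin_report")
  # one subject: every non-empty bin passes the drop rule
  expect_true(all(rep$kept[rep$n_trials > 0]))
  expect_equal(nrow(out$trials), sum(rep$n_trials[rep$kept]))
  # with one subject the shift is zero: shifted strengths span the raw set
  expect_equal(min(rep$lo), min(tab$trials$stimulus_strength))
  expect_equal(max(rep$hi), max(tab$trials$stimulus_strength))
})

test_that("align_and_bin removes a known between-subject PSE offset", {
  # two subjects with true PSEs 0.45 / 0.55
  t1 <- logistic_table(15, -0.45, 150, seed = 31, subject_id = "a")
  t2 <- logistic_table(15, -0.55, 150, seed = 32, subject_id = "b")
  out <- align_and_bin(list(t1, t2), n_bins = 19,
                       min_participant_fraction = 0)
  f <- fit_simple_logistic(out, n_boot = 100, seed = 33)
  expect_within(f$pse, 0.5, 3 * f$se_pse + 0.01)
  # slope survives alignment (between-subject PSE variance removed)
  f1 <- fit_simple_logistic(t1)
  expect_within(f$beta0, f1$beta0, 0.35 * f1$beta0)
})

test_that("the two-thirds drop rule fires on recentred per-subject sets", {
  # 6 subjects whose stimulus sets are recentred on well-separated PSEs
  tabs <- lapply(1:6, function(i) {
    pse <- 0.35 + 0.06 * i
    logistic_table(15, -pse, 40, seed = 40 + i,
                   strengths = pmin(1, pmax(0, std_stimuli$strengths +
                                              (pse - 0.475))),
                   subject_id = paste0("s", i))
  })
  out <- align_and_bin(tabs, n_bins = 19)
  rep <- attr(out, "bin_report")
  expect_true(any(!rep$kept))                    # some bins dropped
  expect_true(all(rep$n_subjects[rep$kept] >= 4))  # ceil(2/3 * 6) = 4
})
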