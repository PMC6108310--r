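#' Simulate drift-diffusion trials
#'
#' Euler-Maruyama simulation (step `dt_sim`, default 0.5 ms, with the
#' Broadie-Glasserman-Kou barrier continuity correction) of a unit-variance
#' evidence process between the two absorbing bounds of `params`, one cell
#' per stimulus. The upper bound yields a sad choice, the lower a happy
#' choice; response time is the first-passage time plus a Gaussian
#' nondecision draw (mean `nd_mean`, SD `nd_sd`), redrawn while
#' non-positive. Fully reproducible from `seed`.
#'
#' @param params a [ddm_params].
#' @param stimuli a [stimulus_set].
#' @param n_per_stimulus trials per stimulus (>= 1).
#' @param seed RNG seed.
#' @param subject_id,condition,experiment_id labels for the output table.
#' @param dt_sim simulation step in seconds.
#' @return a [trial_table].
#' @export
simulate_trials <- function(params, stimuli, n_per_stimulus, seed = 1L,
                            subject_id = "s1", condition = "unadapted",
                            experiment_id = "sim", dt_sim = 5e-4) {
  stopifnot(inherits(params, "ddm_params"), inherits(stimuli, "stimulus_set"),
            n_per_stimulus >= 1L)
  check_bounds(params$bound_mean, params$bound_offset)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  a <- bound_happy(params)
  b <- bound_sad(params)
  rows <- lapply(stimuli$strengths, function(s) {
    mu <- drift_at(params$drift, s)
    sim <- ddm_passage_cpp(n_per_stimulus, mu, a, b, dt_sim, 60)
    nd <- stats::rnorm(n_per_stimulus, params$nd_mean, params$nd_sd)
    bad <- which(nd <= 0)
    while (length(bad)) {                      # resample non-positive draws
      nd[bad] <- stats::rnorm(length(bad), params$nd_mean, params$nd_sd)
      bad <- which(nd <= 0)
    }
    data.frame(subject_id = subject_id, condition = condition,
               stimulus_strength = s,
               choice = ifelse(sim$choice == 1L, "sad", "happy"),
               rt = sim$dtime + nd)
  })
  trial_table(do.call(rbind, rows), experiment_id = experiment_id,
              provenance = sprintf(
                "simulated: %s/%s, %d trials/stimulus, seed %d",
                subject_id, condition, n_per_stimulus, seed))
}

#' Per-subject generative specification
#'
#' @param subject_id opaque label.
#' @param params_by_condition named list with a [ddm_params] for each of
#'   `unadapted`, `happy_adapted`, `sad_adapted`.
#' @param seed subject-level RNG seed.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, params_by_condition, seed) {
  if (!setequal(names(params_by_condition), CONDITIONS))
    stop("params_by_condition must name exactly the three conditions")
  stopifnot(all(vapply(params_by_condition, inherits, TRUE, "ddm_params")))
  structure(list(subject_id = subject_id,
                 params = params_by_condition[CONDITIONS],
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Experiment design
#'
#' @param kind `"fixed_range"` (one shared stimulus set) or `"balanced"`
#'   (per-subject, per-condition sets recentred on the model-implied PSE).
#' @param stimuli base [stimulus_set].
#' @param n_per_stimulus repeats per stimulus per condition (default 100,
#'   i.e. ~1100 trials per condition with the 11-level set).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(kind = c("fixed_range", "balanced"),
                              stimuli = exp1_stimulus_set(),
                              n_per_stimulus = 100L) {
  kind <- match.arg(kind)
  stopifnot(inherits(stimuli, "stimulus_set"), n_per_stimulus >= 1L)
  structure(list(kind = kind, stimuli = stimuli,
                 n_per_stimulus = as.integer(n_per_stimulus)),
            class = "experiment_design")
}

# model-implied PSE: root of P(sad) = 0.5 over the linear drift rule
model_pse <- function(params) {
  f <- function(s) {
    mu <- if (params$drift$kind == "reduced")
      params$drift$k * (s - params$drift$s0)
    else stats::approx(params$drift$strengths, params$drift$drifts,
                       xout = s, rule = 2)$y
    choice_prob_analytic(mu, params$bound_mean, params$bound_offset) - 0.5
  }
  if (f(0) * f(1) > 0) stop("model-implied PSE outside [0, 1]; ",
                            "degenerate parameters")
  stats::uniroot(f, c(0, 1), tol = 1e-9)$root
}

#' Recentre the middle stimuli on the model-implied PSE
#'
#' Emulates the balanced-response calibration: the middle members of
#' `base_set` are translated so their center (mean) sits at the stimulus
#' strength where the closed-form choice probability is 0.5; the extremes
#' are kept; everything is clipped to \[0, 1\].
#'
#' @param params a [ddm_params].
#' @param base_set the base [stimulus_set].
#' @return a recentred [stimulus_set].
#' @export
balanced_stimulus_selection <- function(params, base_set) {
  stopifnot(inherits(base_set, "stimulus_set"))
  pse <- model_pse(params)
  s <- base_set$strengths
  n <- length(s)
  mid <- s[-c(1L, n)]
  shift <- pse - mean(mid)
  stimulus_set(c(s[1L], pmin(1, pmax(0, mid + shift)), s[n]))
}

#' Generate a full multi-subject experiment
#'
#' One trial table per subject covering the three adaptation conditions,
#' plus a ground-truth manifest of every generating parameter (for
#' parameter-recovery studies). For a `"balanced"` design each subject's
#' middle stimuli are recentred per condition via
#' [balanced_stimulus_selection()].
#'
#' @param design an [experiment_design].
#' @param subjects list of [subject_spec]s.
#' @param master_seed integer; per-(subject, condition) seeds are derived
#'   from it (kept below 2^31).
#' @param experiment_id label for all tables.
#' @return list with `tables` (one [trial_table] per subject) and
#'   `manifest` (generating parameters, stimulus sets and seeds).
#' @export
make_experiment <- function(design, subjects, master_seed = 1L,
                            experiment_id = "sim_exp") {
  stopifnot(inherits(design, "experiment_design"),
            all(vapply(subjects, inherits, TRUE, "subject_spec")))
  tables <- list()
  manifest <- list(design_kind = design$kind,
                   n_per_stimulus = design$n_per_stimulus,
                   master_seed = master_seed, subjects = list())
  for (i in seq_along(subjects)) {
    sp <- subjects[[i]]
    cond_tabs <- list()
    man_cond <- list()
    for (j in seq_along(CONDITIONS)) {
      cond <- CONDITIONS[j]
      p <- sp$params[[cond]]
      stim <- if (design$kind == "balanced")
        balanced_stimulus_selection(p, design$stimuli) else design$stimuli
      seed_ij <- (master_seed + 7919L * i + 101L * j) %% .Machine$integer.max
      cond_tabs[[cond]] <- simulate_trials(
        p, stim, design$n_per_stimulus, seed = seed_ij,
        subject_id = sp$subject_id, condition = cond,
        experiment_id = experiment_id)
      man_cond[[cond]] <- list(params = p, stimuli = stim$strengths,
                               seed = seed_ij)
    }
    tab <- pool_participants(cond_tabs)
    tab$experiment_id <- experiment_id
    tables[[sp$subject_id]] <- tab
    manifest$subjects[[sp$subject_id]] <- man_cond
  }
  list(tables = tables, manifest = manifest)
}

#' Default generative world for adaptation experiments
#'
#' Builds subject specifications whose parameters emulate the scale of the
#' adaptation phenomena under study: a baseline observer with symmetric
#' bounds (mean height 1 evidence unit, nondecision 0.3 s, linear drift
#' slope 8 per strength unit crossing zero at 0.5, saturating extreme
#' drifts of magnitude 2.6), and adaptation effects of (a) a drift shift
#' toward the adaptor, (b) a multiplicative bound reduction of ~10%, and
#' (c) a bound offset that lowers the bound opposite the adaptor.
#' Between-subject variability is mild lognormal/Gaussian jitter.
#'
#' @param n_subjects number of subjects (default 6).
#' @param seed RNG seed for the between-subject jitter.
#' @param effects list of adaptation effect sizes: `drift_shift` (evidence
#'   units added toward the adaptor, default 0.16), `bound_scale`
#'   (multiplicative, default 0.9), `bound_offset` (evidence units,
#'   default 0.08; sign is handled per condition), `nd_change` (seconds,
#'   default -0.02).
#' @param between_subject logical: apply between-subject jitter
#'   (default TRUE).
#' @return list of [subject_spec]s.
#' @export
default_subject_specs <- function(n_subjects = 6L, seed = 42L,
                                  effects = list(), between_subject = TRUE) {
  eff <- utils::modifyList(list(drift_shift = 0.16, bound_scale = 0.9,
                                bound_offset = 0.08, nd_change = -0.02),
                           effects)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  stim <- exp1_stimulus_set()
  lapply(seq_len(n_subjects), function(i) {
    if (between_subject) {
      B <- exp(stats::rnorm(1, log(1), 0.08))
      k <- exp(stats::rnorm(1, log(8), 0.10))
      s0 <- stats::rnorm(1, 0.5, 0.03)
      T0 <- max(0.1, stats::rnorm(1, 0.3, 0.03))
    } else {
      B <- 1; k <- 8; s0 <- 0.5; T0 <- 0.3
    }
    mu_ext <- 2.6 * k / 8                     # saturating extremes
    base_drift <- function(shift) drift_map_reduced(
      k, s0 - shift / k, -mu_ext + shift, mu_ext + shift, stim)
    mk <- function(shift, scale, offset, dT0) ddm_params(
      bound_mean = B * scale, bound_offset = offset,
      nd_mean = max(0.05, T0 + dT0), drift = base_drift(shift))
    subject_spec(
      sprintf("s%02d", i),
      list(
        unadapted = mk(0, 1, 0, 0),
        # happy adaptor: stimuli look sadder (positive drift shift), the
        # sad bound (opposite the adaptor) drops -> positive offset
        happy_adapted = mk(eff$drift_shift, eff$bound_scale,
                           eff$bound_offset, eff$nd_change),
        sad_adapted = mk(-eff$drift_shift, eff$bound_scale,
                         -eff$bound_offset, eff$nd_change)),
      seed = 1000L + i)
  })
}
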