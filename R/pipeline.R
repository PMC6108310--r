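#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: simulation design,
#' effect sizes, seeds, fitting method and grid, bootstrap counts, and an
#' optional output directory. Fully serializable to JSON; a run's config
#' is embedded in the report bundle.
#'
#' @param seed master seed for every source of randomness.
#' @param n_subjects subjects to simulate.
#' @param design_kind `"fixed_range"` or `"balanced"`.
#' @param n_per_stimulus repeats per stimulus per condition.
#' @param effects adaptation effect sizes (see [default_subject_specs()]).
#' @param fit_method `"analytic"` (fast closed-form fit) or `"fpe"`
#'   (full-likelihood fit).
#' @param grid_n_v,grid_dt Fokker-Planck grid settings for `"fpe"` fits.
#' @param n_boot_pse bootstrap resamples for PSE-shift SEs.
#' @param max_rt outlier threshold in seconds.
#' @param out_dir optional directory; when given, tables and fit records
#'   are written there as delimited text/JSON.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 6L,
                            design_kind = "fixed_range",
                            n_per_stimulus = 100L, effects = list(),
                            fit_method = c("analytic", "fpe"),
                            grid_n_v = 120L, grid_dt = 2e-3,
                            n_boot_pse = 200L, max_rt = 5.0,
                            out_dir = NULL) {
  fit_method <- match.arg(fit_method)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 design_kind = design_kind,
                 n_per_stimulus = as.integer(n_per_stimulus),
                 effects = effects, fit_method = fit_method,
                 grid_n_v = as.integer(grid_n_v), grid_dt = grid_dt,
                 n_boot_pse = as.integer(n_boot_pse), max_rt = max_rt,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#' @param config a [pipeline_config].
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, TRUE)])
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> outlier filter -> pool (or align-and-bin for
#' balanced designs) -> psychometrics (per-condition logistic fits, PSE
#' shifts, condition logistic) -> decision-model fits per condition ->
#' contribution partition -> summary tables. Deterministic given the
#' config seed.
#'
#' @param config a [pipeline_config].
#' @return a report bundle (list) with the pooled table, per-condition
#'   psychometric and chronometric summaries, fit records, PSE shifts,
#'   contribution partitions, the ground-truth manifest, and the config.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- default_subject_specs(config$n_subjects,
                                    seed = config$seed + 1L,
                                    effects = config$effects)
  design <- experiment_design(config$design_kind,
                              n_per_stimulus = config$n_per_stimulus)
  sim <- make_experiment(design, subjects, master_seed = config$seed)
  filtered <- lapply(sim$tables, filter_outliers, max_rt = config$max_rt)
  pooled <- if (config$design_kind == "balanced")
    align_and_bin(filtered) else pool_participants(filtered)

  fits_psy <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cn)
    fit_simple_logistic(pooled, cn))
  cond_fit <- fit_condition_logistic(pooled)
  sub_tab <- function(cn) {
    tr <- pooled$trials
    tb <- pooled
    tb$trials <- tr[tr$condition == cn, , drop = FALSE]
    tb
  }
  shifts <- lapply(stats::setNames(c("happy_adapted", "sad_adapted"),
                                   c("happy_adapted", "sad_adapted")),
                   function(cn)
    pse_shift(fits_psy[[cn]], fits_psy$unadapted, sub_tab(cn),
              sub_tab("unadapted"), n_boot = config$n_boot_pse,
              seed = config$seed + 2L))

  cells <- summarize_cells(pooled)
  fits_ddm <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cn) {
    if (config$fit_method == "fpe") {
      fit_reduced_model(sub_tab(cn),
                        grid = fpe_grid(config$grid_n_v, config$grid_dt),
                        n_starts = 2L, seed = config$seed + 3L)
    } else {
      fit_highparam_model(cells[cells$condition == cn, , drop = FALSE],
                          n_starts = 5L, seed = config$seed + 3L)
    }
  })

  stim <- exp1_stimulus_set()
  partitions <- lapply(stats::setNames(c("happy_adapted", "sad_adapted"),
                                       c("happy_adapted", "sad_adapted")),
                       function(cn)
    partition_shift(fits_ddm$unadapted$params, fits_ddm[[cn]]$params, stim))

  # observed psychometric points with model-predicted overlays
  psychometric <- cells
  psychometric$p_model <- vapply(seq_len(nrow(cells)), function(i) {
    f <- fits_ddm[[cells$condition[i]]]$params
    choice_prob_analytic(drift_at(f$drift, cells$stimulus_strength[i]),
                         f$bound_mean, f$bound_offset)
  }, numeric(1))
  psychometric$rt_model <- vapply(seq_len(nrow(cells)), function(i) {
    f <- fits_ddm[[cells$condition[i]]]$params
    mean_rt_analytic(drift_at(f$drift, cells$stimulus_strength[i]),
                     f$bound_mean, f$bound_offset, f$nd_mean)
  }, numeric(1))

  chrono <- chronometric_table(pooled, min_trials_per_choice = 10L)
  bundle <- list(config = config, pooled = pooled, cells = cells,
                 psychometric = psychometric,
                 psychometric_fits = fits_psy, condition_fit = cond_fit,
                 pse_shifts = shifts, ddm_fits = fits_ddm,
                 partitions = partitions, chronometric = chrono,
                 manifest = sim$manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# mean RT vs strength per condition, overall and split by choice
# (choice-split cells below the trial floor are suppressed as too noisy)
chronometric_table <- function(table, min_trials_per_choice = 10L) {
  tr <- table$trials
  agg <- stats::aggregate(rt ~ condition + stimulus_strength, data = tr,
                          FUN = mean)
  names(agg)[3L] <- "mean_rt"
  agg$n <- stats::aggregate(rt ~ condition + stimulus_strength, data = tr,
                            FUN = length)$rt
  by_choice <- stats::aggregate(rt ~ condition + stimulus_strength + choice,
                                data = tr, FUN = mean)
  nch <- stats::aggregate(rt ~ condition + stimulus_strength + choice,
                          data = tr, FUN = length)
  by_choice$n <- nch$rt
  by_choice <- by_choice[by_choice$n >= min_trials_per_choice, ,
                         drop = FALSE]
  list(overall = agg, by_choice = by_choice)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(bundle$pooled, file.path(dir, "pooled_trials.csv"))
  utils::write.csv(bundle$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$psychometric,
                   file.path(dir, "psychometric_with_model.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$chronometric$overall,
                   file.path(dir, "chronometric.csv"), row.names = FALSE)
  utils::write.csv(bundle$chronometric$by_choice,
                   file.path(dir, "chronometric_by_choice.csv"),
                   row.names = FALSE)
  for (cn in names(bundle$ddm_fits))
    write_ddm_params(bundle$ddm_fits[[cn]]$params,
                     file.path(dir, paste0("ddm_params_", cn, ".txt")))
  summ <- list(
    pse = lapply(bundle$psychometric_fits, function(f)
      list(pse = f$pse, beta0 = f$beta0)),
    pse_shifts = bundle$pse_shifts,
    condition_coefs = as.list(bundle$condition_fit$coef),
    partitions = lapply(bundle$partitions, unclass))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_pipeline_config(bundle$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write simulated per-subject trial CSVs),
#' `fit` (fit one condition of a trial CSV; `--method analytic|fpe`),
#' `partition` (partition the shift between two parameter files),
#' `report`/`all` (run the full pipeline and write the report bundle).
#' Typical use: `Rscript -e 'adaptddm::adaptddm_main()' all --seed 1
#' --out runs/demo`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
adaptddm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: adaptddm <simulate|fit|partition|report|all> [options]",
    "  simulate  --seed <i> --out <dir> [--subjects <n>] [--balanced]",
    "  fit       --trials <csv> --condition <c> --out <file>",
    "            [--method analytic|fpe]",
    "  partition --unadapted <params> --adapted <params> --out <file>",
    "  report|all --seed <i> --out <dir> [--method analytic|fpe]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- parse_cli_options(args[-1L])
  get_opt <- function(name, default = NULL) {
    if (!is.null(opt[[name]])) opt[[name]] else default
  }
  seed <- as.integer(get_opt("seed", 1L))
  switch(cmd,
    simulate = {
      out <- get_opt("out", "adaptddm_run")
      n_sub <- as.integer(get_opt("subjects", 6L))
      kind <- if (isTRUE(opt$balanced)) "balanced" else "fixed_range"
      sim <- make_experiment(experiment_design(kind),
                             default_subject_specs(n_sub, seed = seed + 1L),
                             master_seed = seed)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (sid in names(sim$tables))
        write_trials(sim$tables[[sid]],
                     file.path(out, paste0("trials_", sid, ".csv")))
      manifest_path <- file.path(out, "ground_truth.json")
      jsonlite::write_json(serialize_manifest(sim$manifest), manifest_path,
                           auto_unbox = TRUE, digits = NA)
      message("wrote ", length(sim$tables), " trial tables to ", out)
    },
    fit = {
      tab <- load_trials(get_opt("trials"))
      cond <- get_opt("condition", "unadapted")
      tr <- tab$trials
      tab$trials <- tr[tr$condition == cond, , drop = FALSE]
      method <- get_opt("method", "analytic")
      fit <- if (method == "fpe") fit_reduced_model(tab, seed = seed)
             else fit_highparam_model(summarize_cells(tab), seed = seed)
      write_ddm_params(fit$params, get_opt("out", "fit_params.txt"))
      message("loglik ", format(fit$loglik))
    },
    partition = {
      un <- read_ddm_params(get_opt("unadapted"))
      ad <- read_ddm_params(get_opt("adapted"))
      res <- partition_shift(un, ad, exp1_stimulus_set())
      jsonlite::write_json(unclass(res), get_opt("out", "partition.json"),
                           auto_unbox = TRUE, digits = NA)
      print(res)
    },
    report = ,
    all = {
      cfg <- pipeline_config(seed = seed,
                             fit_method = get_opt("method", "analytic"),
                             out_dir = get_opt("out", "adaptddm_run"))
      run_pipeline(cfg)
      message("report bundle written to ", cfg$out_dir)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}

parse_cli_options <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1L])) {
        opt[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opt[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opt
}

serialize_manifest <- function(manifest) {
  manifest$subjects <- lapply(manifest$subjects, function(sc)
    lapply(sc, function(cc) list(
      bound_mean = cc$params$bound_mean,
      bound_offset = cc$params$bound_offset,
      nd_mean = cc$params$nd_mean, nd_sd = cc$params$nd_sd,
      drift = cc$params$drift[c("kind", "k", "s0", "mu_low", "mu_high")],
      stimuli = cc$stimuli, seed = cc$seed)))
  manifest
}
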