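#' Discretization grid for the Fokker-Planck solver
#'
#' @param n_v number of evidence-grid intervals spanning the bound-to-bound
#'   range (grid spacing `dv = span / n_v`); default 200.
#' @param dt time step in seconds (default 1 ms).
#' @param t_max solve horizon in seconds. `NULL` (default) chooses the
#'   horizon automatically from the slowest decay eigenvalue of the
#'   bounded diffusion so that the predicted survivor mass falls below
#'   1e-5 (capped at 60 s). A fixed horizon is honoured and the solve is
#'   flagged truncated if the survivor mass at `t_max` exceeds
#'   `survivor_tol`.
#' @param survivor_tol survivor-mass tolerance (default 1e-4).
#' @return object of class `fpe_grid`.
#' @export
fpe_grid <- function(n_v = 200L, dt = 1e-3, t_max = NULL,
                     survivor_tol = 1e-4) {
  stopifnot(n_v >= 8L, dt > 0, is.null(t_max) || t_max > 0)
  structure(list(n_v = as.integer(n_v), dt = dt, t_max = t_max,
                 survivor_tol = survivor_tol),
            class = "fpe_grid")
}

auto_t_max <- function(mu, span) {
  lambda <- mu^2 / 2 + pi^2 / (2 * span^2)
  min(60, max(4, log(1e5) / lambda))
}

#' Solve the Fokker-Planck equation for the first-passage densities
#'
#' Crank-Nicolson integration of
#' `dp/dt = -mu dp/dv + 0.5 d2p/dv2` between absorbing bounds at
#' `-(B_bar + dB)` (happy) and `+(B_bar - dB)` (sad), delta start at 0.
#' Absorbed flux per step is the exact Crank-Nicolson mass balance split by
#' the one-sided probability currents at the two bound nodes, so total
#' absorbed mass plus survivor mass is 1 to machine precision.
#'
#' @param mu drift rate.
#' @param params a [ddm_params] (only the bounds are used).
#' @param grid an [fpe_grid].
#' @return object of class `first_passage_pdf`: time grid (bin midpoints),
#'   per-choice absorption densities, survivor trace, absorption
#'   probabilities, and a `truncated` flag.
#' @export
solve_fpe <- function(mu, params, grid = fpe_grid()) {
  stopifnot(inherits(params, "ddm_params"), inherits(grid, "fpe_grid"))
  a <- bound_happy(params)
  b <- bound_sad(params)
  check_bounds(params$bound_mean, params$bound_offset)
  t_max <- if (is.null(grid$t_max)) auto_t_max(mu, a + b) else grid$t_max
  sol <- fpe_solve_cpp(mu, a, b, grid$n_v, grid$dt, t_max)
  k <- sol$n_steps
  f_up <- sol$f_upper[seq_len(k)]
  f_lo <- sol$f_lower[seq_len(k)]
  surv <- sol$survivor[seq_len(k)]
  survivor_mass <- surv[k]
  truncated <- survivor_mass > grid$survivor_tol
  structure(list(
    time = (seq_len(k) - 0.5) * grid$dt, dt = grid$dt,
    upper = f_up / grid$dt, lower = f_lo / grid$dt,
    survivor = surv,
    p_upper = sum(f_up), p_lower = sum(f_lo),
    survivor_mass = survivor_mass, truncated = truncated,
    mu = mu, params = params),
    class = "first_passage_pdf")
}

#' @export
print.first_passage_pdf <- function(x, ...) {
  cat("first_passage_pdf: P(upper/sad) =", format(x$p_upper),
      " P(lower/happy) =", format(x$p_lower),
      " survivor =", format(x$survivor_mass),
      if (x$truncated) " [TRUNCATED]" else "", "\n")
  invisible(x)
}

#' Mean decision time implied by first-passage densities
#'
#' Unconditional mean of the absorption time (both bounds), normalized by
#' the absorbed mass.
#'
#' @param fp a [solve_fpe()] result.
#' @return mean decision time in seconds.
#' @export
fp_mean_time <- function(fp) {
  w <- (fp$upper + fp$lower) * fp$dt
  sum(fp$time * w) / sum(w)
}

#' Convolve first-passage densities with the nondecision distribution
#'
#' Response-time densities per choice: discrete convolution of the
#' first-passage densities with a Gaussian nondecision kernel truncated at
#' 0 and renormalized. When `nd_sd` is negligible relative to the time
#' step the kernel degenerates to a pure shift by `nd_mean`.
#'
#' @param fp a [solve_fpe()] result.
#' @param nd_mean mean nondecision time (s, > 0).
#' @param nd_sd SD of the nondecision time (s). Default `nd_mean / 3`.
#' @return object of class `rt_pdf` with fields `time`, `upper`, `lower`
#'   (densities per second; each integrates to the corresponding
#'   absorption probability).
#' @export
rt_density <- function(fp, nd_mean, nd_sd = nd_mean / 3) {
  stopifnot(inherits(fp, "first_passage_pdf"), nd_mean > 0, nd_sd >= 0)
  dt <- fp$dt
  if (nd_sd < dt / 10) {
    shift <- round(nd_mean / dt)
    return(structure(list(time = fp$time + shift * dt, dt = dt,
                          upper = fp$upper, lower = fp$lower,
                          p_upper = fp$p_upper, p_lower = fp$p_lower),
                     class = "rt_pdf"))
  }
  w <- nd_kernel(nd_mean, nd_sd, dt)
  up <- convolve_masses_cpp(fp$upper * dt, w) / dt
  lo <- convolve_masses_cpp(fp$lower * dt, w) / dt
  n_out <- length(up)
  # input masses sit at midpoints (j - 1/2) dt and kernel bins at
  # (i - 1/2) dt, so output element k = j + i - 1 sits at k * dt
  structure(list(time = seq_len(n_out) * dt, dt = dt,
                 upper = pmax(0, up), lower = pmax(0, lo),
                 p_upper = fp$p_upper, p_lower = fp$p_lower),
            class = "rt_pdf")
}

rt_pdf_mean <- function(rt) {
  w <- (rt$upper + rt$lower) * rt$dt
  sum(rt$time * w) / sum(w)
}

# Gaussian nondecision kernel: probability mass per dt bin, truncated at 0
# and renormalized; degenerates to a single tap when nd_sd << dt
nd_kernel <- function(nd_mean, nd_sd, dt) {
  if (nd_sd < dt / 10) {
    w <- numeric(max(1L, round(nd_mean / dt)))
    w[length(w)] <- 1
    return(w)
  }
  if (stats::pnorm(0, nd_mean, nd_sd) > 0.05)
    warning("more than 5% of the nondecision Gaussian lies below 0; ",
            "truncation distorts the kernel")
  edges <- seq(0, nd_mean + 6 * nd_sd + dt, by = dt)
  w <- diff(stats::pnorm(edges, nd_mean, nd_sd))
  w[w < 1e-14] <- 0
  w / sum(w)
}

#' Joint choice/response-time log-likelihood of a trial table
#'
#' For each distinct stimulus, solves the Fokker-Planck equation at its
#' drift rate, convolves with the nondecision distribution, and sums the
#' log of the per-trial (choice, rt) density, interpolated linearly on the
#' time grid and floored at 1e-10.
#'
#' @param params a [ddm_params].
#' @param table a [trial_table] for one condition.
#' @param grid an [fpe_grid].
#' @return log-likelihood (scalar) with attribute `n_truncated` counting
#'   trials whose rt fell beyond the solve horizon (each contributes the
#'   floor; a warning is raised if they exceed 1% of trials).
#' @export
loglik_trials <- function(params, table, grid = fpe_grid()) {
  stopifnot(inherits(table, "trial_table"))
  tr <- table$trials
  if (nrow(tr) == 0L) return(structure(0, n_truncated = 0L))
  ll <- 0
  n_trunc <- 0L
  w <- nd_kernel(params$nd_mean, params$nd_sd, grid$dt)
  # the density is only ever evaluated at observed RTs, so the solve
  # horizon never needs to exceed the largest RT (decision time <= RT);
  # this is exact, not an approximation
  if (is.null(grid$t_max)) {
    grid$t_max <- max(tr$rt) + grid$dt
    grid$survivor_tol <- Inf
  }
  rt_split <- split(tr[c("rt", "choice")], tr$stimulus_strength)
  for (s in names(rt_split)) {
    mu <- drift_at(params$drift, as.numeric(s))
    fp <- solve_fpe(mu, params, grid)
    d <- rt_split[[s]]
    t_hi <- max(fp$time) + length(w) * grid$dt
    for (ch in c("sad", "happy")) {
      tt <- d$rt[d$choice == ch]
      if (!length(tt)) next
      f <- if (ch == "sad") fp$upper else fp$lower
      dens <- trial_density_cpp(f * fp$dt, fp$dt, w, tt)
      ll <- ll + sum(log(pmax(dens, 1e-10)))
      n_trunc <- n_trunc + sum(tt > t_hi)
    }
  }
  if (n_trunc > 0.01 * nrow(tr))
    warning(n_trunc, " trials beyond the solve horizon (> 1%); ",
            "consider a longer t_max")
  structure(ll, n_truncated = n_trunc)
}

# parameter transforms for the 7-parameter fit ---------------------------
T0_BOX <- c(0.05, 1.0)

reduced_pack <- function(B, dB, T0, k, s0, mu_low, mu_high) {
  c(log(B), atanh(max(-1 + 1e-9, min(1 - 1e-9, dB / B))),
    stats::qlogis((T0 - T0_BOX[1L]) / diff(T0_BOX)), k, s0, mu_low, mu_high)
}

reduced_unpack <- function(theta, stimuli) {
  B <- exp(theta[1L])
  dB <- B * (1 - 1e-9) * tanh(theta[2L])
  T0 <- T0_BOX[1L] + diff(T0_BOX) * stats::plogis(theta[3L])
  drift <- drift_map_reduced(theta[4L], theta[5L], theta[6L], theta[7L],
                             stimuli)
  ddm_params(bound_mean = B, bound_offset = dB, nd_mean = T0, drift = drift)
}

#' Full-likelihood fit of the reduced (7-parameter) model
#'
#' Maximizes the joint choice/response-time likelihood
#' ([loglik_trials()]) over the seven parameters: linear drift slope `k`
#' and zero-crossing `s0` for the middle stimuli, free drifts for the two
#' extremes, mean bound, bound offset, and mean nondecision time
#' (SD fixed at mean/3). Multi-start Nelder-Mead with a BFGS polish; the
#' first start is a heuristic from the psychometric/chronometric summaries
#' (or `init` if given), the rest jitters.
#'
#' @param table a [trial_table] for one condition.
#' @param grid an [fpe_grid]; for fitting a coarser grid than the
#'   reporting default is often adequate (e.g. `fpe_grid(120, 2e-3)`).
#' @param n_starts optimizer starts (default 10).
#' @param init optional [ddm_params] initial guess.
#' @param seed seed for start jitters.
#' @return object of class `ddm_fit` (method `"fpe"`) with the fitted
#'   [ddm_params] (reduced drift map), `loglik`, all-start summary, and a
#'   `boundary` flag when the optimum sits on the nondecision-time box.
#' @export
fit_reduced_model <- function(table, grid = fpe_grid(), n_starts = 10L,
                              init = NULL, seed = 1L, maxit = 300L,
                              polish = TRUE) {
  stopifnot(inherits(table, "trial_table"))
  tr <- table$trials
  stimuli <- stimulus_set(unique(tr$stimulus_strength))
  if (length(stimuli$strengths) < 5L)
    stop("too few stimulus levels for the reduced drift map")
  negll <- function(theta) {
    p <- tryCatch(reduced_unpack(theta, stimuli), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- tryCatch(suppressWarnings(-as.numeric(loglik_trials(p, table,
                                                             grid))),
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  th0 <- if (!is.null(init)) {
    reduced_pack(init$bound_mean, init$bound_offset, init$nd_mean,
                 init$drift$k, init$drift$s0, init$drift$mu_low,
                 init$drift$mu_high)
  } else reduced_start(table, stimuli)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best <- NULL
  starts <- list()
  for (i in seq_len(n_starts)) {
    scales <- c(0.2, 0.2, 0.3, abs(th0[4L]) * 0.15 + 0.2, 0.02,
                abs(th0[6L]) * 0.15 + 0.2, abs(th0[7L]) * 0.15 + 0.2)
    th <- if (i == 1L) th0 else th0 + stats::rnorm(7L, 0, scales)
    f <- tryCatch({
      nm <- stats::optim(th, negll, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-6))
      if (polish)
        nm <- stats::optim(nm$par, negll, method = "BFGS",
                           control = list(maxit = 40, reltol = 1e-8))
      nm
    }, error = function(e) NULL)
    if (is.null(f)) next
    starts[[length(starts) + 1L]] <- c(value = f$value,
                                       convergence = f$convergence)
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best)) stop("all optimizer starts failed")
  params <- reduced_unpack(best$par, stimuli)
  boundary <- params$nd_mean < T0_BOX[1L] + 1e-3 ||
    params$nd_mean > T0_BOX[2L] - 1e-3
  structure(list(params = params, loglik = -best$value, method = "fpe",
                 grid = grid, n_starts = n_starts,
                 starts = do.call(rbind, starts), boundary = boundary,
                 se = NULL, condition = unique(tr$condition)[1L]),
            class = "ddm_fit")
}

# heuristic initial guess from psychometric + chronometric summaries
reduced_start <- function(table, stimuli) {
  lf <- tryCatch(fit_simple_logistic(table), error = function(e) NULL)
  cells <- summarize_cells(table)
  T0 <- max(T0_BOX[1L] + 0.01, min(T0_BOX[2L] - 0.01,
                                   0.8 * min(cells$mean_rt)))
  B <- sqrt(max(0.09, min(4, max(cells$mean_rt) - T0)))
  b0 <- if (!is.null(lf) && is.finite(lf$beta0)) lf$beta0 else 15
  s0 <- if (!is.null(lf) && is.finite(lf$pse)) lf$pse else 0.5
  k <- b0 / (2 * B)
  st <- stimuli$strengths
  reduced_pack(B, 0, T0, k, s0, k * (st[1L] - s0),
               k * (st[length(st)] - s0))
}

#' Bootstrap standard errors for a fitted decision model
#'
#' Refits the model to trial-level bootstrap resamples (drawn with
#' replacement within the condition) using the base fit as the single
#' starting point, and reports the SD of each parameter across resample
#' fits. Failed resamples are dropped and counted; more than 25% failures
#' is an error.
#'
#' @param fit a [fit_reduced_model()] or [fit_highparam_model()] result.
#' @param table the [trial_table] the fit came from.
#' @param n_boot number of resamples, 40-60.
#' @param seed RNG seed.
#' @param grid [fpe_grid] for `"fpe"` fits (defaults to the fit's grid).
#' @param maxit simplex iteration cap per resample refit (they start at
#'   the base estimate, so fewer iterations suffice than for a cold fit).
#' @return named numeric vector of SEs (attribute `n_failed`); also
#'   attached to a copy of the fit under `$se` in the returned attribute
#'   `fit`.
#' @export
bootstrap_fit_se <- function(fit, table, n_boot = 40L, seed = 1L,
                             grid = NULL, maxit = 120L) {
  stopifnot(inherits(fit, "ddm_fit"), n_boot >= 40L, n_boot <= 60L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  tr <- table$trials
  draws <- list()
  n_failed <- 0L
  for (i in seq_len(n_boot)) {
    tb <- table
    tb$trials <- tr[sample.int(nrow(tr), replace = TRUE), , drop = FALSE]
    est <- tryCatch({
      if (fit$method == "fpe") {
        g <- if (is.null(grid)) fit$grid else grid
        f <- fit_reduced_model(tb, grid = g, n_starts = 1L,
                               init = fit$params, seed = seed + i,
                               maxit = maxit, polish = FALSE)
        p <- f$params
        c(bound_mean = p$bound_mean, bound_offset = p$bound_offset,
          nd_mean = p$nd_mean, k = p$drift$k, s0 = p$drift$s0,
          mu_low = p$drift$mu_low, mu_high = p$drift$mu_high)
      } else {
        cl <- summarize_cells(tb)
        f <- fit_highparam_model(cl, n_starts = 1L, seed = seed + i)
        p <- f$params
        c(bound_mean = p$bound_mean, bound_offset = p$bound_offset,
          nd_mean = p$nd_mean,
          stats::setNames(p$drift$drifts,
                          paste0("mu_", format(p$drift$strengths))))
      }
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else
      draws[[length(draws) + 1L]] <- est
  }
  if (n_failed > 0.25 * n_boot)
    stop("more than 25% of bootstrap refits failed (",
         n_failed, "/", n_boot, ")")
  m <- do.call(rbind, draws)
  se <- apply(m, 2L, stats::sd)
  attr(se, "n_failed") <- n_failed
  se
}
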