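#' Closed-form choice probability of a drift-diffusion process
#'
#' Probability that a unit-variance diffusion starting at 0 is absorbed at
#' the upper (sad) bound, for drift `mu`, mean bound height `B_bar` and
#' bound offset `dB` (upper bound magnitude `B_bar - dB`, lower
#' `B_bar + dB`):
#' \deqn{P = \frac{e^{2\mu \bar B} - e^{-2\mu \Delta B}}
#'              {e^{2\mu \bar B} - e^{-2\mu \bar B}}}
#' A series branch handles |mu| below 1e-6 (zero-drift limit
#' `(B_bar + dB) / (2 B_bar)`), and the expression is evaluated in
#' overflow-safe form for large drifts.
#'
#' @param mu drift rate(s) (evidence units per second).
#' @param B_bar mean bound height (> 0).
#' @param dB bound offset (|dB| < B_bar).
#' @return probability of a sad (upper-bound) choice, vectorized over `mu`.
#' @export
choice_prob_analytic <- function(mu, B_bar, dB = 0) {
  check_bounds(B_bar, dB)
  vapply(as.numeric(mu), function(m) {
    if (abs(m) < 1e-6) {
      # third-order series: agrees with the exact branch to ~1e-15 at the
      # switch point
      num <- (B_bar + dB) + m * (B_bar^2 - dB^2) +
        (2 / 3) * m^2 * (B_bar^3 + dB^3)
      den <- 2 * B_bar + (4 / 3) * m^2 * B_bar^3
      return(num / den)
    }
    if (m > 0) {
      # divide by exp(2 mu B): (1 - e^{-2mu(B+dB)}) / (1 - e^{-4 mu B})
      -expm1(-2 * m * (B_bar + dB)) / -expm1(-4 * m * B_bar)
    } else {
      # reflection: P(mu, dB) = 1 - P(-mu, -dB)
      1 + expm1(2 * m * (B_bar - dB)) / -expm1(4 * m * B_bar)
    }
  }, numeric(1))
}

check_bounds <- function(B_bar, dB) {
  if (!is.finite(B_bar) || B_bar <= 0 || abs(dB) >= B_bar)
    stop("invalid bounds: need B_bar > 0 and |dB| < B_bar")
  invisible(TRUE)
}

#' Closed-form mean response time of a drift-diffusion process
#'
#' Unconditional mean response time
#' \deqn{\bar T = \frac{\bar B (2P - 1) - \Delta B}{\mu} + \bar T_0}
#' with the drift-free limit `B_bar^2 - dB^2 + T0` handled by series
#' expansion.
#'
#' @inheritParams choice_prob_analytic
#' @param T0 mean nondecision time in seconds (>= 0).
#' @return mean response time in seconds, vectorized over `mu`.
#' @export
mean_rt_analytic <- function(mu, B_bar, dB = 0, T0 = 0) {
  check_bounds(B_bar, dB)
  if (T0 < 0) stop("T0 must be non-negative")
  vapply(as.numeric(mu), function(m) {
    if (abs(m) < 1e-6) {
      dec <- (B_bar^2 - dB^2) * (1 - (2 / 3) * m * dB) /
        (1 + (2 / 3) * m^2 * B_bar^2)
    } else {
      p <- choice_prob_analytic(m, B_bar, dB)
      dec <- (B_bar * (2 * p - 1) - dB) / m
    }
    dec + T0
  }, numeric(1))
}

#' Per-cell summaries of a trial table
#'
#' One row per (condition, stimulus strength): trial count, observed sad
#' fraction, mean and variance of response time (variance `NA` for
#' single-trial cells).
#'
#' @param table a [trial_table].
#' @return data.frame of class `cell_summary`.
#' @export
summarize_cells <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  tr <- table$trials
  if (nrow(tr) == 0L) stop("empty trial table")
  key <- interaction(tr$condition, tr$stimulus_strength, drop = TRUE)
  rows <- lapply(split(tr, key), function(d) data.frame(
    condition = d$condition[1L],
    stimulus_strength = d$stimulus_strength[1L],
    n_trials = nrow(d),
    p_sad = mean(d$choice == "sad"),
    mean_rt = mean(d$rt),
    var_rt = if (nrow(d) > 1L) stats::var(d$rt) else NA_real_))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$condition, out$stimulus_strength), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_summary", "data.frame")
  out
}

# objective pieces shared by the fast (closed-form) fit ------------------

highparam_negloglik <- function(theta, cells) {
  B <- exp(theta[1L])
  dB <- B * (1 - 1e-9) * tanh(theta[2L])
  T0 <- exp(theta[3L])
  mus <- theta[-(1:3)]
  if (!is.finite(B) || !is.finite(T0) || any(!is.finite(mus)) ||
      !is.finite(dB) || B < 1e-8 || B > 1e8 || T0 > 1e3)
    return(1e10)
  p <- choice_prob_analytic(mus, B, dB)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  k <- cells$p_sad * cells$n_trials   # fractional counts are acceptable
  ll_choice <- sum(k * log(p) + (cells$n_trials - k) * log(1 - p))
  t_pred <- mean_rt_analytic(mus, B, dB, T0)
  se <- sqrt(cells$var_rt / cells$n_trials)
  use <- is.finite(se) & se > 0
  ll_rt <- sum(stats::dnorm(cells$mean_rt[use], t_pred[use], se[use],
                            log = TRUE))
  -(ll_choice + ll_rt)
}

#' Fast closed-form fit of the high-parameter model
#'
#' Fits the 14-parameter model (one drift rate per stimulus, mean bound,
#' bound offset, nondecision time) to per-stimulus choice fractions and
#' mean response times for a single condition, maximizing the sum of the
#' binomial log-likelihood of choices under the closed-form choice
#' probability and the Gaussian log-likelihood of observed mean response
#' times (standard error `sqrt(var_rt / n)`) under the closed-form mean.
#' The two log-likelihood terms are weighted equally.
#'
#' @param cells a [summarize_cells()] data.frame restricted to one
#'   condition (>= 11 cells recommended).
#' @param n_starts number of optimizer starts (first start is a heuristic
#'   initial guess, the rest are jitters of it).
#' @param seed seed for the start jitters.
#' @return object of class `ddm_fit` (method `"analytic"`): a [ddm_params]
#'   with a per-stimulus drift map, the log-likelihood, and convergence
#'   metadata.
#' @export
fit_highparam_model <- function(cells, n_starts = 20L, seed = 1L) {
  stopifnot(inherits(cells, "data.frame"))
  if (length(unique(cells$condition)) != 1L)
    stop("fit one condition at a time")
  if (nrow(cells) < 3L) stop("too few cells")
  if (all(cells$p_sad == 0) || all(cells$p_sad == 1))
    stop("both choices must be represented")
  cells <- cells[order(cells$stimulus_strength), , drop = FALSE]
  th0 <- highparam_start(cells)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(n_starts)) {
    th <- if (i == 1L) th0 else th0 + stats::rnorm(length(th0), 0, 0.25)
    fit <- tryCatch({
      # restart BFGS until converged: the drift/bound trade-off ridge is
      # shallow and a single pass can stall short of the optimum
      f <- stats::optim(th, highparam_negloglik, cells = cells,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
      for (r in 1:15) {
        f2 <- stats::optim(f$par, highparam_negloglik, cells = cells,
                           method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-12))
        improved <- f$value - f2$value
        f <- f2
        if (improved < 1e-9) break
      }
      f
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- best$par
  B <- exp(th[1L]); dB <- B * tanh(th[2L]); T0 <- exp(th[3L])
  params <- ddm_params(
    bound_mean = B, bound_offset = dB, nd_mean = T0,
    drift = drift_map_per_stimulus(cells$stimulus_strength, th[-(1:3)]))
  structure(list(params = params, loglik = -best$value,
                 method = "analytic", n_starts = n_starts,
                 n_converged = n_conv, se = NULL,
                 condition = cells$condition[1L]),
            class = "ddm_fit")
}

highparam_start <- function(cells) {
  T0 <- 0.8 * min(cells$mean_rt)
  B <- sqrt(max(0.09, max(cells$mean_rt) - T0))
  p <- pmin(0.99, pmax(0.01, cells$p_sad))
  mus <- stats::qlogis(p) / (2 * B)
  c(log(B), 0, log(T0), mus)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("ddm_fit (", x$method, "), condition ", x$condition,
      ": loglik = ", format(x$loglik), "\n", sep = "")
  print(x$params)
  if (!is.null(x$se)) {
    cat("bootstrap SEs:\n")
    print(x$se)
  }
  invisible(x)
}

# seed helpers: set the RNG locally and restore the caller's state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
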