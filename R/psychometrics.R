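# Both logistic models use the multiplicative parameterization
#   logit[P(sad)] = beta0 * (S + beta1),     PSE = -beta1
# and are fit by direct numerical maximum likelihood (not via a GLM
# re-parameterization) so that estimates and bootstrap SEs are reported for
# these parameters. A standard GLM is used only to initialise.

logistic_cells <- function(table, condition = NULL) {
  tr <- table$trials
  if (!is.null(condition)) tr <- tr[tr$condition %in% condition, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials after condition filter")
  agg <- stats::aggregate(cbind(k = choice == "sad", n = 1) ~
                            stimulus_strength, data = tr, FUN = sum)
  agg[order(agg$stimulus_strength), , drop = FALSE]
}

simple_negloglik <- function(theta, cells) {
  p <- stats::plogis(theta[1L] * (cells$stimulus_strength + theta[2L]))
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
}

perfectly_separated <- function(cells) {
  p <- cells$k / cells$n
  all(p %in% c(0, 1)) && !is.unsorted(p) && length(unique(p)) == 2L
}

fit_simple_ml <- function(cells, n_starts = 5L) {
  # GLM initialisation: logit p = a + b S  =>  beta0 = b, beta1 = a / b
  ini <- tryCatch({
    g <- suppressWarnings(stats::glm(cbind(k, n - k) ~ stimulus_strength,
                                     family = stats::binomial(),
                                     data = cells))
    co <- stats::coef(g)
    if (abs(co[2L]) < 1e-8) {
      c(1e-3, -stats::weighted.mean(cells$stimulus_strength, cells$n))
    } else c(co[2L], co[1L] / co[2L])
  }, error = function(e) c(5, -0.5))
  best <- NULL
  jit <- cbind(c(1, 0.5, 2, 1, 1), c(0, 0, 0, 0.1, -0.1))
  for (i in seq_len(n_starts)) {
    th <- c(ini[1L] * jit[i, 1L], ini[2L] + jit[i, 2L])
    f <- tryCatch(stats::optim(th, simple_negloglik, cells = cells,
                               control = list(maxit = 1000,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("logistic optimizer failed to converge")
  best$par <- unname(best$par)
  best
}

#' Fit the simple logistic psychometric model
#'
#' Maximum-likelihood fit of `logit[P(sad)] = beta0 * (S + beta1)` (the
#' multiplicative parameterization); the point of subjective equality is
#' `PSE = -beta1`. Perfect separation is detected and flagged with an
#' infinite-slope marker; near-zero slopes are flagged as giving an
#' unreliable PSE.
#'
#' @param table a [trial_table].
#' @param condition optional condition filter (default: use all trials).
#' @param n_boot number of trial-level bootstrap resamples for standard
#'   errors (0 to skip).
#' @param seed bootstrap seed.
#' @return object of class `logistic_fit` with fields `beta0`, `beta1`,
#'   `pse`, `loglik`, `se_beta0`, `se_beta1`, `se_pse`, and flags
#'   `separated`, `pse_unreliable`.
#' @export
fit_simple_logistic <- function(table, condition = NULL, n_boot = 0L,
                                seed = 1L) {
  stopifnot(inherits(table, "trial_table"))
  cells <- logistic_cells(table, condition)
  if (nrow(cells) < 2L)
    stop("need >= 2 distinct stimulus strengths")
  if (sum(cells$k) == 0L || sum(cells$k) == sum(cells$n))
    stop("both responses must be represented")
  if (perfectly_separated(cells)) {
    # infinite-slope marker: PSE taken at the midpoint of the step
    p <- cells$k / cells$n
    lo <- max(cells$stimulus_strength[p == 0])
    hi <- min(cells$stimulus_strength[p == 1])
    return(structure(list(beta0 = Inf, beta1 = -(lo + hi) / 2,
                          pse = (lo + hi) / 2, loglik = 0,
                          se_beta0 = NA_real_, se_beta1 = NA_real_,
                          se_pse = NA_real_, separated = TRUE,
                          pse_unreliable = FALSE),
                     class = "logistic_fit"))
  }
  best <- fit_simple_ml(cells)
  out <- structure(list(beta0 = best$par[1L], beta1 = best$par[2L],
                        pse = -best$par[2L], loglik = -best$value,
                        se_beta0 = NA_real_, se_beta1 = NA_real_,
                        se_pse = NA_real_, separated = FALSE,
                        pse_unreliable = abs(best$par[1L]) < 1),
                   class = "logistic_fit")
  if (n_boot > 0L) {
    tr <- table$trials
    if (!is.null(condition)) tr <- tr[tr$condition %in% condition, ,
                                      drop = FALSE]
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    bs <- replicate(n_boot, {
      d <- tr[sample.int(nrow(tr), replace = TRUE), , drop = FALSE]
      cl <- stats::aggregate(cbind(k = choice == "sad", n = 1) ~
                               stimulus_strength, data = d, FUN = sum)
      f <- tryCatch(fit_simple_ml(cl, n_starts = 1L),
                    error = function(e) NULL)
      if (is.null(f)) c(NA, NA) else f$par
    })
    out$se_beta0 <- stats::sd(bs[1L, ], na.rm = TRUE)
    out$se_beta1 <- stats::sd(bs[2L, ], na.rm = TRUE)
    out$se_pse <- out$se_beta1
  }
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic_fit: beta0 =", format(x$beta0), " PSE =", format(x$pse))
  if (!is.na(x$se_pse)) cat(" +/-", format(x$se_pse))
  if (isTRUE(x$separated)) cat("  [perfect separation]")
  if (isTRUE(x$pse_unreliable)) cat("  [PSE unreliable: |beta0| < 1]")
  cat("\n")
  invisible(x)
}

condition_negloglik <- function(theta, cells) {
  # theta = (b0, b1, b2, b3, b4); L1 happy-adapted, L2 sad-adapted,
  # L3 either adapted
  L1 <- as.numeric(cells$condition == "happy_adapted")
  L2 <- as.numeric(cells$condition == "sad_adapted")
  L3 <- pmax(L1, L2)
  eta <- (theta[1L] + theta[5L] * L3) *
    (cells$stimulus_strength + theta[2L] + theta[3L] * L1 + theta[4L] * L2)
  p <- pmin(1 - 1e-12, pmax(1e-12, stats::plogis(eta)))
  -sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
}

#' Fit the condition logistic model
#'
#' Joint ML fit of
#' `logit[P(sad)] = (beta0 + beta4 L3)(S + beta1 + beta2 L1 + beta3 L2)`
#' where L1/L2 indicate happy-/sad-adapted trials and L3 either adapted
#' condition. `beta2`/`beta3` are the PSE changes of the adapted conditions
#' relative to unadapted (a positive value shifts the curve leftward, i.e.
#' the adapted PSE is `-(beta1 + beta2)`), and `beta4` is the slope change
#' under adaptation. Standard errors come from the inverse observed
#' information (numerical Hessian).
#'
#' @param table a [trial_table] spanning all three conditions.
#' @return object of class `condition_logistic_fit` with `coef` (beta0 to
#'   beta4), `se`, and `loglik`.
#' @export
fit_condition_logistic <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  tr <- table$trials
  if (!all(CONDITIONS %in% tr$condition))
    stop("all three conditions must be present")
  agg <- stats::aggregate(cbind(k = choice == "sad", n = 1) ~
                            stimulus_strength + condition, data = tr,
                          FUN = sum)
  un <- fit_simple_logistic(table, "unadapted")
  ha <- fit_simple_logistic(table, "happy_adapted")
  sa <- fit_simple_logistic(table, "sad_adapted")
  th0 <- c(un$beta0, un$beta1, ha$beta1 - un$beta1, sa$beta1 - un$beta1,
           (ha$beta0 + sa$beta0) / 2 - un$beta0)
  th0[!is.finite(th0)] <- 0
  best <- NULL
  jitters <- rbind(0, diag(c(1, 0.02, 0.02, 0.02, 0.5)),
                   -diag(c(1, 0.02, 0.02, 0.02, 0.5)))
  for (i in seq_len(nrow(jitters))) {
    th <- th0 + jitters[i, ]
    f <- tryCatch(stats::optim(th, condition_negloglik, cells = agg,
                               method = "BFGS",
                               control = list(maxit = 1000,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("condition logistic failed to converge")
  H <- stats::optimHess(best$par, condition_negloglik, cells = agg)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, 5))
  nm <- paste0("beta", 0:4)
  structure(list(coef = stats::setNames(best$par, nm),
                 se = stats::setNames(se, nm), loglik = -best$value),
            class = "condition_logistic_fit")
}

#' @export
print.condition_logistic_fit <- function(x, ...) {
  cat("condition_logistic_fit (loglik", format(x$loglik), ")\n")
  print(data.frame(estimate = x$coef, se = x$se))
  invisible(x)
}

#' PSE shift between two conditions with bootstrap SE
#'
#' `shift = PSE(adapted) - PSE(unadapted)`. The standard error is the SD
#' of the shift over trial-level bootstrap resamples drawn independently
#' within each condition.
#'
#' @param adapted,unadapted [fit_simple_logistic()] fits.
#' @param adapted_table,unadapted_table the trial tables the fits came from
#'   (needed for resampling; omit to skip the SE).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return list with `shift`, `se`, `n_boot_failed`.
#' @export
pse_shift <- function(adapted, unadapted, adapted_table = NULL,
                      unadapted_table = NULL, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(adapted, "logistic_fit"),
            inherits(unadapted, "logistic_fit"))
  out <- list(shift = adapted$pse - unadapted$pse, se = NA_real_,
              n_boot_failed = 0L)
  if (!is.null(adapted_table) && !is.null(unadapted_table) && n_boot > 0L) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    resample_pse <- function(tab) {
      tr <- tab$trials
      d <- tr[sample.int(nrow(tr), replace = TRUE), , drop = FALSE]
      cl <- stats::aggregate(cbind(k = choice == "sad", n = 1) ~
                               stimulus_strength, data = d, FUN = sum)
      f <- tryCatch(fit_simple_ml(cl, n_starts = 1L),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else -f$par[2L]
    }
    draws <- replicate(n_boot,
                       resample_pse(adapted_table) -
                         resample_pse(unadapted_table))
    out$n_boot_failed <- sum(is.na(draws))
    out$se <- stats::sd(draws, na.rm = TRUE)
  }
  out
}

#' Across-subject bootstrap aggregation
#'
#' Builds the bootstrap distribution of an across-subject average: per
#' iteration one resampled value of the statistic is drawn for each subject
#' and the values are averaged. The p value is the fraction of iterations
#' on the declared null side of zero, with ties at exactly zero counted as
#' one half.
#'
#' @param samples list of numeric vectors, one per subject: resampled
#'   (e.g. trial-bootstrap) values of the statistic of interest.
#' @param n_iter bootstrap iterations (default 10000; below 100 warns).
#' @param seed RNG seed.
#' @param side `"greater"` tests the claim that the statistic exceeds zero
#'   (p = fraction of averages <= 0); `"less"` the reverse.
#' @return list with the bootstrap `distribution` of across-subject
#'   averages and the one-sided `p` value.
#' @export
aggregate_across_subjects <- function(samples, n_iter = 10000L, seed = 1L,
                                      side = c("greater", "less")) {
  side <- match.arg(side)
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (n_iter < 100L) warning("n_iter < 100 gives an unstable p value")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  draws <- vapply(seq_len(n_iter), function(i) {
    mean(vapply(samples, function(v) v[sample.int(length(v), 1L)],
                numeric(1)))
  }, numeric(1))
  ties <- mean(draws == 0)
  p <- if (side == "greater") mean(draws < 0) + 0.5 * ties else
    mean(draws > 0) + 0.5 * ties
  list(distribution = draws, p = p, side = side)
}

#' Per-subject bootstrap samples of an arbitrary statistic
#'
#' Convenience generator of the `samples` argument of
#' [aggregate_across_subjects()]: for each subject's trial table, draws
#' trial-level bootstrap resamples (within condition) and evaluates the
#' statistic on each.
#'
#' @param tables list of per-subject [trial_table]s.
#' @param statistic function taking a [trial_table] and returning a number.
#' @param n_samples resamples per subject.
#' @param seed RNG seed.
#' @return list of numeric vectors, one per subject.
#' @export
subject_statistic_samples <- function(tables, statistic, n_samples = 200L,
                                      seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lapply(tables, function(tab) {
    tr <- tab$trials
    idx_by_cond <- split(seq_len(nrow(tr)), tr$condition)
    vapply(seq_len(n_samples), function(i) {
      take <- unlist(lapply(idx_by_cond, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      tb <- tab
      tb$trials <- tr[take, , drop = FALSE]
      statistic(tb)
    }, numeric(1))
  })
}

#' Model-free evidence profile: logit of the sad-choice fraction
#'
#' Per stimulus strength, the empirical P(sad) and its logit; under a
#' fixed-bound diffusion the logit is linear in the average evidence
#' conferred by the stimulus. P is clipped to
#' \[1/(2n), 1 - 1/(2n)\] before the logit (n = trials at that stimulus)
#' and clipped cells are flagged.
#'
#' @param table a [trial_table].
#' @param condition optional condition filter.
#' @return data.frame with `stimulus_strength`, `n`, `p_sad`, `logit`,
#'   `clipped`.
#' @export
logit_evidence_profile <- function(table, condition = NULL) {
  cells <- logistic_cells(table, condition)
  p_raw <- cells$k / cells$n
  lo <- 1 / (2 * cells$n)
  p <- pmin(1 - lo, pmax(lo, p_raw))
  data.frame(stimulus_strength = cells$stimulus_strength, n = cells$n,
             p_sad = p_raw, logit = stats::qlogis(p),
             clipped = p != p_raw)
}
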