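#' Model-predicted psychometric function
#'
#' Closed-form P(sad) per stimulus for a parameter set (exact for this
#' model class; agrees with the Fokker-Planck absorbed mass to
#' numerical tolerance).
#'
#' @param params a [ddm_params].
#' @param stimuli a [stimulus_set].
#' @return named numeric vector of P(sad), one per stimulus.
#' @export
predict_psychometric <- function(params, stimuli) {
  stopifnot(inherits(params, "ddm_params"), inherits(stimuli, "stimulus_set"))
  mus <- drift_at(params$drift, stimuli$strengths)
  p <- choice_prob_analytic(mus, params$bound_mean, params$bound_offset)
  stats::setNames(p, format(stimuli$strengths))
}

#' PSE of a predicted psychometric function
#'
#' Fits the simple logistic `logit(p) = beta0 (S + beta1)` to predicted
#' probabilities by unweighted least squares on the logit scale (with
#' endpoint clipping) and returns `-beta1`. If the predictions never cross
#' 0.5 within the stimulus range the returned PSE carries an
#' `extrapolated` attribute.
#'
#' @param probs per-stimulus P(sad).
#' @param stimuli the matching [stimulus_set].
#' @return the PSE (strength units), attribute `extrapolated` flag.
#' @export
pse_from_predictions <- function(probs, stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  s <- stimuli$strengths
  if (length(probs) != length(s)) stop("probs/stimuli length mismatch")
  if (all(probs > 0.5) || all(probs < 0.5))
    extrap <- TRUE else extrap <- FALSE
  y <- stats::qlogis(pmin(1 - 1e-6, pmax(1e-6, probs)))
  fit <- stats::lm.fit(cbind(1, s), y)
  a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
  if (abs(b) < 1e-12) stop("predictions carry no slope; PSE undefined")
  pse <- -a / b
  if (pse < min(s) || pse > max(s)) extrap <- TRUE
  structure(pse, extrapolated = extrap)
}

#' Partition a PSE shift into sensitivity, bound, and interaction parts
#'
#' Counterfactual decomposition of the adapted-minus-unadapted PSE shift:
#' `C_S` is the expected shift with unadapted bounds but adapted drift
#' rates; `C_B` the expected shift with adapted bounds (the pair mean
#' height + offset moved together) but unadapted drifts; the interaction
#' `C_BxS` is the residual `total - C_S - C_B`, so the three parts add to
#' the total exactly. The overall contributions split the interaction
#' evenly: `overall_sensitivity = C_S + 0.5 C_BxS`,
#' `overall_bound = C_B + 0.5 C_BxS`. Nondecision time plays no role (it
#' cannot move the psychometric function).
#'
#' @param unadapted,adapted [ddm_params] for the two conditions, defined on
#'   the same stimuli.
#' @param stimuli the [stimulus_set] to predict over.
#' @return object of class `contribution_result`.
#' @export
partition_shift <- function(unadapted, adapted, stimuli) {
  pse_of <- function(p) as.numeric(
    pse_from_predictions(predict_psychometric(p, stimuli), stimuli))
  swap_bounds <- function(base, from) {
    base$bound_mean <- from$bound_mean
    base$bound_offset <- from$bound_offset
    base
  }
  pse_un <- pse_of(unadapted)
  total <- pse_of(adapted) - pse_un
  c_s <- pse_of(swap_bounds(adapted, unadapted)) - pse_un   # drifts changed
  c_b <- pse_of(swap_bounds(unadapted, adapted)) - pse_un   # bounds changed
  c_bxs <- total - c_s - c_b
  res <- list(total_shift = total, C_S = c_s, C_B = c_b, C_BxS = c_bxs,
              overall_sensitivity = c_s + 0.5 * c_bxs,
              overall_bound = c_b + 0.5 * c_bxs)
  if (total != 0) {
    res$normalized_sensitivity <- res$overall_sensitivity / total
    res$normalized_bound <- res$overall_bound / total
  }
  structure(res, class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("contribution_result (strength units):\n")
  cat(sprintf("  total shift      %+.5f\n", x$total_shift))
  cat(sprintf("  C_S (drift)      %+.5f\n", x$C_S))
  cat(sprintf("  C_B (bounds)     %+.5f\n", x$C_B))
  cat(sprintf("  C_BxS (interact) %+.5f\n", x$C_BxS))
  cat(sprintf("  overall: sensitivity %+.5f, bound %+.5f\n",
              x$overall_sensitivity, x$overall_bound))
  if (!is.null(x$normalized_sensitivity))
    cat(sprintf("  normalized: %.3f / %.3f\n", x$normalized_sensitivity,
                x$normalized_bound))
  invisible(x)
}

#' Separation of the two adapted-condition PSEs
#'
#' Given the PSE shifts of the happy- and sad-adapted conditions relative
#' to unadapted (strength units, signed), returns their separation in
#' strength units and in steps along the morph line (a 41-image line has
#' 40 steps of 1/40 strength units each).
#'
#' @param shift_happy_adapted signed PSE shift of the happy-adapted
#'   condition (negative when the curve shifts toward the happy prototype).
#' @param shift_sad_adapted signed PSE shift of the sad-adapted condition.
#' @param n_morph_steps number of steps on the morph line (default 40).
#' @return list with `strength` (separation in strength units) and
#'   `steps` (the same expressed in morph-line steps).
#' @export
pse_separation <- function(shift_happy_adapted, shift_sad_adapted,
                           n_morph_steps = 40L) {
  sep <- abs(shift_sad_adapted - shift_happy_adapted)
  list(strength = sep, steps = sep * n_morph_steps)
}
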