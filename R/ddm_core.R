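#' Stimulus set on the morph line
#'
#' A sorted set of distinct stimulus strengths in \[0, 1\] (morph-line
#' positions; 0 = happy prototype, 1 = sad prototype). The lowest and
#' highest members are designated "extreme"; a reduced drift map treats
#' them separately from the middle stimuli.
#'
#' @param strengths numeric vector of stimulus strengths in \[0, 1\],
#'   at least 3 distinct values.
#' @return an object of class `stimulus_set`: the sorted strengths with the
#'   extreme positions recorded.
#' @export
stimulus_set <- function(strengths) {
  s <- sort(unique(as.numeric(strengths)))
  if (length(s) < 3L) stop("a stimulus set needs at least 3 distinct strengths")
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("stimulus strengths must lie in [0, 1]")
  structure(list(strengths = s, extreme_indices = c(1L, length(s))),
            class = "stimulus_set")
}

#' The fixed 11-level stimulus set of a constant-stimuli design
#'
#' Nine middle levels spaced 0.025 apart around the morph midpoint plus two
#' extreme anchors.
#' @return a [stimulus_set]
#' @export
exp1_stimulus_set <- function() {
  stimulus_set(c(0.125, seq(0.375, 0.575, by = 0.025), 0.875))
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("stimulus_set:", length(x$strengths), "levels in [",
      min(x$strengths), ",", max(x$strengths), "]\n")
  invisible(x)
}

#' Per-stimulus drift map
#'
#' One free drift rate per stimulus strength (the 14-parameter model's
#' sensitivity table). Lookup is exact (within a small tolerance).
#'
#' @param strengths stimulus strengths.
#' @param drifts drift rates, same length (evidence units per second;
#'   positive favours the sad / upper bound).
#' @return an object of class `drift_map` with kind `"per_stimulus"`.
#' @export
drift_map_per_stimulus <- function(strengths, drifts) {
  strengths <- as.numeric(strengths)
  drifts <- as.numeric(drifts)
  if (length(strengths) != length(drifts))
    stop("strengths and drifts must have equal length")
  if (anyDuplicated(strengths)) stop("duplicate strengths in drift map")
  o <- order(strengths)
  structure(list(kind = "per_stimulus", strengths = strengths[o],
                 drifts = drifts[o]),
            class = "drift_map")
}

#' Reduced (4-parameter) drift map
#'
#' Linear drift rule mu = k * (S - s0) for the middle stimuli of a working
#' stimulus set, with free drifts for the two extremes. This is the drift
#' parameterization of the 7-parameter model.
#'
#' @param k slope of the linear rule (drift per strength unit).
#' @param s0 zero-crossing strength (the stimulus with zero mean evidence).
#' @param mu_low free drift of the lowest (most happy) extreme stimulus.
#' @param mu_high free drift of the highest (most sad) extreme stimulus.
#' @param stimuli the working [stimulus_set]; its first and last members are
#'   the extremes.
#' @return an object of class `drift_map` with kind `"reduced"`.
#' @export
drift_map_reduced <- function(k, s0, mu_low, mu_high, stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  structure(list(kind = "reduced", k = as.numeric(k), s0 = as.numeric(s0),
                 mu_low = as.numeric(mu_low), mu_high = as.numeric(mu_high),
                 stimuli = stimuli),
            class = "drift_map")
}

#' Evaluate a drift map at a stimulus strength
#'
#' @param map a `drift_map`.
#' @param S stimulus strength(s). For a per-stimulus map, each S must match
#'   a tabulated strength exactly (tolerance 1e-9). For a reduced map, the
#'   extremes of the working set get their free drifts and any other S in
#'   \[0, 1\] follows the linear rule.
#' @return drift rate(s).
#' @export
drift_at <- function(map, S) {
  stopifnot(inherits(map, "drift_map"))
  S <- as.numeric(S)
  if (map$kind == "per_stimulus") {
    idx <- vapply(S, function(s) {
      i <- which(abs(map$strengths - s) < 1e-9)
      if (length(i) != 1L)
        stop("no drift tabulated for stimulus strength ", format(s))
      i
    }, integer(1))
    return(map$drifts[idx])
  }
  st <- map$stimuli$strengths
  lo <- st[1L]; hi <- st[length(st)]
  out <- map$k * (S - map$s0)
  out[abs(S - lo) < 1e-9] <- map$mu_low
  out[abs(S - hi) < 1e-9] <- map$mu_high
  out
}

#' Drift-diffusion model parameters
#'
#' Full parameterization of the decision model: mean bound height, bound
#' offset, nondecision time, and a drift map. Conventions (locked by the
#' closed-form choice probability): the upper bound collects sad choices and
#' its magnitude is `bound_mean - bound_offset`; the lower (happy) bound
#' magnitude is `bound_mean + bound_offset`. A positive `bound_offset`
#' therefore lowers the sad bound and makes sad choices more likely.
#' Momentary evidence has variance 1 per second; time is in seconds.
#'
#' @param bound_mean mean of the two absolute bound heights (evidence
#'   units, > 0).
#' @param bound_offset offset of the absolute bound heights (evidence
#'   units, |offset| < bound_mean).
#' @param nd_mean mean nondecision time (seconds, > 0).
#' @param nd_sd SD of the Gaussian nondecision time; defaults to
#'   `nd_mean / 3`.
#' @param drift a [drift_map_per_stimulus()] or [drift_map_reduced()] map.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(bound_mean, bound_offset = 0, nd_mean, nd_sd = NULL,
                       drift) {
  bound_mean <- as.numeric(bound_mean)
  bound_offset <- as.numeric(bound_offset)
  nd_mean <- as.numeric(nd_mean)
  if (!is.finite(bound_mean) || bound_mean <= 0)
    stop("bound_mean must be a positive number")
  if (abs(bound_offset) >= bound_mean)
    stop("|bound_offset| must be smaller than bound_mean ",
         "(both bounds strictly positive)")
  if (!is.finite(nd_mean) || nd_mean <= 0) stop("nd_mean must be positive")
  if (is.null(nd_sd)) nd_sd <- nd_mean / 3
  if (nd_sd < 0) stop("nd_sd must be non-negative")
  if (!inherits(drift, "drift_map")) stop("drift must be a drift_map")
  structure(list(bound_mean = bound_mean, bound_offset = bound_offset,
                 nd_mean = nd_mean, nd_sd = as.numeric(nd_sd),
                 drift = drift),
            class = "ddm_params")
}

#' @rdname ddm_params
#' @param params a `ddm_params` object.
#' @export
bound_sad <- function(params) params$bound_mean - params$bound_offset

#' @rdname ddm_params
#' @export
bound_happy <- function(params) params$bound_mean + params$bound_offset

#' @export
print.ddm_params <- function(x, ...) {
  cat("ddm_params: B_mean =", format(x$bound_mean),
      " dB =", format(x$bound_offset),
      " T0 =", format(x$nd_mean), "s (sd", format(x$nd_sd), ")\n")
  if (x$drift$kind == "reduced") {
    cat("  drift (reduced): k =", format(x$drift$k), " s0 =",
        format(x$drift$s0), " mu_low =", format(x$drift$mu_low),
        " mu_high =", format(x$drift$mu_high), "\n")
  } else {
    cat("  drift (per stimulus):", length(x$drift$strengths), "levels\n")
  }
  invisible(x)
}

#' Serialize / deserialize model parameters
#'
#' Flat key-value text records with an explicit units header. The round
#' trip `read_ddm_params(write_ddm_params(p, f))` is the identity.
#'
#' @param params a [ddm_params] object.
#' @param path file path.
#' @return `write_ddm_params` returns `path` invisibly; `read_ddm_params`
#'   returns a [ddm_params] object.
#' @export
write_ddm_params <- function(params, path) {
  stopifnot(inherits(params, "ddm_params"))
  ln <- c("# units: evidence variance 1 per second; time in seconds",
          paste0("bound_mean=", format(params$bound_mean, digits = 17)),
          paste0("bound_offset=", format(params$bound_offset, digits = 17)),
          paste0("nd_mean=", format(params$nd_mean, digits = 17)),
          paste0("nd_sd=", format(params$nd_sd, digits = 17)),
          paste0("drift_kind=", params$drift$kind))
  if (params$drift$kind == "reduced") {
    d <- params$drift
    ln <- c(ln,
            paste0("k=", format(d$k, digits = 17)),
            paste0("s0=", format(d$s0, digits = 17)),
            paste0("mu_low=", format(d$mu_low, digits = 17)),
            paste0("mu_high=", format(d$mu_high, digits = 17)),
            paste0("stimuli=", paste(format(d$stimuli$strengths, digits = 17),
                                     collapse = ",")))
  } else {
    ln <- c(ln,
            paste0("strengths=", paste(format(params$drift$strengths,
                                              digits = 17), collapse = ",")),
            paste0("drifts=", paste(format(params$drift$drifts, digits = 17),
                                    collapse = ",")))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_ddm_params
#' @export
read_ddm_params <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(key) as.numeric(vals[[key]])
  vec <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  drift <- if (vals[["drift_kind"]] == "reduced") {
    drift_map_reduced(num("k"), num("s0"), num("mu_low"), num("mu_high"),
                      stimulus_set(vec("stimuli")))
  } else {
    drift_map_per_stimulus(vec("strengths"), vec("drifts"))
  }
  ddm_params(bound_mean = num("bound_mean"),
             bound_offset = num("bound_offset"),
             nd_mean = num("nd_mean"), nd_sd = num("nd_sd"), drift = drift)
}
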