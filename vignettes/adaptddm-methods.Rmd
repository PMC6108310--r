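---
title: "Methods: decomposing perceptual adaptation into sensory and decisional components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing perceptual adaptation into sensory and decisional components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prolonged exposure to a stimulus (an *adaptor*) shifts subsequent
judgments away from it. In a happy/sad facial-expression paradigm, the
observer judges morphed faces whose strength $S \in [0,1]$ runs from the
happy prototype (0) to the sad prototype (1); after adapting to a happy
face, ambiguous faces look sadder, and the psychometric function shifts
toward the adaptor. The classical reading is purely sensory. Recording
*response times* alongside choices lets one separate two mechanisms
inside a bounded evidence-accumulation (drift-diffusion) account:

* a **sensory** change — the mean momentary evidence (drift rate) of each
  stimulus shifts toward the adaptor;
* a **decisional** change — the amount of evidence required for each
  choice (the decision bounds) shrinks and becomes asymmetric.

`adaptddm` implements the full analysis pipeline: trial-table handling
and pooling, logistic psychometrics with bootstrap inference, two
drift-diffusion fitting strategies, a calibrated simulator (the study's
raw data are not public, so synthetic data are first-class here), and
the counterfactual partition of the PSE shift into sensitivity, bound,
and interaction components.

## The decision model

Momentary evidence is Gaussian with unit variance per second and mean
$\mu_S$ (positive values favour "sad"). Evidence is accumulated from 0
until it reaches the upper (sad) or lower (happy) absorbing bound. With
mean bound height $\bar B$ and offset $\Delta B$, the bound magnitudes
are $\bar B - \Delta B$ (sad, upper) and $\bar B + \Delta B$ (happy,
lower): this assignment is forced by the closed-form choice probability

$$P(\mathrm{sad}\mid S) =
\frac{e^{2\mu_S \bar B} - e^{-2\mu_S \Delta B}}
     {e^{2\mu_S \bar B} - e^{-2\mu_S \bar B}},$$

whose zero-drift limit is $(\bar B + \Delta B)/(2\bar B)$ — so a positive
$\Delta B$ lowers the sad bound and makes sad choices more likely. The
unconditional mean response time is

$$\bar T(S) = \frac{\bar B\,(2P - 1) - \Delta B}{\mu_S} + \bar T_0,$$

with drift-free limit $\bar B^2 - \Delta B^2 + \bar T_0$. Nondecision
time is Gaussian with SD fixed at one third of its mean (draws at or
below zero are redrawn; at SD = mean/3 these are ~0.13% of draws).

Both formulas are implemented with series branches below
$|\mu| = 10^{-6}$ (third-order, matching the exact branch to ~15
significant digits at the switch) and in overflow-safe form for large
drifts.

### Units

Evidence variance is fixed at 1 per second and time is in seconds, which
makes bounds of order 1 and drifts of order 0–3 for realistic response
times. Published parameter tables in this literature often use other
internal scalings (bounds of order 20); no numeric identity with any
particular table is claimed — only dimensionless quantities (percent
bound reduction, PSE shifts in strength units) are comparable.

## Psychometrics

The simple logistic model is fit in the multiplicative parameterization
$\mathrm{logit}[P(\mathrm{sad})] = \beta_0 (S + \beta_1)$, so the point
of subjective equality is $PSE = -\beta_1$ exactly. We fit by direct
numerical maximum likelihood (a GLM supplies only the starting point)
because the reported estimates and bootstrap SEs should be for these
parameters; a multi-start ladder guards the $\beta_0$–$\beta_1$ ridge.
Perfect separation yields an infinite-slope flag (PSE reported as the
step midpoint); $|\beta_0| < 1$ flags the PSE as unreliable (for flat
data the likelihood is nearly constant in $\beta_1$).

The condition model
$\mathrm{logit}[P(\mathrm{sad})] =
(\beta_0 + \beta_4 L_3)(S + \beta_1 + \beta_2 L_1 + \beta_3 L_2)$
uses indicators $L_1$ (happy-adapted), $L_2$ (sad-adapted), $L_3$
(either); $\beta_2, \beta_3$ are PSE changes and $\beta_4$ the slope
change under adaptation. SEs come from the inverse observed information.

Bootstrap conventions: PSE-shift SEs resample trials within condition
(1,000 resamples by default; the resample count is a package choice: the
reported analyses state the use of bootstrapping but not a count). Across-subject inference follows
the two-level scheme: per iteration one resampled statistic value per
subject, averaged; $10^4$ iterations; the p value is the fraction of
averages on the declared null side of zero with ties counted as one
half. Sidedness is caller-declared.

## Fitting strategy 1: closed forms on cell summaries

The 14-parameter model (11 per-stimulus drifts, $\bar B$, $\Delta B$,
$\bar T_0$) is fit to per-stimulus choice fractions and mean RTs by
maximizing the binomial log-likelihood of choices under the closed-form
probability plus a Gaussian log-likelihood of the observed mean RT with
standard error $\sqrt{\mathrm{var}/n}$ (the simplest defensible reading
of a mean-RT likelihood; the two terms are weighted equally). Transforms
keep the parameters admissible ($\bar B = e^\theta$,
$\Delta B = \bar B\tanh\theta$, $\bar T_0 = e^\theta$); BFGS is
restarted until the objective stops improving because the drift–bound
trade-off ridge is shallow.

**Known limitation (measured, not assumed):** per-cell mean RTs
marginalize away the per-choice RT split that carries most of the
information about $\Delta B$. On simulated data the profile likelihood
is nearly flat in $\Delta B$ (and $\bar T_0$ trades off against it), so
this fit identifies $\bar B$, the drift *profile* (its slope and
linearity across the middle stimuli — its primary analytical use), and
$\bar T_0$ only to ~50 ms. Precise bound/nondecision estimation belongs
to the full-likelihood fit below.

## Fitting strategy 2: Fokker–Planck full likelihood

The density $p(v,t)$ of accumulated evidence obeys
$\partial_t p = -\mu_S \partial_v p + \tfrac12 \partial_v^2 p$ with
$p(v,0) = \delta(v)$ and absorbing conditions at both bounds. We
integrate by Crank–Nicolson finite differences (unconditionally stable,
second order) with:

* grid spacing `dv = span / n_v` (`n_v = 200` for reporting; a validated
  `n_v = 80`, `dt = 4 ms` grid is used inside optimization loops),
  `dt = 1 ms`;
* a **warm-up start**: a raw grid delta makes Crank–Nicolson ring, so the
  march starts from the exact free-diffusion Gaussian after
  $t_0 = \lceil 9\,dv^2/dt\rceil$ steps (the Gaussian then spans ≥ 3
  cells per SD, while the bounds are ~100 cells away, so absorption
  during warm-up is negligible); this replaces the naive
  "all mass on the node at 0" start, which is exact only in the limit
  and numerically noisy;
* **horizon**: `t_max = NULL` picks the horizon from the slowest decay
  eigenvalue $\mu^2/2 + \pi^2/(2\,\mathrm{span}^2)$ so that the
  predicted survivor mass is below $10^{-5}$ (capped at 60 s); a fixed
  horizon is honoured and flagged truncated above a $10^{-4}$ survivor
  tolerance. A fixed default of a few seconds fails exactly for the
  slow cells (wide bounds, weak drift) where accuracy matters. Inside
  the trial likelihood the horizon is instead capped at the largest
  observed response time — the density is never evaluated beyond it, so
  this is exact, not an approximation;
* **flux bookkeeping**: the absorbed mass per step is the exact
  Crank–Nicolson mass balance, split between the bounds in proportion to
  second-order one-sided probability currents — conservation
  ($\sum$upper $+\sum$lower $+$ survivor $= 1$) holds to machine
  precision while the split stays second-order accurate.

Against the closed forms, the solver agrees to better than $10^{-4}$ in
absorbed probability and ~0.01% in mean decision time over the full
$(\mu, \bar B, \Delta B)$ validation grid — an order of magnitude inside
the acceptance tolerances.

RT densities are the first-passage densities convolved with the
truncated-at-zero, renormalized Gaussian nondecision kernel. The trial
log-likelihood interpolates the density linearly at each observed RT,
floored at $10^{-10}$ (RTs beyond the horizon contribute the floor and
are counted; more than 1% warns). The 7-parameter reduced model —
linear drift rule $\mu = k(S - s_0)$ for the middle stimuli, free
drifts for the two extremes (the minimum and maximum of the working
set), $\bar B$, $\Delta B$, $\bar T_0$ — is fit by multi-start
Nelder–Mead with a BFGS polish; $\bar T_0$ lives in a (0.05, 1.0) s box
and a fit on the box edge is flagged. Parameter SEs come from 40–60
bootstrap refits (single-started from the base fit) as the SD across
resamples.

## The synthetic world

Because no raw data are deposited, the generator states the world the
analysis assumes, and its defaults are fixed once:

* 6 subjects, 3 conditions, the fixed 11-level stimulus set
  (0.125, 0.375–0.575 in 0.025 steps, 0.875), ~100 repeats per stimulus
  per condition (~1,100 trials/condition/subject, the per-subject scale
  of the source experiments);
* baseline observer: $\bar B = 1$, $\Delta B = 0$, $\bar T_0 = 0.3$ s,
  drift slope $k = 8$ per strength unit crossing zero at 0.5 (so the
  psychometric slope is $2k\bar B \approx 16$, typical of published
  pooled fits), extreme drifts saturating at $\pm 2.6$ (the documented
  departure from linearity at the ends of the morph line);
* adaptation effects at the scale of the fitted values reported in this
  literature: drift shift 0.16 evidence units toward the adaptor
  (≈ 0.02 strength units of PSE), 10% multiplicative bound reduction,
  bound offset 0.08 lowering the bound opposite the adaptor, ~20 ms
  nondecision reduction; mild lognormal/Gaussian between-subject jitter;
* simulation by Euler–Maruyama at 0.5 ms with the
  Broadie–Glasserman–Kou barrier continuity correction
  ($0.5826\sqrt{dt}$ per bound), which removes the leading
  discrete-monitoring bias; calibration against the closed forms at
  $n = 20{,}000$/cell and a step-halving test are part of the suite.

What the generator does **not** emulate: within-block adaptation
dynamics (conditions are stationary), sequential effects, lapses,
non-Gaussian nondecision time, trial-to-trial drift or start-point
variability. A green suite therefore establishes that the pipeline
recovers the truth *of this model class at these scales* — not that the
model class is right for any particular dataset.

Balanced designs are emulated by recentring the middle stimuli of each
subject/condition on the model-implied PSE (the root of the closed-form
choice probability at 0.5), extremes kept, clipped to [0, 1].

## Pooling across subjects

Trials with RT > 5 s are outliers. Fixed-range designs pool by
concatenation. Balanced designs align first: per condition, each
subject's strengths are shifted by (group-average PSE − subject PSE),
then binned into 19 equal-width bins over the pooled shifted range
(half-open, top bin closed), bins with contributions from fewer than
$\lceil \tfrac23 n_{\mathrm{subjects}} \rceil$ subjects are dropped, and
retained trials adopt their bin center. Equal-width binning, the
strictly-fewer-than reading of the two-thirds rule, a "contribution"
meaning ≥ 1 trial, and counting subjects per condition are package
choices the source leaves open; the bin report records them.

## Contribution partition

With fitted parameters for the unadapted and an adapted condition, the
model predicts $P(\mathrm{sad})$ per stimulus (closed form — it agrees
with the solver to $10^{-3}$ and makes the partition deterministic); the
simple logistic is fit to the predictions by unweighted least squares on
the logit scale and its $-\beta_1$ is the expected PSE. Then

* $C_S$: expected shift with unadapted bounds and adapted drifts;
* $C_B$: expected shift with adapted bounds (the pair $\bar B, \Delta B$
  moved together) and unadapted drifts;
* $C_{B\times S} = \mathrm{total} - C_S - C_B$ (the residual, hence the
  three parts add up exactly);
* overall sensitivity/bound contributions split the interaction evenly.

Nondecision time is excluded: it cannot move the psychometric function.

## Numerical choices not covered above

* Logistic ML: 5+ starts, Nelder–Mead then BFGS, relative tolerance
  $10^{-12}$; probabilities clipped at $10^{-12}$ inside likelihoods.
* Model-free evidence profiles clip $P$ to $[1/(2n), 1 - 1/(2n)]$ before
  the logit and flag clipped cells.
* Seeds: every stochastic routine takes an explicit seed, sets the RNG
  locally, and restores the caller's RNG state; per-(subject, condition)
  simulation seeds are derived from a master seed below $2^{31}$.
* The empty-count logistic cells use fractional counts when handed
  model-predicted probabilities, so a fit to exactly-generated summaries
  has its optimum exactly at the generating parameters.

## Known limitations

* The Palmer-style fit's $\Delta B$ ridge, described above.
* The FPE fitting grid inside optimizers trades ~$10^{-4}$ probability
  accuracy for speed; reported solves use the fine grid.
* Bin geometry for balanced pooling is a stated convention, not a
  recovered fact.
* The pipeline treats conditions as independent stationary processes;
  no attempt is made to model the build-up of adaptation within blocks.
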