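---
title: "From residual tumor burden to recurrence curves: the regrowr model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From residual tumor burden to recurrence curves: the regrowr model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrowr)
library(dplyr)
```

## The model

After a cytoreductive treatment (radiotherapy, surgery, some
chemotherapies) each patient is left with some residual *viable* tumor
burden $B_V$ — the subset of remaining tumor volume still capable of
regrowth. `regrowr` simulates what happens next. The burden evolves as

$$\frac{dB_V}{dt} = f(B_V)\left(\frac{B_V}{\varepsilon_V} - 1\right),$$

where $f$ is a classic tumor growth law and $\varepsilon_V$ (cc) is a
*minimum viability threshold*: the smallest burden that can survive in
the post-treatment tissue environment, analogous to an Allee extinction
threshold in population ecology. The factor $(B_V/\varepsilon_V - 1)$
makes $\varepsilon_V$ an unstable equilibrium. Burdens below it decay
deterministically to zero — the patient is cured; burdens above it
regrow until they cross a *detection threshold* $\omega_d$ (cc), at
which point the recurrence is clinically detectable. The per-patient
recurrence indicator is the step function $R_i(t) = \mathbf{1}\{B_V(t)
\ge \omega_d\}$, and a cohort of $n$ patients yields the recurrence
curve $R(t) = \tfrac{1}{n}\sum_i R_i(t)$; the package works with the
event-free (Kaplan–Meier-style) curve $1 - R(t)$.

Because a whole treated population is heterogeneous in its residual
burden, the cohort is modelled by a lognormal distribution of $B_V$.
The geometry of the event-free curve then decomposes cleanly:

* the **y-intercept** is the fraction of the distribution below
  $\omega_d$ at $t = 0$ (everyone above is already detectable);
* the **plateau** is the cure fraction — the mass below
  $\varepsilon_V$, i.e. the lognormal CDF at the viability threshold;
* the **rate of the drop** between the two is governed by the regrowth
  rate $\lambda$.

The model addresses recurrence only. It is not a model of overall
survival, and no censoring or surveillance schedule is simulated: the
monitoring is assumed continuous and perfect, so a recurrence is
declared the instant the trajectory touches $\omega_d$.

## Growth laws

Three forms of $f$ are implemented:

| law | $f(V)$ | parameters |
|---|---|---|
| exponential | $\lambda V$ | $\lambda$ (per day) |
| logistic | $\lambda V (1 - V/K)$ | $\lambda$, carrying capacity $K$ (cc) |
| Gompertz | $\lambda V \ln(K/V)$ | $\lambda$, $K$ |

In the regime that matters for recurrence — burdens far below any
carrying capacity — logistic growth is indistinguishable from
exponential: at $V = \omega_d = 0.056$ cc with $K = 13.8$ cc the
logistic attenuation factor is $1 - \omega_d/K = 0.996$. Gompertz
growth is *superexponential* there: its rate multiplier $\ln(K/V)$
evaluates to $\ln(13.8/0.056) \approx 5.51$ at the detection threshold,
so Gompertz cohorts recur several-fold faster than exponential ones at
the same $\lambda$ and their curves have inverted curvature. (Quoted
summaries of this factor sometimes print values nearer 5.4, consistent
with evaluating it at a sampled rather than the mean carrying capacity;
`growth_rate()` always evaluates the formula exactly at the volume you
give it.) For the saturating laws each virtual patient can carry their
own $K$, sampled from its own lognormal distribution.

The viability factor can be switched off
(`viability_term = FALSE`), giving plain $f(V)$ dynamics in which
$dV/dt > 0$ everywhere, the cure class is empty, and every simulated
curve eventually reaches zero — a useful contrast that isolates what
the threshold contributes.

For the exponential law the full dynamics form a Bernoulli equation
with exact solution

$$B_V(t) = \left[\frac{1}{\varepsilon_V} + \left(\frac{1}{B_0} -
\frac{1}{\varepsilon_V}\right)e^{\lambda t}\right]^{-1},$$

which gives closed forms for the trajectory
(`exponential_burden_at()`), the recurrence time
(`exponential_recurrence_time()`), and the finite *blow-up time* above
which the solution diverges. These closed forms are both the fast path
used for exponential-law cohorts and the independent oracle against
which the numerical integrator is tested.

## Lognormal parameter conventions

Burden distributions in the clinical literature are reported under
more than one lognormal parameterisation, and misreading one for
another silently changes every downstream curve. `burden_dist()`
therefore requires the convention to be stated explicitly:

* `log_space` — location and scale of $\ln B_V$, e.g.
  $\mathrm{lognormal}(\mu = -8.0, \sigma = 6.8)$;
* `arithmetic` — arithmetic mean and standard deviation in cc, e.g.
  mean $= 0.05$ cc, sd $= 0.06$ cc;
* `mean_logsd` — arithmetic mean in cc with the spread in log space,
  the natural reading of "mean $= 13.8$ cc, sd $= 0.5$" for a quantity
  spread over orders of magnitude (0.5 cc as an arithmetic sd would
  contradict that spread).

Conversions between conventions are exact (`convert_convention()`
round-trips to floating-point precision), and `fraction_below()`
evaluates the exact CDF used for cure fractions and intercepts.

## Numerical choices

* **Integration.** Trajectories and non-exponential recurrence times
  use deSolve's `lsodar` (adaptive step with root finding) at
  `rtol = 1e-10`, `atol = 1e-14` cc. These tolerances keep trajectories
  within a relative error of $10^{-6}$ of the exact Bernoulli solution
  even on the steep approach to blow-up, where looser settings leave
  errors just above that level.
* **Event detection.** Recurrence times are located by root-finding on
  $B(t) - \omega_d$ inside the solver, never by inspecting a fixed
  output grid, so they are grid-independent.
* **Blow-up.** Above $\varepsilon_V$ the exponential-law dynamics reach
  infinity in finite time. Trajectory integration stops at a ceiling
  ($10^4$ cc for the exponential law, $10K$ otherwise) and flags the
  truncation; recurrence detection always fires long before the
  ceiling because $\omega_d$ is orders of magnitude below it.
* **Degenerate inputs.** $f(0) = 0$ exactly for every law; the Gompertz
  log argument is floored at $10^{-30}$ cc to avoid overflow (no
  trajectory needs smaller values before being classified cured);
  $\varepsilon_V = 0$ with the viability factor enabled is rejected as
  a configuration error with instructions to disable the factor — that
  is the $\varepsilon_V \to 0$ limit of the model.
* **Tie-breaks.** $B_0 = \varepsilon_V$ is classified as cure (an
  unstable equilibrium strictly below $\omega_d$ never detects);
  $B_0 = \omega_d$ recurs at $t = 0$ (detection uses $\ge$). Both are
  measure-zero under continuous sampling.
* **Horizon.** The default follow-up is 7,300 days (20 years). A
  progressor whose crossing lies beyond the horizon is flagged
  `beyond_horizon`, distinct from cure, so aggregation can count it as
  non-recurrent within follow-up without misstating the asymptote.
* **Curves.** $R(t)$ is computed exactly from sorted event times on a
  uniform grid (default 1-day step), not from binned histograms. The
  drop-rate proxy reported by `curve_features()` is the time at which
  the curve first comes within 0.01 of its plateau — a concrete,
  testable stand-in for the qualitative notion of "rate of drop-off".
* **Replicate bands.** Pointwise empirical quantiles (2.5/97.5%) with
  linear interpolation on Weibull plotting positions, which degrade
  gracefully to min/max at two replicates.

## Reproducibility contract

Every stochastic operation takes an explicit integer seed and restores
the caller's RNG state. Sampling is *prefix-stable*: with the same
seed, the first $k$ patients of a cohort are identical whatever the
cohort size, so enlarging a study never reshuffles earlier patients.
Parameter sweeps and arm comparisons reuse one sampled cohort across
all sweep points and arms (common random numbers), so the differences
they report are parameter-driven, not sampling noise.

## Calibration

`fit_parameters()` fits the three global parameters $(\lambda,
\omega_d, \varepsilon_V)$ to one or more observed event-free curves
(time, fraction event-free), with the burden distributions treated as
fixed inputs. Design choices:

* **Loss.** Unweighted least squares on event-free fractions at the
  observed time points, summed across arms — the simplest metric
  consistent with minimising curve error. Weighting is deliberately not
  a default.
* **Search.** Nelder–Mead over $(\log\lambda, \log\omega_d,
  \mathrm{logit}(\varepsilon_V/\omega_d))$, which enforces
  $0 < \varepsilon_V < \omega_d$ by construction. The replicate-mean
  loss is only piecewise-smooth, so a derivative-free simplex is the
  right tool; default budget 500 iterations, relative tolerance
  $10^{-6}$.
* **Common random numbers.** The burden matrices ($n$ patients
  $\times$ `n_reps` replicates per arm) are drawn once per fit, so the
  loss surface is exactly deterministic and the fit reproducible under
  its seed. With the exponential law's closed-form recurrence times,
  one loss evaluation is a few vectorised operations.
* **Identifiability.** The cure fraction — the CDF of each arm's
  distribution at $\varepsilon_V$ — is well identified by the plateau;
  $\varepsilon_V$ itself is only weakly identified when the burden
  distribution is very wide in log space, since the CDF then changes
  slowly per log-unit of threshold. $\lambda$ is identified only by
  observation times that resolve the drop-off: with very fast regrowth,
  yearly observations see an already-flat curve and $\lambda$ is
  unconstrained from above. Parameter-recovery checks in the test suite
  therefore observe monthly over the first two years. Because the loss
  at the generating parameters is floored by replicate (binomial)
  noise, recovery tests assert closeness to that noise floor, never
  exact zero.
* Non-exponential growth laws are available throughout the simulator
  but not in the fit routine, whose speed and determinism rest on the
  closed form; calibrating a saturating law would need the ODE path
  inside the loss and is left as an extension.

No formal uncertainty quantification of the fitted parameters
(bootstrap, profile likelihood) is provided, and no between-arm
statistical test is computed — arm comparisons report feature deltas
only; a log-rank hook is a documented extension point.

## Scenarios and the fixture generator

`load_scenario()` ships the demonstration parameter sets as named
built-ins (`workflow_demo`, `baseline`, `trial_arms`,
`growth_laws`, `rtog9003_like`) and reads user scenarios from YAML
with the same shape. Validation is strict: every constraint
($\varepsilon_V < \omega_d < K$) is checked at load time and unknown
keys are errors, not warnings — a typo in a parameter name must never
silently fall back to a default. (One YAML quirk dictated a naming
choice: a bare key `n` is a YAML 1.1 boolean, so the cohort-size key is
`n_patients`.)

Two scenario details are package choices rather than given quantities.
The two-arm `trial_arms` scenario states the arm means (0.03 and
0.05 cc) but no scale; the scale is a free parameter defaulting to 1.0
in log space, and only ordering conclusions (the lower-mean arm
plateaus higher) should be drawn from it, since they hold at any equal
scale. The carrying-capacity distribution of `growth_laws` reads
"mean 13.8 cc, sd 0.5" under the `mean_logsd` convention, as discussed
above.

`generate_fixture()` writes per-arm cohort and curve CSVs plus a
metadata YAML recording every generating parameter and the seed;
outputs are byte-identical under a fixed seed. The generated curves
emulate the *shape* features of real locoregional-control data —
intercept, drop, cure-fraction plateau — under the model's own
assumptions: a unimodal lognormal burden distribution, one shared
$\lambda$ across patients, continuous monitoring, no censoring, no
competing risks. Passing tests against these fixtures therefore
validate internal consistency and the stated mathematics, not the
model's adequacy for any particular clinical dataset; fitting real
registry data would additionally require surveillance-schedule and
censoring handling that is out of scope here.

## Problem sizes used in the checks

The package's own test suite exercises: oracle equivalence on 100
random parameter sets; cure-fraction plateaus at $n = 10^4$ patients;
sweep monotonicities at $n = 1000$; growth-law orderings at the
$n = 50$ demonstration cohort; replicate bands at $n = 265$ with 100
replicates; and parameter recovery with two arms of 500 patients, 50
replicates, over five seeds. These sizes were chosen so each check's
sampling error is small against the tolerance it asserts.

## A worked run

```{r, eval = FALSE}
library(regrowr)

dist <- burden_dist("arithmetic", 0.05, 0.06)   # residual burden, cc
model <- regrowth_model(growth_law("exponential", lambda = 0.0015),
                        eps_V = 0.01, omega_d = 0.056)

curve <- sample_cohort(dist, n = 1000, seed = 1) |>
  simulate_recurrence(model) |>
  cohort_curve()

curve_features(curve)
fraction_below(dist, 0.01)   # the exact cure fraction the plateau tracks
autoplot(curve)
```

## Known limitations

Unimodal lognormal burden distributions only; one $\lambda$ per cohort
(no patient-level covariates); recurrence only, never overall survival;
no censoring, competing risks, or surveillance schedules (a visit-grid
hook exists in the recurrence layer but is off by default); calibration
assumes the exponential law; fitted parameters come without uncertainty
intervals.
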