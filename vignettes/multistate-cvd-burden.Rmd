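---
title: "Multistate modelling of cardiovascular disease burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate modelling of cardiovascular disease burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msexpect)
```

## The model and its assumptions

`msexpect` implements an incidence-based discrete-time Markov chain
illness–death model for cardiovascular disease (CVD). The state space has
three states — CVD-free (`FREE`), `CVD`, and `DEAD` — with irreversible
disease entry: once a first CVD event has occurred, the person remains in
the CVD state until death. Death is all-cause and is the single absorbing
state; cause-specific mortality is out of scope because a discrete-time
chain of this form admits exactly one absorbing state.

Age is measured in months on a quarterly grid from 480 to 1,200 months
(ages 40–100): 241 grid points, 240 intervals of 0.25 years. The quarterly
step matters substantively: with annual steps, many first CVD events that
fall in the same year as death would be missed in the state assignment.
State is assigned at grid points; a transition "happens" in the interval
between two consecutive points.

The model is a *period* model: all metrics are for a synthetic cohort that
lives its entire life under a single calendar period's transition
probabilities. Five five-year periods (1996–2000 … 2016–2020) are carried
as a categorical covariate. The Markov assumption — next state depends only
on current state, age, period, and stratum — keeps the machinery tractable;
it is adequate for the population-level quantities computed here
(probabilities and means), though not for individual trajectory prediction
(e.g. duration-in-state dependence of CVD mortality is not modelled).

## Transition probability estimation

For each transient origin state the one-step probabilities follow a
multinomial logit in centered/scaled age in months (default
`(age − 840)/120`), its square, and period dummies with the first period as
reference. Origin FREE competes three destinations (stay, CVD, death);
origin CVD degenerates to a binary stay-or-die logit. Two conventions
deserve note:

- **Reference destination.** The reference is each origin's "stay" state
  (FREE→FREE, CVD→CVD). Describing the reference as a single global state
  is not well defined for the CVD origin, where CVD is both the origin and
  a possible (stay) outcome; the stay-reference convention is unambiguous,
  and predicted probabilities are invariant to the choice of reference, so
  nothing of substance depends on it.
- **Per-origin fitting.** The likelihood factorizes over origin states, so
  fitting one model per origin is exactly equivalent to a joint fit with
  origin interactions, and simpler. Period effects are origin- and
  destination-specific.

Fitting aggregates person-period rows to covariate-cell counts (identical
likelihood, far cheaper), takes a `nnet::multinom()` warm start, and
polishes with a small in-package Newton–Raphson on the grouped likelihood.
The polish is not cosmetic: it takes the optimum to near machine precision,
which is what makes predicted probabilities numerically invariant (to
1e−10 and better) under reparameterization of the age scaling, and makes
the analytic-Hessian standard errors exact at the optimum. No
regularization is applied; perfect separation (a destination never
observed, or a diverging coefficient) is surfaced as an error naming the
offending destination/covariate rather than silently penalized.

Stratified analyses refit the model per subpopulation: the total
population; women and men (not controlling for education); and the six
gender × education strata (not controlling for the other variable). Each
stratum's probabilities thus describe that subpopulation as it actually
exists — the stratifying variable is never entered as a covariate.

## Metric conventions

All metrics derive from the transition-probability array by absorbing-chain
arithmetic, with three explicit conventions (each pinned by a closed-form
test):

- **Occupancy counting.** Expectancies count occupancy at *interval
  starts*: each occupied start contributes 0.25 years. A deathless chain
  from age 40 therefore gives exactly 60.0 years.
- **Horizon truncation.** The chain ends at 1,200 months; survivors at age
  100 contribute nothing further. This biases expectancies downward
  slightly at extreme ages and is the price of staying on the observed
  grid.
- **Onset age.** The first-passage age is assigned to the *destination*
  grid point of the transition interval — the assessment at which the event
  is first observed. Onset confined to the first interval gives exactly
  40.25 years.

The onset-age mean conditions on being CVD-free at exactly age 40
(prevalent cases excluded), matching the synthetic-cohort reading of the
period design. Undefined conditional quantities (mean onset when lifetime
risk is zero; gain shares when the total gain is zero) return `NA` with a
warning rather than raising, so batch tables never abort.

Education standardization mixes *transition probabilities*, not final
metrics: `p_adj = Σ_e w_e p_e` entrywise, with weights equal to the pooled
person-period education shares over the whole window. A convex combination
of row-stochastic rows is row-stochastic, so the standardized array is a
valid probability object. Weights are age-marginal (one triple per
context); `standardize_transition_probs()` accepts any
`education_weights`, so age-specific weighting can be layered on by calling
it per age band if ever needed.

## The synthetic register generator

Real register data of this kind cannot be redistributed, so the package
ships a generator whose defaults define the study conditions for all tests.
Each simulated person turns 40 in a calendar quarter drawn uniformly from
1936–2020, starts CVD-free at 480 months (optionally in CVD with stated
probability), and advances quarter by quarter under a known parametric
transition model until death or age 100. With the register-entry
observation rule, only person-quarters inside the 1996–2020 window are
emitted — people who turned 40 before 1996 are left-truncated and
contribute only their in-window old ages, which reproduces the age × period
coverage of an administrative register. Because simulated histories are
complete from age 40, the look-back needed in real registers to verify that
"CVD-free" really means no prior diagnosis is trivially satisfied.

The baseline hazards were calibrated once from Gompertz-style reasoning:
annual CVD-free mortality rising from roughly 0.1% at 40 to ~30% at 100;
annual CVD incidence from ~0.4% to ~8%; CVD mortality about 2.5× the
CVD-free level at equal age; period effects lowering mortality by ~0.1 per
period step on the logit scale (and incidence by half that), so later
periods live longer with later onset. On these defaults the model produces
Finland-like magnitudes (lifetime risk ~64%, onset ~70, TLE at 40 ~42–45
years, ~79% CVD-free). The four scenarios are: `baseline` (above, with
gender and education carried as labels but exchangeable), `no_cvd` (onset
impossible), `constant_hazard` (age- and period-constant probabilities,
for pooled-fraction and closed-form checks), and `strong_gradient`
(baseline plus higher male incidence/mortality, logit shifts +0.30/+0.45,
and a protective education gradient, −0.25/−0.50 for secondary/tertiary).
Keeping the baseline strata exchangeable makes the total-population fit
exactly correctly specified, which is what a parameter-recovery study
needs; the education gradient and the upward education drift that the
standardization analysis requires live in `strong_gradient` with a
per-period entry distribution moving tertiary shares from 20% to 40%.

Randomness is consumed in a fixed, documented order (entry characteristics,
then one uniform per alive person per age step, age-major): output is
byte-identical for a given seed and config, for either output format. What
the generator does *not* emulate: hospital-episode or diagnosis-code
structure, emigration/loss to follow-up (no mechanism is exposed rather
than guessing at one), cohort effects beyond the period regime, and
duration-dependence of CVD mortality. Passing tests therefore demonstrate
the correctness of the estimation and life-table machinery under the
model's own assumptions — not robustness of the substantive findings to
violations of those assumptions in real registers.

## Validation strategy and problem sizes

Three independent routes check the computational core:

1. **Closed forms.** Constant-probability chains have truncated-geometric
   lifetime risk, expectancies and conditional TLE; the implementation
   matches them to 1e−10. The onset-age constant is computed by brute-force
   first-passage summation in the test itself.
2. **Microsimulation oracle.** `microsim_metrics()` recomputes every metric
   by simulating trajectories from the same probability array; matrix and
   simulation agree within Monte-Carlo error (3 SE at n = 200,000 in the
   acceptance checks).
3. **Parameter recovery.** Fitting on generated registers recovers the
   generating coefficients within 3 estimated standard errors at 500,000
   persons, and mean bias over 50 replicates of 100,000 persons is within
   Monte-Carlo error of zero.

The routine test suite uses smaller cohorts (hundreds to tens of
thousands) chosen to keep the full suite around five minutes while leaving
comfortable statistical margins; the acceptance checks run the sizes above.

## Known limitations

- Period (synthetic-cohort) metrics do not describe any real birth cohort.
- No variance or confidence-interval estimation for the metrics.
- The horizon truncation slightly understates expectancies for subgroups
  with non-trivial survival past 100.
- The generator's period regime is the only calendar structure; there are
  no seasonal or within-period trends.
- Printed-table reporting operations use the published (rounded) cells, so
  gaps computed from them inherit display rounding; pipeline outputs use
  unrounded values throughout and round only for display.
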