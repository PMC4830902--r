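---
title: "Methods: Bass diffusion modelling of survey-measured adoption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bass diffusion modelling of survey-measured adoption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bassadopt)
```

## The model and its assumptions

bassadopt models the cumulative adopted fraction of a technology with the
Bass mixed-influence diffusion model. Non-adopters face the hazard
$p + q\,F(t)/m$, where $p > 0$ is the external (innovation) coefficient —
adoption pressure independent of how many have adopted, such as
advertising, availability, or policy — and $q \ge 0$ is the internal
(imitation) coefficient — social contagion proportional to the installed
base. Integrating gives the closed form

$$F(t) \;=\; m\,\frac{1 - e^{-(p+q)t}}{1 + (q/p)\,e^{-(p+q)t}},$$

with $F(0)=0$ and $F \to m$. The package fixes the market potential at
$m = 1$ by default: the motivating application measures the adopted share
of the whole adult population and the survey percentages are of that full
weighted population; $m$ remains a parameter for generality but is never
estimated. When $q > p$ the curve is S-shaped with an inflection at
$t^* = \log(q/p)/(p+q)$; at $q \le p$ (including the tie $q = p$, which we
classify as inverse-J because the S-curve regime requires imitation to
strictly dominate) adoption decelerates from the start.

Time is measured as $t = \text{calendar year} - \text{start year}$, with
zero adoption at the start year. This convention reproduces the published
model estimates for the 2001 and 2004 introduction-date scenarios to
within about 0.1 percentage points; the 2007 scenario appears to have been
computed with an off-by-one convention and is treated as less reliable
throughout. We standardize on one convention rather than per-scenario
conventions.

A related precision convention: published coefficient tables round $p$ to
3 decimals, which at $p \approx 0.002$ destroys most of its information
(dividing the printed $q = 0.268$ by the printed $p = 0.002$ gives 134,
not the printed ratio 117.040). Wherever published coefficients are
re-evaluated, the $q/p$ ratio is treated as the authoritative anchor and
$p = q / \text{ratio}$, because forward evaluation with ratio-anchored $p$
reproduces the published per-year estimates and rounded $p$ does not.

## From survey records to an adoption series

The unit of analysis is the joint response to two binary items: tracked
personal health information online, and communicated electronically with a
provider. `tabulate_adoption()` forms sampling-weight-weighted counts of
the four joint categories; the adoption fraction for a year is the
weighted both-yes share. Missing item responses default to listwise
exclusion (`missing_policy = "exclude"`); the source analysis does not
state its handling, and exclusion is the conservative choice because it
imposes no assumption on nonrespondents. `treat_as_no` is provided for
sensitivity. Only point estimates are produced: replicate-weight variance
estimation is out of scope.

## Constrained estimation of (p, q)

`bass_fit()` minimizes the sum of squared residuals between $F$ and the
observed fractions (fraction scale), subject to box bounds
($p \in [10^{-6}, 0.5]$, $q \in [0, 1]$) and the feasibility band: every
absolute residual must be at most `band` (default 0.02, i.e. 2 percentage
points). The absolute reading of the band is deliberate — a relative
(2%-of-observed) reading is contradicted by the published residuals, which
reach 0.8 points at an observed 9.8%. SSE is the standard Bass-fitting
objective; the original spreadsheet analysis names its solver but not its
objective, so small differences between refit and published coefficients
are expected, and all validation against published numbers anchors on
forward evaluation of the published coefficients instead.

The optimizer is built for bit-reproducibility rather than speed: a
deterministic $40 \times 40$ grid over $(\log p, q)$ is scanned, the five
best grid points are refined with bounded Levenberg-Marquardt least
squares (`minpack.lm::nls.lm`, `ftol = ptol = 1e-12`), and the best
refined pair wins. Levenberg-Marquardt was chosen over a derivative-free
polish because the residuals are smooth and it converges quadratically on
zero-residual problems — exactly identified two-point fits come back with
residuals at machine precision. If the least-squares minimizer violates
the band, an exterior-penalty search from the same starts looks for the
best feasible pair; when none exists in the bounds the unconstrained
minimizer is returned with `feasible = FALSE` and a warning, never an
abort, so sensitivity tables over many start years always complete.
Degenerate (non-increasing) series are fitted the same way, with a
poor-identifiability warning.

## Start-date sensitivity and the stability check

Because the introduction year of a diffuse, consumer-driven technology is
genuinely uncertain, `bass_sensitivity()` refits over candidate start
years (2001, 2004 and 2007 in the motivating analysis). Later assumed
starts force the same observed growth into fewer years, so fitted $p$
rises and $q$ (and $q/p$) falls — the monotone pattern the package's tests
assert. Under our single time convention the 2007-start refit collapses to
the $q = 0$ boundary and cannot stay inside the 2-point band, consistent
with the off-by-one issue noted above; its row is reported and flagged
infeasible rather than suppressed.

`bass_stability()` refits with the last survey round omitted and reports
the absolute change of the horizon-year forecast. An important structural
caveat: with two free parameters, dropping the third point of a
three-point series leaves an exactly identified system, and the refit is
the *unique interpolant* of the two remaining points. For the observed
series the interpolant is a much shallower curve (the omitted 2013 point
carries all the evidence of acceleration), so the 2020 forecast moves by
tens of percentage points. The function reports this honestly; a
spreadsheet solver warm-started at the three-point solution with loose
convergence can report near-zero movement for the same exercise, but that
is an artifact of not converging, not a property of the model. Stability
conclusions from two-point refits of two-parameter models should be
treated with corresponding skepticism.

## The policy-milestone curve

`fit_policy_targets()` fits the same constrained model through policy
milestone fractions as if they were observations. The default milestone
set is the two consumer electronic-communication targets — 5% by 2014 and
10% by 2017 — with a 2004 start; the exact milestone set behind the
published policy-curve coefficients is unstated, so it is an explicit
configurable input rather than a guess baked into the code. The package's
checks therefore assert the published *orderings* (the policy curve has
lower $p$ and higher $q/p$ than the 2004 observed-data fit, and lower
uptake than every observed-data scenario at the horizon) rather than the
printed policy coefficients themselves. Similarly, the claim that the
best scenario exceeds 75% adoption by 2020 is not reproducible from any
published coefficient set under the convention that reproduces the
per-year estimates (closed-form 2020 values fall near 50-65%);
`threshold_year()` and the forecast trajectories expose the computed 2020
values rather than tuning toward the claim.

## The synthetic survey generator

`generate_population()` emulates the structure of the motivating survey:
repeated weighted cross-sections (defaults: rounds 2008/2011/2013, 10,000
respondents per round, weighted population rising from 153 to 182 million)
in which each respondent falls in one of the four joint categories with
probabilities (Bass truth at that year, a communication-only rate, a
tracking-only rate, remainder). Default single-item rates span the 8-13%
and 9-11% bands observed in the real tabulations, and the default truth
$(p = 0.007,\ q = 0.214,\ \text{start } 2004)$ is the contagion-dominated
regime the observed data display. Weights are gamma-distributed with unit
mean (dispersion = coefficient of variation, default 0.5) and rescaled to
the round's target population; `noise = "binomial"` draws category counts
from a multinomial per round (noise on the joint category, not per item,
because the joint category is the analysis object), while
`noise = "none"` allocates expected counts by largest remainder and
rescales category weight mass so weighted shares equal the design
probabilities exactly up to count rounding. Randomness is a single seeded
stream with fixed sub-stream order (weights, then categories, year-major),
so a given seed is bit-reproducible; the session RNG state is restored on
exit.

What the generator does *not* emulate: the real survey's stratified
sampling frame, mode effects, item and unit nonresponse mechanisms, and
replicate-weight structure. Passing recovery tests therefore demonstrate
that the estimation machinery is correct under clean multinomial sampling
at realistic sizes — not that real-survey complications are harmless.

`recovery_experiment()` quantifies estimator behaviour: replicate $r$ uses
seed $\text{seed} + r$, runs generation, tabulation and fitting end to
end, and reports per-replicate estimates, bias, RMSE and the feasible
fraction.

## Numerical choices and problem sizes

Grid resolution $40 \times 40$ with 5 refinements balances robustness
against the double-optimum risk of the Bass SSE surface at trivial cost
(a fit takes well under a second). Feasibility is checked with a
$10^{-12}$ slack on the band so boundary solutions are not misflagged.
Percentages are rounded only at report boundaries (2 decimals, mirroring
the published tables); all internal comparisons use full precision. The
test suite exercises noise-free recovery across a $3 \times 3$ grid of
truths, binomial-noise recovery at 10,000 respondents per round with 100
replicates (about half a minute), and smaller replicate sets elsewhere —
sizes chosen to make Monte-Carlo conclusions stable while keeping the
whole suite fast.

## Known limitations

- $m$ is fixed, not estimated; with three observed points a free $m$
  would be weakly identified at best.
- No uncertainty quantification for $(p, q)$ — the source analysis
  reports none, and bootstrap/jackknife machinery for complex surveys is
  out of scope.
- Three observations fitting two parameters leave essentially no room for
  model criticism; the start-date sensitivity analysis is the honest
  substitute.
- The generalized Bass model (covariates), multi-generation variants, and
  Gompertz/logistic alternatives are not implemented.
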