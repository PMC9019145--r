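---
title: "Thermal metabolic phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal metabolic phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermetab)
```

## Scope

`thermetab` implements the complete chain from raw respirometry oxygen
traces to population-level inference for thermal metabolic phenotyping of
small fish: mosquitofish-like cohorts drawn from geothermally warmed
("warm-source") and ambient streams, acclimated in the laboratory to 20 or
30 °C, and measured for standard, routine and maximum metabolic rate (SMR,
RMR, MMR) plus two behaviours (refuge-emergence latency, right-censored at
600 s, and seconds of activity in a 5-minute window). Because the archived
field data are not bundled, every stage is paired with a synthetic-data
generator whose ground truth is known exactly, so the package can
demonstrate — and its tests verify — that each stage recovers what it
claims to recover.

## The measurement model

Oxygen consumption in a closed, stirred respirometer follows

$$\dot M O_2 = (V_r - V_f)\,\frac{\Delta C_{wO_2}}{\Delta t},$$

with chamber volume $V_r$ and fish volume $V_f$ in ml and the oxygen
concentration in mg L$^{-1}$ ($\equiv$ µg ml$^{-1}$), so rates come out in
µg O$_2$ min$^{-1}$ with no hidden unit conversions (mass is carried in
mg). The slope $\Delta C_{wO_2}/\Delta t$ is estimated by ordinary least
squares over each closed measurement window; for overnight
intermittent-flow cycles (5 min flush, 30 s wait, 15 min measure) the first
30 s of each window are discarded as a mixing transient, while the single
static RMR (15 min) and post-chase MMR (5 min) windows are used in full.

Background (microbial) respiration is measured in water-only chambers
before and after every trial and assumed to grow linearly in time between
those two anchors; each cycle's rate is corrected by the interpolated
background at the cycle midpoint, clamped at the endpoints outside the
anchor interval. Because an OLS slope over a symmetric window equals the
derivative at the window centre for any quadratic path, a truly linear
drift is corrected *exactly* — the trace simulator integrates its signal
with the midpoint rule precisely so that this exactness is testable at
numerical precision.

SMR is the mean of the lowest 10 % of cycle rates after discarding
outliers beyond ±2 SD of the cycle mean. Two readings of that rule are
possible; the default screens globally first (over all cycles) and then
takes the lowest decile of the survivors, which prevents a single spike
from inflating the subset SD. The alternative (decile first, screen
within) is exposed as `outlier_order = "subset"`. The decile count is
`ceiling(0.1 n)`, never less than one. Negative blank-corrected rates are
kept and flagged rather than floored, so cycle-level variability
statistics remain unbiased. Aerobic scope is MMR − SMR and factorial scope
MMR/SMR; an MMR at or below RMR or SMR raises a `chase_underestimate`
flag, since an exhaustive chase can fail to elicit a true maximum.

## Scaling and temperature sensitivity

Allometric exponents $b$ come from least-squares fits of $\log_{10}$ rate
on $\log_{10}$ mass, separately per thermal history × acclimation
temperature. Activation energies use the Arrhenius construction on
mass-normalized rates $\dot MO_2 \times M^{-b}$ against $1/kT$
($k = 8.62\times10^{-5}$ eV K$^{-1}$, $T$ in Kelvin, °C + 273.15 exactly).
With only two acclimation temperatures the slope is the two-point form

$$E_a = \frac{\ln R_2 - \ln R_1}{1/kT_2 - 1/kT_1},$$

whose sign is *not* flipped: rates that increase with temperature give
negative $E_a$. The natural log is used on the Arrhenius axis (the usual
metabolic-theory convention); $\log_{10}$ is reserved for allometry.

Which exponent enters $M^{-b}$ is a genuinely open choice. The default is
the matching group's own $\hat b$ (the fits are per group, so this is
self-consistent), with a single global per-trait exponent as an option.
The two differ in a way worth knowing about: the sensitivity of
$\ln \overline{M^{-b} R}$ to an error $\delta$ in $b$ is roughly
$-\delta \,\overline{\ln M}$, about −5.6 per unit $b$ for masses around
300 mg, and under group-specific normalization the two temperatures'
exponent errors are independent, so they propagate straight into the
two-point slope. Under a global exponent the same error applies to both
temperatures and cancels almost entirely — but a global $b$ is *biased*
whenever the true exponent differs between acclimation temperatures
(exactly the mass × temperature pattern this design features), and that
bias also feeds through the $-\overline{\ln M}$ sensitivity into $E_a$.
In simulation the qualitative history ordering of $E_a$ (warm flatter
than ambient) is preserved essentially always under global-b, but only
~three quarters of the time under group-b at default noise; group-b, in
turn, is unbiased on average. The package keeps group-b as the default
for fidelity to per-group fitting; both are one switch apart
(`b_mode = "group" | "global"`), and the history *difference* in $E_a$
is more stable than either history's level under both modes.

## The inference layer

Seven candidate fixed-effect structures over mass, thermal history and
acclimation temperature (model 7 the mass-only null; model 5 adds the
history × temperature and mass × temperature interactions to the main
effects) are fitted as linear mixed models with random intercepts for
population and tank. Comparisons across fixed-effect structures use ML
(`REML = FALSE`) likelihoods — REML likelihoods are not comparable across
fixed effects — with REML available for reporting final variance
components. Ranking uses the second-order criterion

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k$ the full parameter count including variance components and $n$
the number of observations (not groups). Models within ΔAICc < 4 of the
best are retained; Akaike weights are renormalized over the retained set
and coefficients averaged conditionally (per term, over the models that
contain it), with full (zero-substitution) averaging as an option. A
screen that drops retained models whose interaction terms are all
non-significant exists but is off by default: it mixes a p-value criterion
into an information-theoretic ranking, so it is offered only for
compatibility. Metabolic responses are analysed as $\log_{10}$ rates;
mass enters as $\log_{10}$ mg. Sex is excluded from the default formulas
(it is confounded with size in live-bearing mosquitofish) but present in
the cohort tables. Likelihood-ratio comparisons replace
denominator-degree-of-freedom approximations for any p-values; the
package's contracts are about direction and magnitude recovery, not exact
p-values.

Boldness (emerged / did not emerge within 600 s) is a logit-link binomial
mixed model estimated by Laplace approximation; complete separation is
detected (degenerate response or unbounded coefficients) and answered
with a Firth-penalized fixed-effects fit, clearly flagged. Activity is a
Poisson-lognormal mixed model: Poisson response with log link, random
intercepts for population and tank, plus an observation-level normal
random effect that supplies the lognormal overdispersion. Emergence
latency versus metabolism is a right-censored Gaussian (Tobit) regression
maximizing

$$\sum_{obs}\left[\log\phi\!\left(\frac{y_i - x_i\beta}{\sigma}\right) - \log\sigma\right]
  + \sum_{cens}\log\Phi\!\left(\frac{x_i\beta - 600}{\sigma}\right),$$

by BFGS on $(\beta, \log\sigma)$ with an analytic gradient and three
deterministic starts; fits are per acclimation temperature so metabolic
rate is not confounded with temperature. The optimizer's relative
function tolerance is 10⁻¹⁰, which in practice pins the no-censoring case
onto the least-squares solution to machine precision; standard errors
come from the inverse observed information.

## What the generator emulates

The generative law for a fish of mass $M$ at temperature $T$ is the
mass–temperature model

$$\log_{10} R = \log_{10} a + b_T \log_{10} M +
  \frac{E_a^{(h)}(1/kT - 1/kT_0) + \gamma h_c t_c}{\ln 10} +
  u_{pop} + u_{tank} + \varepsilon,$$

anchored at $T_0 = 25$ °C, with per-history activation energies, an
optional exponent shift between temperatures ($b_T$), contrast codes
$h_c, t_c = \pm 1/2$, and fish-level log-normal noise shared across
traits. Anchoring both histories to a common intercept at 25 °C while
letting $E_a$ differ by history automatically produces the crossing
pattern the design targets — warm-source fish relatively high at 20 °C
and relatively low at 30 °C — without any extra offset ($\gamma$ defaults
to 0). The exponent shift (default −0.15 at 30 °C versus 20 °C) produces
the mass × temperature interaction; together these make candidate model 5
the true structure. RMR and MMR are tied to SMR by multiplicative gaps
$1 + (\rho - 1)e^{\eta}$ with mean-adjusted log-normal $\eta$, so
SMR ≤ RMR ≤ MMR holds for *every* draw and the zero-noise cohort sits
exactly on the per-trait power laws — which is what makes exact
end-to-end identity tests possible.

Defaults are the study conditions: 8 populations (4 per history), 2 tanks
per population (one per temperature), 198 fish, masses log-uniform on
50–1500 mg, $b$ of 0.40/0.40/0.35 (SMR/RMR/MMR) and per-history $E_a$ of
−1.33/−1.06 eV (SMR, ambient/warm) inside the reported ranges; trait
intercepts place MMR/SMR near 1.8 at 20 °C and 1.6 at 30 °C. Fish-level
noise is 0.10 log₁₀ units (~26 % CV), population and tank SDs 0.05 and
0.03. Emergence latency is log-normal with history, temperature, mass and
metabolic-residual effects sized so that roughly a third of
ambient-source and three quarters of warm-source fish emerge within
600 s; activity is Poisson-lognormal with observation-level variance 0.5
and a history × temperature interaction (warm-source less active at
20 °C), capped at the 300 s window.

The trace simulator follows the trial timeline on one clock: pre-trial
blank, RMR at $t = 0$, flush, ~18 h of SMR cycles, post-chase MMR, and a
post-trial blank, with the microbial rate drifting linearly between the
blank midpoints. Spontaneous activity during SMR cycles is a marked
Poisson process (default 2 bursts h⁻¹, 90 s, ×2.5 consumption), which is
exactly what the lowest-decile SMR rule is designed to shed; sensor noise
is Gaussian (0.01 mg L⁻¹). Flushes relax the chamber exponentially toward
supply water. What the generator does *not* emulate: oxygen-solubility
physics, % saturation conversions, the chase protocol itself, diel or
digestive rhythms in SMR, within-individual repeatability of behaviour
(one trial per fish, as in the design), or population-genetic structure.
Passing tests therefore demonstrate correctness of the estimators under
the stated signal model, not robustness to every field artefact.

## Numerical choices and degenerate inputs

Slope fits require ≥ 3 points and strictly increasing timestamps; SMR
needs ≥ 2 cycles; allometric fits require positive rates and masses, ≥ 3
points and non-identical masses, and report offending rows otherwise.
$E_a$ requires exactly two distinct temperatures and positive means. The
AICc correction refuses $n \le k + 1$. Mixed models drop random terms
with a single level (warning) and fall back to least squares with none
left; boundary (zero) variance estimates are accepted silently. Blank
rates are floored at zero before interpolation; a missing blank yields a
constant correction with a warning, two missing an error. Tobit fits
refuse data with no uncensored observations and warn when the scale
collapses. All simulation entry points take explicit integer seeds and
are bit-reproducible; the pipeline derives per-stage seeds from one root
seed by fixed offsets.

Problem sizes used by the test-suite demonstrations were chosen to keep
the full suite comfortably interactive: identity checks on 24–48 fish
with 2 h overnight runs (exactness does not depend on duration),
accuracy checks on 200 full-length runs, model-selection behaviour on 100
cohorts of 198 fish, and reduced replicate counts (30–60) for the slower
GLMM recovery demonstrations.

## Known limitations

* Two acclimation temperatures support only the two-point Arrhenius form;
  no curvature (e.g. Sharpe–Schoolfield) can be or is estimated.
* The group-b normalization noise discussed above is inherent to
  normalize-then-average with estimated exponents; with only two
  temperatures it cannot be averaged away.
* With 8 populations, population-level noise occasionally lets the
  full-interaction candidate (model 2) overtake the true structure
  (model 5) in AICc — observed in roughly 15 % of simulated cohorts —
  which is a small-sample property of the design, not of the ranking
  code.
* The Poisson-lognormal activity model treats the 300 s window cap as
  negligible; defaults keep the cap rare, but heavily active cohorts
  would need an explicit upper truncation.
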