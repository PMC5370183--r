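---
title: "Photocycle-coupled degradation kinetics: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photocycle-coupled degradation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztlkin)
```

## The model and its assumptions

ZEITLUPE (ZTL) is a LOV-domain F-box protein that targets the Arabidopsis
clock proteins PRR5 and TOC1 for ubiquitin-mediated degradation, and it is
the *dark-state* conformation of ZTL that degrades them efficiently. Blue
light drives the LOV cysteinyl–FMN C4a adduct (light state); in darkness the
adduct decays thermally with first-order rate constant $k_3$ (time constant
$\tau = 1/k_3$). `ztlkin` models the consequence for a ZTL target:

$$\frac{dc}{dt} = -\left[(k_1 - k_2)\,e^{-k_3 t} + k_2\right] c,$$

where $t$ is the *dusk clock* (hours since the last lights-off), $k_1$ and
$k_2$ are the degradation rates under fully light-state and fully dark-state
ZTL, and for TOC1 an additional ZTL-independent channel $-m_8 c$ is included.
The bracketed coefficient follows from normalising total ZTL to 1 and writing
the light-state fraction as $e^{-k_3 t}$ (dark fraction $1 - e^{-k_3 t}$).
The package evaluates the exact solution

$$c(t) = c_0 \exp\!\left[\frac{k_1 - k_2}{k_3}\left(e^{-k_3 t} - 1\right) - k_2 t\right]$$

and cross-checks it against adaptive numerical integration
(`integrate_numeric()`, `deSolve::lsoda`, rtol $10^{-8}$ / atol $10^{-12}$);
the two agree to a relative tolerance of $10^{-6}$ across the tested
parameter sweep. The contract is accuracy, not scheme identity.

Assumptions inherited from the modelling setting:

* **Pure degradation.** Synthesis terms are omitted: the model describes
  decay after dusk (or under constant light) of pre-accumulated protein, the
  regime in which the time courses it is fitted to are collected. Levels are
  therefore positive and non-increasing, and the package asserts this on
  every simulation.
* **Constant total ZTL, normalised to 1.** Appropriate for ZTL
  overexpressors, in which ZTL protein cycling is lost; endogenous ZTL
  cycling and GI-mediated stabilisation are out of scope.
* **Light phases are photostationary.** Under the growth irradiances in
  question the light state is near-saturated, so during light phases the
  coefficient is $k_1$ and the light-state fraction is pinned at 1.

## Tunable parameters

| parameter | meaning | unit | default / preset |
|---|---|---|---|
| $k_1$ | degradation rate under light-state ZTL | hr⁻¹ | 0.14 |
| $k_2$ | degradation rate under dark-state ZTL | hr⁻¹ | 0.8 |
| $k_3$ | LOV adduct-decay (dark-reversion) rate | hr⁻¹ | variant-specific |
| $m_8$ | ZTL-independent TOC1 degradation | hr⁻¹ | 0 |

$k_1$ and $k_2$ derive from the published clock models (light-phase rate
$m_{17}$/$m_6$, dark-phase sum $m_{17}{+}m_{24}$ / $m_6{+}m_7$;
`convert_pokhilko_params()`) and from constant-light and dark-mimic
experiments. $m_8$ defaults to 0 because no fitted value accompanies the
model's own simulations, which exclude TOC1 from quantitative analysis.
`preset_params()` carries the measured photocycle variants: WT
($\tau$ 1.4 hr, $k_3$ 0.7 hr⁻¹), G80R (6.6 hr, 0.15), V48I (10.7 hr, 0.09),
G46S:G80R (21 hr, 0.05) and V48I:G80R ($>65$ hr, 0.02 — the printed rate for
a bounded time constant). Every preset satisfies $|k_3 - 1/\tau| \le$ half an
ulp of the printed $k_3$, the sharpest statement consistent with the
rounding.

**V48I encoding.** V48I is allosteric: its light state behaves like
dark-state ZTL (constitutively high degradation activity). The presets
encode this as $k_1 = k_2 = 0.8$ hr⁻¹, kept deliberately separate from the
variant's slowed photocycle $k_3$ — the two effects are mechanistically
distinct and the package lets them be combined or not.

## Numerical choices and degenerate inputs

* $k_3 = 0$ (a photocycle that never reverts) and $k_3 = \infty$
  (instantaneous reversion) are explicit limit branches returning
  $c_0 e^{-k_1 t}$ and $c_0 e^{-k_2 t}$; the generic closed form divides by
  $k_3$ and is never evaluated there. $k_3 = 0$ additionally warns.
* $k_1 = k_2$ collapses the model to a single exponential; the trajectory
  then carries no information about $k_3$, and `fit_degradation()` flags
  this combination as non-identifiable instead of returning an arbitrary
  number.
* Schedule simulation is evaluated analytically piecewise (phase-boundary
  levels propagated in closed form), so trajectories are continuous and
  independent of the sampling grid. Times exactly at a transition belong to
  the phase that starts there: at dusk the dusk clock reads 0, at dawn the
  light-state fraction resets to 1. The dawn reset is instantaneous because
  photo-activation is fast relative to the hours timescale of everything
  else in the model.

## Photocycle fitting

`fit_monoexponential()` fits $y = y_0 + A e^{-k x}$ to one absorbance
channel by unweighted Levenberg–Marquardt least squares in linear absorbance
space (no weighting scheme is implied by the measurement protocol).
Starting values are derivative-free: $y_0$ from the last 10% of points, $A$
from first-minus-plateau, $k$ from the slope of $\log|y - \hat y_0|$ over
points clearly off the plateau. The two wavelength channels report the same
process and are fitted independently, then combined by `combine_channel_fits()`
(mean $k$; uncertainty the larger of the half-range and the pooled SE) —
averaging was chosen because nothing in the measurement privileges either
channel; a joint shared-$k$ fit is a possible alternative but the channels'
residuals need not share a variance. Base-catalysed (imidazole) recovery
runs use the same model; the flag is metadata only.

When the fitted $\tau$ exceeds three times the observation window the result
is flagged as a lower bound: beyond that the plateau is essentially
unconstrained, which is how a bounded report ("$\tau > 65$ hr") arises for
the slowest variant.

## Degradation-parameter inference

`fit_degradation()` minimises pooled squared residuals with box bounds
$[0, 10]$ hr⁻¹ (L-BFGS-B) and 5 multi-starts (the supplied start plus
lognormal-jittered copies, seeded); objective ties are broken toward the
smallest $k_3$. Residuals are taken on the **log scale** by default: the
biological noise in densitometry-normalised protein levels is multiplicative,
so log residuals are approximately homoscedastic; a linear-space option is
retained. Because L-BFGS-B can report a line-search stall when started at or
near the optimum, convergence is confirmed by a local probe of the objective
rather than trusting the return code alone.

LD fits use only dark-phase observations on the dusk clock, with the level
scale anchored at the first dark-phase observation (mean over replicates) —
the convention in which such time courses are normalised. Because the model
is time-inhomogeneous, anchoring at $t_1 > 0$ uses the ratio
$c(t)/c(t_1)$ on the true dusk clock, not a shifted clock. `c0 = "free"`
instead profiles the log-scale intercept analytically, which is statistically
cleaner when the first observation is noisy; the anchored default mirrors the
field convention and the difference is negligible at the tested designs.

LL data identify only $k_1$ (plus $m_8$ for TOC1): the light-state fraction
stays 1, so $k_2$ and $k_3$ drop out of the trajectory. Freeing them on LL
data is refused with an identifiability error, and `profile_objective()`
returns the correspondingly flat profile. The recommended protocol mirrors
the estimation narrative: fix $k_1$ from LL data, fix $k_2$ from a
constitutively dark-active (dark-mimic) series, then free $k_3$ on LD
dark-phase data.

`bootstrap_ci()` provides percentile intervals by case bootstrap (resampling
replicates) or residual bootstrap. With the default three biological
replicates the case bootstrap has only three resampling units and
undercovers; the residual bootstrap reaches approximately nominal coverage
at the tested design (95% intervals covering the generating $k_3$ in ~95% of
repetitions at CV 10%) and is the sensible choice for small replicate
counts. Both are deterministic under a seed. The apparent-rate helper
`effective_rate_constant()` is log-linear least squares — a single
exponential fitted as if only dark-state protein were present; its output is
a time-averaged rate between $k_1$ and $k_2$, meaningful as a comparative
quantity between variants, not a mechanistic constant.

## What the synthetic data emulate — and what they do not

`gen_absorbance_trace()` produces $y_0 + Ae^{-kt}$ plus additive Gaussian
noise, default sd 0.005 AU — chosen so that replicate-to-replicate spread of
the recovered $\tau$ matches the scale of the published replicate standard
deviations (0.1 hr on 1.4 hr for WT); defaults $y_0 = 0.35$, $A = -0.30$ AU
correspond to a ~30 µM LOV sample (450 nm extinction 12500 M⁻¹cm⁻¹) fully
bleached at $t=0$. Sampling in the tests follows the measurement cadence of
10–20 points per half-life. `gen_protein_timecourse()` multiplies the exact
model trajectory by independent mean-one lognormal factors
($\sigma^2 = \log(1+\mathrm{CV}^2)$, $\mu = -\sigma^2/2$), CV 10%, three
replicates — the replicate structure of the western-blot time courses; the
true densitometry noise magnitude is unpublished, so the CV is a declared
assumption. Seeds fully determine all generated data, and the generators
restore the caller's RNG state.

What passing recovery tests therefore show: the estimation machinery is
unbiased and precise *under multiplicative, independent, correctly-specified
noise at the stated design*. Real western-blot data add loading-control
error correlated within a blot, saturation nonlinearity, and residual
synthesis near dusk — none of which the generator emulates, so recovery
performance here is an upper bound on what in vivo densitometry supports.

## Problem sizes

The shipped tests run the full pipeline at the study's own scale: 3
replicates per condition, hourly (protein) or sub-half-life (absorbance)
sampling, 25-seed recovery batches for the headline $k_3$ check, 10-seed
batches for the single-rate checks, 50 seeds for the $\tau$-precision
property and 20 outer repetitions (100 bootstrap refits each) for CI
coverage. These sizes give Monte-Carlo error comfortably below the
tolerances asserted while keeping the suite fast.

## Known limitations

* No synthesis/mRNA dynamics, no full clock network, no circadian-period
  prediction, and no GI competition — the model covers degradation only.
* TOC1 is supported structurally ($m_8$) but there is no published value for
  $m_8$; quantitative TOC1 fits require the user to supply or free it.
* The dusk-anchored model assumes a clean light-to-dark transition;
  twilight or partial irradiance schedules are not represented.
* The in vivo apparent rates tabulated for PRR5 variants derive from figure
  densitometry that is not published as numbers; the package implements the
  estimation procedure but does not reproduce those specific values.
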