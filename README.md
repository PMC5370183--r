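# ztlkin

Kinetic analysis of how the photocycle of the Arabidopsis photoreceptor
ZEITLUPE (ZTL) shapes the nightly degradation of the clock proteins PRR5 and
TOC1.

ZTL is an F-box E3-ligase adaptor with a LOV (Light, Oxygen, or Voltage)
photosensor domain. Blue light drives a cysteinyl–FMN C4a adduct (the "light
state"); in darkness the adduct ruptures thermally ("dark reversion") with
rate constant k₃, and dark-state ZTL is the more active degrader of its
targets. The package is for photobiologists and circadian modellers who want
to (i) extract k₃ from in vitro absorbance-recovery kinetics, (ii) simulate
what a given k₃ implies for target-protein decay under light/dark cycles, and
(iii) fit the degradation parameters to (or validate them against) protein
time-course data.

## The model

Total ZTL is normalised to 1 and partitioned into light- and dark-state
fractions. After dusk (the dusk clock `t` restarts at every lights-off),

    c_ZTL-L(t) = exp(−k₃ t),        c_ZTL-D(t) = 1 − c_ZTL-L(t)

A target degraded at rate k₁ by light-state ZTL and k₂ by dark-state ZTL then
obeys

    dc/dt = −[(k₁ − k₂) e^(−k₃ t) + k₂] c        (PRR5)

with an extra ZTL-independent channel −m₈·c for TOC1. The package implements
the exact solution

    c(t) = c₀ · exp[ ((k₁ − k₂)/k₃)(e^(−k₃ t) − 1) − k₂ t ]

(with documented limit branches at k₃ = 0 and k₃ → ∞), an adaptive ODE
integrator as an independent numerical oracle, and piecewise simulation under
arbitrary light/dark schedules (light phases decay at k₁ with the adduct
photostationary; the light fraction resets to 1 at dawn).

In vitro, the adduct-decay rate is measured from dual-wavelength (450/478 nm)
absorbance recovery fitted as `y = y₀ + A·e^(−k x)`, with τ = 1/k. Built-in
presets carry the measured time constants of the characterised photocycle
variants — WT (τ = 1.4 hr, k₃ = 0.7 hr⁻¹), G80R (6.6 hr), V48I (10.7 hr),
G46S:G80R (21 hr), V48I:G80R (> 65 hr) — together with the degradation rates
k₁ = 0.14 hr⁻¹ and k₂ = 0.8 hr⁻¹. V48I-class variants are allosteric
dark-mimics and are encoded with k₁ = k₂ = 0.8 hr⁻¹.

## Worked example

```r
library(ztlkin)

## 1. photocycle: recover tau from synthetic WT recovery traces
traces <- gen_absorbance_trace(k = 1/1.4, t_grid = seq(0, 7, 0.15),
                               noise = noise_spec(seed = 11))
fit <- fit_monoexponential(traces[[1]], "a450")
fit
#> Monoexponential recovery fit (a450, n = 47)
#>   k   = 0.719 +/- 0.014 hr^-1
#>   tau = 1.391 +/- 0.026 hr
#>   y0  = 0.348 AU, A = -0.3006 AU, RSS = 0.000796
summarize_replicates(lapply(traces, fit_monoexponential, channel = "a450"))
#>   tau_mean     tau_sd    k_mean n
#> 1 1.369025 0.02889045 0.7306661 3

## 2. degradation: fit k3 from an LD dark-phase PRR5 time course
g80r <- preset_params("G80R")
tc <- gen_protein_timecourse(g80r$params, gen_ld_schedule(),
                             times = 12:24, noise = noise_spec(seed = 11))
fit2 <- fit_degradation(tc, g80r$params, free = "k3", seed = 1)
fit2 <- bootstrap_ci(fit2, n_boot = 200, type = "residual", seed = 1)
fit2
#> Photocycle-coupled degradation fit: PRR5 under LD
#>   free: k3   (objective: log residuals, anchor scale)
#>   k3  = 0.1491 hr^-1  [0.1412, 0.1589]
#>   fixed: k1 = 0.14, k2 = 0.8, m8 = 0
#>   objective 0.2305 (from 0.2331 at start), converged
```

The first block simulates three replicate 450 nm dark-recovery traces at the
WT adduct-decay rate and refits them: the per-trace fit returns the
recovered rate (0.719 hr⁻¹, true 0.714) and time constant (1.39 hr, true
1.4), and the replicate summary averages τ across the three traces. The
second block generates a 12L/12D PRR5 time course with the G80R parameter
set (k₃ = 0.15 hr⁻¹), then re-estimates k₃ from the dark-phase points with
k₁ and k₂ held fixed; the bracketed interval is a 95% residual-bootstrap CI
that covers the generating value.

A thin command-line wrapper over the same functions is shipped in
`inst/cli/ztlkin.R`:

```sh
Rscript inst/cli/ztlkin.R simulate --preset WT --schedule 12L12D --out sim.csv
Rscript inst/cli/ztlkin.R recover --preset G80R --seeds 25 --out summary.csv
```

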