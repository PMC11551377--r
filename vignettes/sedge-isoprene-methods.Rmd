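---
title: "Methods: Q10 response fitting and heat-wave emission modelling for sedges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Q10 response fitting and heat-wave emission modelling for sedges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedgeflux)
```

# The scientific problem

Isoprene is the dominant biogenic volatile organic compound and a key ozone
and aerosol precursor. Emission inventories describe its leaf-temperature
dependence with a response whose effective Q10 — the multiplicative change
per 10 °C — is about 3, calibrated on tree species. Sedges (Cyperaceae)
behave differently: their emission follows a much steeper exponential
response, with Q10 values in the 7–12 range. A steep exponential matters
mostly in its tail: a species that emits modestly at 25 °C can out-emit its
own baseline several-fold when a heat wave lifts air temperature by 8–10 K.
`sedgeflux` implements the chain needed to quantify this: chamber flux
calculation, Q10 fitting, a leaf-scale MEGAN-style emission model in which
the temperature response can be swapped, and heat-wave period statistics.

# Chamber flux calculation

A dynamic leaf chamber is flushed at flow rate $\dot V$ (L min$^{-1}$); the
isoprene mixing ratio rises from $\chi_{in}$ to $\chi_{out}$ (ppbv) across
the enclosed leaf area $A$ (m$^2$). The emission rate is the mass balance

$$F = (\chi_{out} - \chi_{in}) \cdot 10^{-9} \, \frac{\dot n}{A}, \qquad
  \dot n = \frac{P \dot V}{R T_{gas}},$$

with the molar flow $\dot n$ evaluated by the ideal gas law **at the gas
temperature and pressure at which the flow was metered** (defaults 298.15 K,
101325 Pa), not at STP — using STP silently misstates fluxes by up to ~8%.
A depleted chamber ($\chi_{out} < \chi_{in}$) produces a valid negative
flux, retained with a warning rather than clamped, so that downstream
filtering is an explicit, counted decision. An optional per-record
`background` offset (e.g. an empty-chamber blank) is subtracted from the
enhancement; full blank-correction protocols are out of scope.

# Q10 response fitting

The exponential response is
$E(T) = E_{ref} \, Q_{10}^{(T - T_{ref})/10}$ with $T_{ref} = 30$ °C, so
that the normalised response $\gamma(T) = Q_{10}^{(T-T_{ref})/10}$ equals 1
at 30 °C. `fit_q10()` estimates $Q_{10}$ and $E_{ref}$ by ordinary least
squares in log space:

$$\ln E = \ln E_{ref} + \frac{T - T_{ref}}{10} \ln Q_{10}.$$

Log-space OLS was chosen over nonlinear least squares on the raw fluxes
because (i) it is closed-form and deterministic, (ii) it matches the
multiplicative error structure of chamber flux data, and (iii) it makes
noiseless recovery exact, which anchors the test suite. Nonlinear least
squares (`method = "nls"`) is retained for sensitivity analysis; it is
started from the log-space solution and uses a `scaleOffset` in the
convergence control so that zero-residual data converge rather than fail.

Two filters precede the fit, both counted and reported:

- **Temperature cap** (`t_fit_max`, default 35 °C): emission above ~35 °C
  destabilises (enzyme optimum, stomatal effects), so only the stable rising
  limb is fitted. The boundary is *inclusive* by default
  ($T \le$ `t_fit_max`); `inclusive = FALSE` gives a strict inequality. The
  choice is declared rather than hidden because the convention differs
  between groups.
- **Positivity**: non-positive fluxes cannot enter the log transform and are
  excluded.

Fewer than two usable points, or a design with a single distinct
temperature, raises an error rather than returning a degenerate fit.

**Confidence intervals.** The default 95% CI is the t-based Wald interval on
the log-slope mapped through `exp` — for lognormal multiplicative noise the
log-space model is exactly Gaussian, so this interval has nominal coverage.
Because the method by which published response-curve CIs are shaded is
rarely stated, a seeded nonparametric bootstrap (resampling observations,
default 1000 replicates, percentile limits) is provided as an alternative.
For a noiseless series the Wald interval legitimately collapses to the point
estimate.

**Effective Q10.** Any temperature-activity function can be summarised over
an interval as
$\left(\gamma(T_{hi})/\gamma(T_{lo})\right)^{10/(T_{hi}-T_{lo})}$. For an
exponential response this returns its Q10 for *any* interval; for the
default MEGAN response the value depends on the interval (about 2.98 over
25–35 °C, 3.19 over 20–35 °C at standard acclimation), which is why the
interval is an argument rather than a constant: quoted "MEGAN Q10 ≈ 3"
values do not state their interval.

# The leaf-scale emission model

Ground-area flux is the single-layer product

$$F = EF \cdot LAI \cdot \gamma_P \cdot \gamma_T,$$

with $EF$ the species emission factor at standard conditions (nmol m$^{-2}$
leaf s$^{-1}$) and $LAI$ the leaf area index. The MEGANv2.1 activity factors
are used for light, always, and for temperature when
`response = megan_default`:

$$\gamma_T = E_{opt} \frac{C_{T2} e^{C_{T1} x}}
  {C_{T2} - C_{T1}\left(1 - e^{C_{T2} x}\right)}, \qquad
  x = \frac{1/T_{opt} - 1/T}{R'},$$

with $T_{opt} = 313 + 0.6\,(T_{240} - 297)$ K,
$E_{opt} = 2.034\, e^{0.05 (T_{24} - 297)} e^{0.05 (T_{240} - 297)}$,
$C_{T1} = 95$, $C_{T2} = 230$ kJ mol$^{-1}$, $R' = 0.00831$ kJ mol$^{-1}$
K$^{-1}$; and

$$\gamma_P = C_P \frac{\alpha \cdot PPFD}{\sqrt{1 + \alpha^2 PPFD^2}},
  \qquad \alpha = 0.004 - 0.0005 \ln P_{240}, \quad
  C_P = 0.0468\, e^{0.0005 (P_{24} - 200)} P_{240}^{0.6}.$$

$T_{24}, T_{240}$ are trailing 24-h and 240-h mean air temperatures and
$P_{24}, P_{240}$ trailing means of PPFD over *daytime* steps
(PPFD $> 0$) in the same windows; these acclimation terms shift the
temperature optimum and light sensitivity with the recent environment. The
coefficient values are the MEGANv2.1 isoprene sun-leaf set; they are
overridable via `megan_coefficients()` so alternative parameterisations can
be recorded in configuration with their provenance.

Design choices, each genuinely open and settled as follows:

- **Standard-condition normalisation.** With these coefficients
  $\gamma_T = 1.0001$ at a leaf temperature of 303 K and standard
  acclimation (297 K); 2.034 was calibrated at 303 K, the model's standard
  leaf temperature. At 303.15 K (30.0 °C) the value is 1.017. The package
  treats 303 K as the normalisation point and the test suite asserts
  $|\gamma_T(303) - 1| \le 0.01$ (and $\approx 1$ within 2% at 303.15 K).
- **Temperature-response swap only.** A fitted exponential replaces
  $\gamma_T$; $\gamma_P$ and its acclimation are retained for both response
  kinds, because sedge isoprene is light-dependent (emission falls to ~zero
  in the dark, at both low and high temperature — there is no storage pool),
  so removing the light response would be wrong for either species.
- **Leaf temperature = air temperature.** Weather stations measure air
  temperature only; leaf energy balance is not modelled. This understates
  midday leaf-air temperature differences and is stated as an explicit
  assumption, not a hidden one.
- **Single layer, no canopy radiative transfer; $\gamma_{age}$,
  soil-moisture and CO$_2$ factors fixed at 1.** The scientific contrast
  here is driven by the temperature-response swap; the $\gamma$ factors are
  isolated behind one interface so a canopy scheme could be added without
  touching the response code.
- **Spin-up.** Trailing windows expand at the series start (the first
  record's $T_{24}$ is its own temperature) instead of discarding ten days
  of forcing; analyses can always be restricted to later periods.
- **Overflow guard.** For leaf temperatures far above the optimum,
  $e^{C_{T2} x}$ exceeds double range while $\gamma_T \to 0$; the exponent
  is capped so the closed form stays finite.
- **Dark-history degeneracy.** A series with no daylight in the 240-h
  window has $P_{240} = 0$; $\gamma_P$ returns 0 (with a note) rather than
  evaluating $\ln 0$.

# Heat-wave analysis

Periods are half-open intervals $[start, end)$ in the station's time zone,
so a step on a boundary belongs unambiguously to the period starting there.
`summarize_period()` returns the arithmetic mean and maximum flux and the
step count; `percent_change()` is $100 (\bar F_{during} - \bar
F_{before})/\bar F_{before}$; `species_comparison()` returns the mean ratio
(how much of species b's emission species a accounts for) and the peak
excess. Statistics cover all steps, day and night, by default, with a
`daytime_only` option, since published period statistics rarely state which
convention was used. Heat-wave boundaries are *inputs* (or the generator's
recorded block boundaries); no percentile-based heat-wave detection is
attempted. Because the model is linear in $EF \cdot LAI$, within-species
percent change is exactly invariant to rescaling either — a property the
tests use as an oracle.

# Synthetic data: what it emulates, and what it does not

`gen_chamber_series()` emulates a temperature-ramp chamber experiment:
leaf temperatures evenly spaced over a range (default 20–42 °C so that the
fitting filter is actually exercised), fluxes on a known exponential curve,
and multiplicative lognormal noise with unit mean and configurable CV
(default 0.05, a realistic proportional scatter for chamber work). Points
are treated as independent equilibrium observations; ramp-rate and
equilibration artefacts are not simulated.

`gen_met_series()` emulates late-summer urban forcing: a baseline block
(default 14 days) followed by a heat-wave block (default 7 days) with a
uniform additive boost (default 8 K, the canonical scenario in the test
suite); diurnal temperature is a sinusoid (default mean 296.15 K ≈ 23 °C,
amplitude 6 K, maximum at 14:00) and PPFD a 12-h half-sinusoid peaking at
2000 µmol m$^{-2}$ s$^{-1}$ at solar noon, zero at night, on a 30-min step.
The additive whole-day boost keeps expected flux changes analytically
computable. The generator makes no attempt to reproduce any specific
observed meteorology: no weather noise by default (a seeded Gaussian
temperature jitter is available), no clouds, humidity, wind or soil
moisture. Consequently, passing tests demonstrate correctness of the
*method* — recovery of known parameters, exactness of identities,
direction and invariance of heat-wave effects — not agreement with any
measured flux record. Reproducing published period statistics requires the
corresponding archived meteorology and species parameters (emission
factors, LAI, exact heat-wave dates), which are supplied to the pipeline as
inputs, not bundled.

The synthetic heat-wave scenario used by the tests and the acceptance
script assigns the sedge-like species $EF = 2$ nmol m$^{-2}$ s$^{-1}$,
$LAI = 2$, $Q_{10} = 7.2$ and the tree-like species $EF = 6$, $LAI = 4$,
$Q_{10} = 3.7$ — the tree deliberately higher in both $EF$ and $LAI$, the
sedge steeper in temperature response, so the qualitative contrast (larger
relative heat-wave amplification for the sedge despite smaller absolute
emissions) emerges from the response shape alone. These are synthetic
scenario values, not measured parameters.

# Problem sizes and reproducibility

The test suite and acceptance script run desk-scale by design: Q10 recovery
uses 200 seeded chamber series of 30 points per true Q10 (3.7, 7.2, 12;
noise CV 0.05) — the seed-mean fitted Q10 sits within 2% of truth and the
nominal-95% interval covers the truth at a rate inside [90%, 99%]; the
heat-wave simulation covers 21 days at 30-min resolution (1008 steps).
Everything completes in seconds on one CPU. All randomness flows from
explicit integer seeds; generators restore the caller's RNG state, and
re-running any stage with an identical configuration is bit-reproducible.
Every pipeline run writes a YAML echo of its configuration and a log of
package version, seed and filter counts alongside its outputs.

This is an analysis package driven from R: the pipeline stages
(simulate/read chamber data, fit, simulate/read meteorology, simulate flux,
analyse) are exported functions plus the configuration-driven
`run_pipeline()`, rather than a shell executable.

# Known limitations

- Leaf temperature is approximated by air temperature; midday fluxes under
  strong radiation are therefore conservative for both response kinds.
- The single-layer canopy treats all leaves as sun leaves at the measured
  PPFD; no within-canopy light extinction.
- The exponential response is extrapolated beyond the fitted range when the
  forcing exceeds the chamber ramp; with Q10 ≈ 7–12 this tail dominates
  heat-wave totals, so fitted-range coverage of the forcing should be
  checked.
- The default CI assumes independent observations; chamber ramps can be
  serially correlated, for which the bootstrap option is only a partial
  remedy.
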