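---
title: "Models and methods behind vocflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vocflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocflux)
library(dplyr)
```

vocflux quantifies leaf-level volatile organic compound (VOC) emission
fluxes from PTR-TOF-MS channel time series recorded in a dynamic leaf
cuvette, and infers in vivo isoprene precursor kinetics from the
post-illumination decay of isoprene emission. This vignette explains the
models the package implements, the assumptions behind them, the default
parameter values and why they were chosen, and what the bundled simulator
does and does not emulate.

## The cuvette mass balance

A leaf enclosed in a flow-through cuvette receives air at molar flow $Q$
(µmol s⁻¹) with inlet mixing ratio $\chi_{in}$ and emits at area-specific
rate $E$ (nmol m⁻² s⁻¹) over leaf area $A$ (m²). The chamber headspace
holds $n$ µmol of air, so

$$n \frac{d\chi}{dt} = Q(\chi_{in} - \chi) + E\,A .$$

At steady state ($n \to 0$ or slow transients) this reduces to the familiar
$E = Q(\chi_{out} - \chi_{in})/A$; with the defaults $Q = 500$ µmol s⁻¹ and
$A = 6\ \mathrm{cm}^2$ one nmol mol⁻¹ of concentration difference
corresponds to 0.8333 nmol m⁻² s⁻¹ of flux. `flux_from_mixing_ratio()`
implements both the static balance and, optionally, the storage term
$(n/A)\,d\chi/dt$ (central differences on the native 1 Hz grid). The
storage term matters during fast transients: with a washout time constant
$\tau = n/Q = 5$ s and a decay rate constant $k = 0.05$ s⁻¹, the naive
static balance underestimates $k$ by roughly 20%, and enabling the dynamic
term removes more than 95% of that bias (this is a property test in the
package suite). By default `n_chamber = 0`: a well-flushed cuvette at
500 µmol s⁻¹ has $\tau$ of a few seconds and the static balance is the
conventional choice; the dynamic term is switched on whenever a nonzero
chamber molar content is configured.

Empty-chamber blanks measured under matched temperature and CO₂ are
subtracted channel by channel. Because blanks and leaf measurements are not
synchronous, the default subtracts the *time-mean* of the blank window
rather than pairing samples; a `pointwise` mode exists for synchronous
designs. Negative corrected fluxes are preserved and flagged, never
clipped: truncation at zero would bias every downstream mean and integral
upward.

## Channel registry

PTR-TOF-MS reports protonated ions at exact mass-to-charge ratios. The
default registry maps 16 channels to compounds and six biosynthetic
groups: isoprene (m/z 69.070), four lipoxygenase-pathway green-leaf
volatile channels, seven reactive-carbonyl channels, methanol (33.034),
formic and acetic acid, and ethanol (47.049). The match tolerance defaults
to ±0.01 Da because the registry contains two near-isobaric pairs —
47.013/47.049 (formic acid vs ethanol) and 59.014/59.049 (glyoxal vs
propanal/acetone) — that a looser tolerance could not separate.
`map_channels()` refuses ambiguous assignments (two registry channels
within tolerance of one observed mass) rather than guessing, and names both
candidates in the error. One registry quirk is recorded rather than
resolved: the conventional acetaldehyde channel at m/z 45.034 is keyed on
its mass, because the ion formula usually quoted for it is inconsistent
with protonated acetaldehyde (C₂H₅O⁺); a `note` column carries the caveat.
Formaldehyde has no default channel and is omitted.

Drift-tube bookkeeping is included because the reduced electric field
$E/N$ governs PTR ion chemistry: $E/N = (U/L) \,/\, (p / k_B T)$, reported
in Townsend (1 Td = 10⁻¹⁷ V cm²). With 600 V, 2.5 mbar, 60 °C and the
9.3 cm drift length typical of this instrument class, $E/N = 118.7$ Td,
quoted as ≈120 Td at the conventional ten-Td rounding. The drift length is
not a measurement but an instrument constant, so it is an explicit argument
with that default.

## The single-pool decay model

Isoprene is produced from dimethylallyl diphosphate (DMADP) by isoprene
synthase (IspS). The package models the chloroplastic DMADP pool $S$
(nmol m⁻²) as a single well-mixed compartment supplied by the MEP pathway
at rate $F$ while light is on, and drained by IspS with first-order rate
constant $k$:

$$\frac{dS}{dt} = F \cdot L(t) - k S, \qquad I(t) = k S(t) + E_{floor},$$

with $L(t) \in \{0, 1\}$ and a small residual dark emission floor. Under
light the pool settles at $S^* = F/k$ and emission at $I = F$. When the
light is cut, MEP supply ceases (assumed instantaneous; an optional
exponential supply lag, default 0 s, covers non-instant cessation) and
emission decays as $I(t) = k S^* e^{-kt}$. Two identities drive the
inference:

* the **pool size** equals the area under the decay curve,
  $\int_0^\infty (I - E_{dark})\,dt = S(t_{off})$;
* the **rate constant** is the initial relative decay rate,
  $k = -\dot I / (I - E_{dark})$.

The model deliberately treats the pool as one compartment; cytosolic and
chloroplastic DMADP are not deconvolved, and a multi-exponential tail will
be absorbed into a single apparent $k$.

## The decay analysis chain

`analyze_decay()` runs five stages, each exported separately:

1. **Transition detection.** The dark transition is the first sample where
   PPFD falls below 1% of its light-phase median. Without a PPFD column, a
   sequential change-point fallback is used: the first time two
   consecutive non-overlapping 3-sample forward means fall more than
   4σ below the trailing 30-sample lit-level mean, with σ estimated from
   the trailing window's first differences. On simulated decays with 3%
   channel noise this lands within ±2 s of the true switch.
2. **Steady state.** Mean flux over the 60 s before the transition, with a
   drift check (fitted slope relative to the mean; flagged above 0.1% s⁻¹,
   about 4.5 standard errors of the slope under 3% channel noise).
3. **Dark baseline.** Mean over the *terminal* stable window (default 30 s
   at the end of the dark tail), accepted when its fitted |slope| is below
   0.5% of the steady-state emission per second. Using the earliest window
   that passes a slope criterion — a plausible alternative — selects a
   window only ~46 s after darkening for $k = 0.05$ s⁻¹, where the decay
   still carries ~10% of the pool; that choice biases the integral by
   ~20%. The terminal window is the most exhausted part of the decay, and
   with the simulator's default tail length (below) keeps the pool bias
   under 2%. If the terminal window still slopes, the analysis proceeds
   but flags `baseline-not-reached` and `truncated-integral`, and flagged
   leaves are excluded from treatment statistics by default.
4. **Pool integration.** Trapezoidal integral of $E(t) - E_{dark}$ from the
   transition to the start of the baseline window, on the native 1 Hz grid
   (no resampling; at $k \le 0.1$ s⁻¹ the trapezoid error is below 0.1%).
   Negative excursions are kept — under zero-mean noise they cancel in
   expectation — and a negative *total* integral is rejected as a sign of
   baseline overestimation.
5. **Rate constant.** Two estimators over the initial window after the
   transition, both reported: `k_loglin`, the slope of
   $\ln(E - E_{dark})$ versus time, and `k_slope`, the least-squares slope
   of $E$ versus time normalized by the window-mean excess, with a
   finite-window correction (solved by `uniroot` against an exact
   exponential on the same grid) that makes it unbiased for first-order
   decay at any window length. The naive textbook form — raw slope over
   steady-state amplitude — carries an $O(kW/2)$ curvature bias, 25% for
   $k = 0.05$ s⁻¹ over a 10 s window, which is why the corrected form is
   used. A third consistency estimator `k_ratio` $= (E_{ss} -
   E_{dark})/S_{pool}$ follows from the first-order identity; on noise-free
   exponentials all three agree to better than 1%.

The **initial window defaults to 20 s**. At 1 Hz with 3% multiplicative
noise, the log-linear slope standard error is ≈0.0033 s⁻¹ for a 10 s
window and ≈0.0012 s⁻¹ for 20 s; the shorter window would make per-leaf
estimates at the cool end of the temperature range ($k \approx 0.012$ s⁻¹)
noisier than 25% relative, while 20 s keeps them near 10% without
distorting fast decays (at $k = 0.08$ s⁻¹ the window spans 1.6 mean
lifetimes, and the log-linear fit is curvature-free for a single
exponential). `k_loglin` is the primary reported constant; the others are
diagnostics.

## The simulator and what passing its tests means

`generate_experiment()` produces the package's validation bed: a 4 × 2
factorial design (25/30/35/40 °C × 400/800 µmol mol⁻¹ CO₂) with six
replicate leaves per cell, 48 traces in total, each a full 1 Hz channel
table passed through the chamber model with multiplicative Gaussian noise
(CV 3%, a typical 1 Hz channel precision for this instrument class) plus a
small additive floor. The default physiological surfaces are anchored on
the magnitudes reported for poplar leaves under acute heat:

* the apparent IspS rate constant follows an Arrhenius form
  ($\log k$ linear in $1/T$) from 0.012 s⁻¹ at 25 °C to ≈0.07 s⁻¹ at
  40 °C, inside the 0.06–0.08 s⁻¹ range observed at the thermal extreme;
* the steady-state DMADP pool expands sigmoidally with temperature,
  diverging with CO₂ (≈200 vs ≈320 nmol m⁻² at 35 °C for ambient vs
  elevated CO₂; ≈460 nmol m⁻² at 40 °C under 800 ppm);
* net assimilation declines sigmoidally to below 2 µmol m⁻² s⁻¹ at 40 °C
  under ambient CO₂, with a ~30% CO₂ enhancement at the optimum;
* the five stress-VOC groups are temperature sigmoids with CO₂-dependent
  burst amplitudes (methanol baseline ≈11 and ≈36 nmol m⁻² s⁻¹ at 40 °C
  converging across CO₂; LOX products ≈2.4, short-chain acids ≈15.4 and
  ethanol ≈50 nmol m⁻² s⁻¹ at 40 °C under elevated CO₂). Ethanol is the
  one biphasic group — a sum of two sigmoids, with elevated CO₂
  suppressing the mid-temperature component and amplifying the acute
  fermentation burst. The reactive-carbonyl burst amplitude
  (≈450 nmol m⁻² s⁻¹ at 40 °C/800 ppm) follows the reported value even
  though it sits well above every other group.

One internal tension is worth stating plainly: a single-pool first-order
model forces $E = kS$ at steady state, so with $k \approx 0.07$ s⁻¹ and
$S \approx 460$ nmol m⁻² the simulated steady-state isoprene emission at
40 °C is ≈30 nmol m⁻² s⁻¹, higher than the ≈13 nmol m⁻² s⁻¹ reported for
real leaves alongside those same pool and rate-constant magnitudes. Real
leaves are not a single well-mixed pool. The simulator anchors the pool and
the rate constant — the two quantities the decay analysis estimates — and
lets emission follow from the model. Parameter-recovery results therefore
validate the *inference machinery* under the model's own assumptions
(known noise structure, exact first-order kinetics, perfectly matched
blanks, abrupt supply cessation); they do not certify accuracy on real
leaves, where multi-pool kinetics, supply lag, stomatal dynamics and
instrument drift add structure the simulator does not emulate.

The default protocol holds light for 300 s and extends the dark tail to
$\max(300, 6/k)$ s, so the decay is ≥99.75% exhausted before the terminal
baseline window; a tail shorter than $5/k$ raises a warning and marks the
truth record. Identical seeds give bit-identical experiments.

## Treatment statistics

Temperature responses are fitted with the four-parameter logistic
$y(T) = y_{min} + (y_{max} - y_{min})/(1 + e^{-(T - T_{mid})/s})$ — the
minimal monotone saturating family consistent with the observed response
shapes — by Levenberg–Marquardt (`minpack.lm::nlsLM`) from a 3 × 3 grid of
midpoint/scale starts, keeping the best converged fit; fits are
canonicalized so `y_max` is the upper asymptote, flat responses return a
flagged degenerate fit, and a midpoint more than 10 °C outside the data
range clears the convergence flag.

Substrate-control regressions (emission against pool size or rate
constant) are ordinary least squares with a configurable excluded
temperature set, defaulting to {40 °C}: at the thermal extreme emission
decouples from substrate control, and including those cells would distort
the coupled-regime slope. Excluded points are echoed in the result —
never silently dropped — so the decoupling itself stays visible.

CO₂ treatments are compared at each temperature with the independent
two-tailed Student's *t*-test (pooled variance, $df = n_1 + n_2 - 2$),
computed from the textbook statistic and cross-checked against
`stats::t.test` in the suite; a Welch variant is available behind a flag
and never substituted silently. Cells with fewer than two leaves are
skipped with a record. No multiple-testing correction is applied — the
convention for per-temperature stars at 0.05/0.01/0.001 — but the report
carries the number of tests performed so a reader can apply one.

## Numerical choices and degenerate inputs

* Exact exponential-step updates (not Euler) for both the pool ODE and the
  chamber washout, so grid solutions are closed-form within each
  constant-supply segment.
* Identical cells in a *t*-test give $t = 0$, $p = 1$ (zero pooled variance
  is treated as no evidence, not an error).
* A trace with no dark phase fails at the transition stage with the stage
  name; one corrupted trace in an experiment contributes an error row and
  the remaining traces proceed.
* Registry validation rejects channel pairs closer than twice the match
  tolerance, duplicated compound labels, and unknown groups.

## Worked example

A complete run on the default simulated design:

```{r example, eval = FALSE}
exp <- generate_experiment(sim_config(), seed = 1)
decays <- analyze_experiment(exp$traces, blanks = exp$blanks)
decays |>
  dplyr::summarise(pool = mean(s_pool), k = mean(k_loglin),
                   .by = c(t_leaf_c, co2))

fit <- fit_substrate_control(decays, "s_pool", "e_ss", exclude_temps = 40)
glance(fit)
autoplot(fit)
```

Problem sizes throughout the package's own test suite are chosen to keep a
full check fast on a laptop: the factorial recovery uses the full 48-leaf
design, the type-I-error calibration uses 1000 simulated null experiments
of per-leaf statistics (not full traces), and property sweeps use reduced
grids.

## Known limitations

* Single-pool kinetics: no cytosolic/chloroplastic deconvolution; apparent
  $k$ mixes compartments on real leaves.
* Counts-to-mixing-ratio conversion (primary-ion normalization, reaction
  kinetics) is out of the default path; `mixing_ratio_from_counts()`
  exists for workflows that need it, but TOF peak fitting, mass
  calibration and transmission are out of scope entirely.
* The simulator's stress-VOC groups are steady baselines per treatment,
  not time-resolved bursts; group statistics exercise aggregation and
  comparison machinery, not burst dynamics.
* No mechanistic photosynthesis or stomatal model: A_net is treatment-level
  metadata.
* No mixed-effects structure for plant identity; replicates are treated as
  independent.
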