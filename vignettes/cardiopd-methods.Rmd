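---
title: "cardiopd: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiopd: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiopd)
```

## The assay and its data

A semi-isolated insect heart (the dorsal vessel, exposed in the opened
abdomen) is perfused in an incubation chamber at ~300 µL/min while a light
beam through the myocardium records tissue-density changes as a
*cardiomyogram*. After a preincubation period the signal is registered for
22 minutes; test solutions replace saline either continuously in a
mid-recording window (**variant A**) or as a single microsyringe bolus into
the perfusion line during continuous drug perfusion (**variant B**). The
derived quantity underlying all analysis is the per-minute (or
per-half-minute) heart contraction frequency.

`cardiopd` models this world in four layers: `protocol_spec` (the perfusion
timeline), `od_trace` (the raw optical signal), `recording` (the frequency
series), and the metric/interaction layers on top. Time is minutes from the
start of registration; segments are half-open `[t_start, t_end)` intervals.
The default compound window `[4, 13.5)` min and pulse time 8 min are
read off the published per-minute result tables (first significant drops at
minute 4.5, rebounds at 13.5–14.5, bolus "in 8 min"); the exact on/off
minutes appear only as figure shading in the source material, so both
defaults are plain constructor arguments, not assumptions baked into the
analysis.

## Per-recording metrics

**Percent change.** With baseline `f̄₀` the mean frequency over the first
minute (configurable window, closed interval — a sample stamped `t` covers
the interval ending at `t`), the analysed trajectory is
`y(t) = 100 · (f(t) − f̄₀)/f̄₀`. A zero baseline is an error, not a silent
NaN. Percent change is invariant to rescaling frequencies by any positive
constant (property-tested).

**Slope coefficient.** The dynamics statistic is the per-interval
difference quotient `a = (y₂ − y₁)/(x₂ − x₁)` in %/min, computed exactly
for non-uniform spacing and stamped with the interval's right endpoint, as
the published slope tables are indexed.

**E_max and point effects.** `E_max` is the signed extreme of `y` within
the exposure window (onset of the first non-vehicle segment to the end of
the last, or the pulse time(s) for pulse-only protocols); `E_at(m)` reads
the sample nearest minute `m` (within half a bin). An `arrested` flag marks
frequencies reaching zero inside the window.

**t50 and RT50.** `t50` is the time from exposure *onset* to the first
crossing of `E_max/2`; `RT50` the time from exposure *end* until the effect
has recovered halfway back to the 0% baseline. Both clocks' origins are
reported with the estimate so alternative conventions remain recoverable.
The phrase "recovers 50% of the initial value" admits a second reading
(frequency reaching 50% of baseline); we use the half-of-the-change-
recovered reading because it is the only one defined for effects smaller
than a 50% decrease (e.g. α-solanine's −25.3%). Each statistic ships two
estimators: `interp` (piecewise-linear crossing on the raw samples;
assumption-free, the default) and `fit` (least-squares mono-exponential,
`t50 = ln 2 / k`, mirroring the nonlinear-regression tooling used in
practice). On analytic first-order trajectories both agree with `ln 2 / k`
within one sampling interval across `k ∈ [0.1, 2]` /min (acceptance-tested).
The rate optimisation brackets the SSE minimum on a log-spaced grid before
golden-section refinement, because the SSE is flat in `k` above the
identifiable range and plain `optimize()` can stall on the plateau.

## Dose–response

Inhibition curves are fitted by least squares on the log-dose axis with the
four-parameter logistic in its inhibition orientation,

`E(C) = E_top + (E_bottom − E_top) / (1 + (IC50/C)^h)`,

with `E_top = 0` fixed by default (no effect at zero dose) and `E_bottom`
free in `[−100, 0]` or user-fixed. Fitting is deterministic: a multi-start
grid (Hill slope in {0.5, 1, 2, 4} × IC50 at each observed dose) seeds
L-BFGS-B, best SSE wins. Flat data yield a flagged `degenerate` fit rather
than an arbitrary IC50; an IC50 more than 100× outside the spanned dose
range is flagged `extrapolated`. `inverse_dose()`/`ec()` invert the fitted
curve in closed form, e.g. `ec(fit, 75)` for the EC75; with `h = 1` and a
full 0 → −100 span, EC75 = 3 × IC50 exactly (tested).

Per-dose effects entering a fit default to the *final-exposure-minute*
group mean (dose–response panels in this assay are read "in the last min of
perfusion"); `E_max`-based fitting is a caller choice.

## Interaction indices

For a binary mixture with same-direction effects,

* toxic index `TI = E_mix / (E_a + E_b)`,
* toxic units `TU = E_mix/E_a + E_mix/E_b`.

An exactly additive mixture gives `TI = 1` and `TU` equal to the additive
reference `TU* = (E_a + E_b)/E_a + (E_a + E_b)/E_b ≥ 4`, with the identity
`TU = TI · TU*` holding algebraically (asserted to 1e−12 on random inputs).
Classification uses a reporting tolerance δ (default 0.05): additive within
δ of the reference (1 for TI, `TU*` for TU, relatively), antagonism below,
synergism above. The TU decision rule is not published anywhere we know of;
comparing TU against `TU*` is our inference — it reproduces every published
label — and is flagged as a convention, not a statistical test. Mixed-sign
effects are rejected: the framework assumes co-directional action.

Arm effects are group means of the percent change at fixed evaluation
minutes (continuous designs: minute 13; pulse designs: minutes 9 and 13),
not per-preparation pairs, since arms are independent preparations. No
Loewe/Bliss/Chou–Talalay surface is attempted; the two indices above are
the method.

## The simulator: what it emulates, and what it does not

The generator exists to give every pipeline stage a ground truth. It
encodes, as its *stated world*:

* a stable baseline rhythm — default `f0 = 48` contractions/min, a
  documented placeholder (the absolute adult baseline is not published for
  this preparation) that every function takes as a parameter;
* concentration-dependent reversible bradycardia: Hill equilibrium effect
  `E_eq(C) = E_max·C^h/(C^h + EC50^h)` with first-order kinetics
  `dE/dt = k·(E_eq − E)`, deepening at `k_on` and recovering at `k_off`
  (the published slope tables show asymmetric onset vs rebound dynamics,
  hence two rates). Integration uses the exponential exact-step update, so
  it is unconditionally stable and exact wherever `E_eq` is piecewise
  constant;
* chamber concentration as a step function during segments (perfusion
  treated as instantaneous medium exchange; mixing dead time is absorbed
  into `k_on`), plus instantaneous boluses clearing exponentially at
  `pulse_decay`;
* mixture modes at equilibrium: `independent` (Bliss-style product),
  `additive` (sum, floored at −100%), `antagonistic(λ)` (λ × additive), so
  the generator's λ *is* the expected TI by construction — the
  generator/analysis consistency criterion exploits exactly this;
* bounded measurement variation: per-bin Gaussian noise (SD 0.25
  contractions/min) clamped at 2.5 SD and a linear baseline-drift ramp with
  total amplitude drawn from N(0, 0.5%) clamped at 2 SD. The clamping is
  deliberate: control preparations in this assay are reported never to move
  more than ±3% over 22 min, and unbounded Gaussian tails would
  occasionally contradict that stated behaviour. These defaults were fixed
  when the generator was written, before the stability criterion was run.

Raw traces are integrate-and-fire: the phase integral of the instantaneous
rate emits a beat at each unit crossing, each beat stamped as a
raised-cosine pulse on a noisy baseline.

The simulator does **not** model channel-level electrophysiology, circadian
modulation of heart activity, beat-to-beat autocorrelation, waveform
variability, or motion artifacts. A green test therefore establishes that
the *analysis* recovers the truth of this generative model at realistic
noise — not that the model captures every feature of real recordings.

## Numerical and design choices

* First-order kinetics is the simplest model consistent with the monotone
  published trajectories; the source fits no kinetic model, so this is a
  stand-in generator, not a scientific claim.
* Beat detection is greedy highest-prominence-first under a refractory
  constraint, ties broken by earlier time — chosen for determinism (the
  original acquisition software is unpublished). Edge samples may be
  one-sided maxima (a trace can end mid-beat); prominence of an edge peak
  ignores the missing side. Beat times are parabolic-interpolated apexes.
  An exhaustive O(n²) oracle replicates the rule independently in the test
  suite. Detector defaults for the noisy benchmark (prominence 0.5 of unit
  pulse amplitude, 0.12 s smoothing, 0.3 s refractory) were tuned against
  the simulator only.
* Binned frequency is count-based (beats per bin scaled to per-minute), not
  reciprocal inter-beat interval, matching the reporting granularity of the
  assay; a partial terminal bin scales by its actual width; one-bin windows
  are legal (a single-point recording).
* Degenerate inputs fail loudly everywhere: zero baselines, malformed
  protocols (gaps, overlaps, out-of-range pulses), duplicate time stamps,
  mixed-sign interaction effects, flat dose–response data.
* All machine-readable outputs are written with locale-independent
  formatting; identical seed + config gives byte-identical files (tested).

## Known limitations

* No mixed-effects or repeated-measures modelling across the n ≈ 15
  preparations per arm; arms are summarised by mean (± SD at the caller's
  discretion) as in the original analysis.
* The TU classification reference and the exact perfusion on/off minutes
  are inferences (see above), kept configurable.
* The simulator's noise model is per-bin white noise; real recordings
  likely show slow autocorrelated variation beyond the linear drift term.
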