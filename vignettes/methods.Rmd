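---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aismature)
```

`aismature` quantifies the functional and structural maturation of cortical
pyramidal neurons: passive membrane properties, firing output, action
potential (AP) phase-plane structure, and axon initial segment (AIS)
geometry, plus the group statistics that compare age cohorts. This vignette
documents the models and estimators, the tunable parameters with their
units and defaults, the numerical choices, and the known limits of what the
synthetic validation shows.

## Units

API boundaries use mV, pA, MΩ, pF and ms; time vectors inside `trace`
objects are in seconds. The unit identities used throughout:
mV/MΩ = nA, MΩ·pF = µs, ms/MΩ = nF, pF·V/s = pA, and
1 µF/cm² = 0.01 pF/µm².

## Passive properties from the seal test

The whole-cell membrane test is modelled as the pipette series resistance
$R_s$ feeding the parallel pair ($R_m$, $C_m$). A command step $\Delta V$
(default −5 mV) elicits

$$I(t) = \frac{\Delta V}{R_s + R_m} +
  \left(\frac{\Delta V}{R_s} - \frac{\Delta V}{R_s+R_m}\right)
  e^{-t/\tau}, \qquad \tau = C_m \frac{R_s R_m}{R_s + R_m}.$$

`analyze_seal_test()` implements the conventional estimators exactly as
practitioners print them: $R_s = |\Delta V| / |I_{max}|$ from the
capacitive peak, $R_{In} = |\Delta V| / |I_{mem}|$ from the steady-state
current, and $C_m = \tau / R_s$. On a true RC cell these recover
$R_s$ exactly, $R_{In} = R_s + R_m$, and $C_m^{est} = C_m R_m/(R_s+R_m)$ —
the input resistance includes the series resistance and the capacitance
carries a known bias factor. The package asserts these identities in its
tests rather than hiding them; `corrected = TRUE` reports
$R_{In} - R_s$ and $\tau(1/R_s + 1/R_m)$ instead.

Numerical choices (the acquisition convention is silent on all of them):

- Baseline: mean over the 10 ms immediately pre-step; all currents are
  baseline-subtracted, which makes every estimate invariant to a constant
  holding current.
- $I_{mem}$: mean over the final 20% of the step. The simulator therefore
  extends the step to at least 15τ when τ is large, so the transient has
  decayed below the 0.1% tolerance inside the averaging window.
- τ fit: window from two samples after the peak down to 5% of the transient
  amplitude above $I_{mem}$; log-linear regression initializes a
  Levenberg–Marquardt refinement (`minpack.lm::nlsLM`). The fit $r^2$ must
  exceed 0.9, otherwise a quality error is raised. A transient smaller than
  the noise floor (or a pure resistor) yields τ = 0, $C_m$ = 0 with a flag.
- The first sample at step onset carries the unfiltered peak $\Delta V/R_s$
  — the generator's convention, matching the idealized circuit. When
  τ < 1% of a sampling interval the transient is unresolvable and the
  generator omits it (the capacitor-removed limit).
- Seal tests are generated at 2 µs sampling by default: time constants at
  the small end of the physiological grid (tens of µs) need this resolution
  for the decay fit. Step-protocol voltage traces use 10 kHz, the usual
  acquisition rate.

## Firing analysis

Spikes are upward crossings of 0 mV that reach a local maximum within 2 ms
and rise with ≥ 20 mV prominence over the preceding 2 ms; a 1 ms refractory
rule suppresses double counts, and a crossing within one peak-latency after
step offset still counts (an AP initiated at the end of a step completes
after it). Rheobase is the smallest amplitude of the 5 pA-step protocol
with ≥ 1 detected spike, so protocol quantization biases it upward by at
most one 5 pA step relative to the continuous threshold current. Firing
frequency is spike count over step duration (not 1/ISI), and the
input–output gain is the maximum finite-difference slope of the f–I curve,
reported with the current at the midpoint of the maximizing interval;
optional 3-point smoothing is off by default. The field also reports a
"voltage at maximal gain"; its definition is ambiguous, so the package
exports the raw ingredients (the f–I curve and per-step voltages) and does
not guess.

## AP waveform metrics

dV/dt is computed by central differences in V/s and paired with voltage
(the phase plot). AP threshold is the voltage at the first upward crossing
of the 20 V/s criterion before the peak, linearly interpolated between
samples. Half-width is measured at threshold + (peak − threshold)/2 with
both flanks interpolated; the 50% reference is threshold-to-peak, a choice
the package documents because conventions differ. Max/min dV/dt are the
global extrema within the single-AP window.

The rising phase between threshold and peak is scanned for local maxima of
dV/dt after mild Savitzky–Golay smoothing (window 7, order 3; applied for
peak-finding only, default on). With ≥ 2 maxima of topographic prominence
≥ 10 V/s, the first (lower-voltage) maximum is the initial-segment (IS)
component and the absolute maximum the somatodendritic (SD) component;
a single maximum means a monophasic AP whose only component is attributed
to the AIS, as in immature neurons. Raising the prominence cutoff can only
merge components, never split them.

After-potentials are measured from the downward threshold recrossing over a
100 ms window (truncated at the next spike; < 5 ms flags the profile
unresolved), with amplitudes signed relative to threshold. A tri-phasic
profile requires fast AHP (local minimum), ADP (local maximum) and a later
slow AHP, each with ≥ 0.5 mV prominence; anything else is mono-phasic with
the deepest excursion reported.

## Two-compartment model

The mechanistic generator couples a soma (150 pF) to a small AIS
compartment (5 pF) through an axial conductance (80 nS ≈ 12.5 MΩ). Each
compartment carries leak, instantaneous-activation sodium
($m_\infty^3 h$, first-order $h$) and first-order potassium currents; AIS
sodium activation is shifted −18 mV, emulating the hyperpolarized
activation of AIS channels. Integration is fixed-step RK4 (`deSolve`) at
dt ≤ 0.01 ms; exceeding ±200 mV raises a stability error naming dt.

The defaults were chosen so the model reproduces the qualitative
phase-plane phenomenology that motivates the IS/SD decomposition: the AIS,
with its small capacitance and dense, left-shifted sodium conductance,
fires first and its axial current produces the first somatic dV/dt maximum;
somatic sodium then ignites and produces the absolute maximum. With
`gNa_soma = 0` only the axial surge remains and the somatic AP is
monophasic; increasing `gNa_ais` raises the IS/SD ratio monotonically,
hyperpolarizes the detected threshold and raises max dV/dt. Peak dV/dt
values (~150–170 V/s) sit at the lower end of the physiological range — the
model is a minimal mechanism demonstrator, not a fitted neuron model.

## Analytic AP waveforms

For cohort-scale waveform analysis the package also generates APs by
integrating a *designed* dV/dt profile (`simulate_ap_waveform()`): Gaussian
rising-phase bumps whose amplitudes are exactly the prescribed IS and SD
components, a sub-criterion approach ramp (max 12 V/s) so the 20 V/s
criterion crosses at the prescribed threshold, a repolarization lobe, and
mono- or tri-phasic after-potentials built the same way. This gives every
cell phase-plane ground truth by construction, at 200 kHz so derivatives
are faithful. The slow AHP is made to undershoot the resting potential so
it remains a genuine local minimum before the exponential tail back to
rest. Residual bump overlap biases the measured threshold by well under
1 mV at the default geometries.

## AIS morphometry

Profiles are modelled as an ideal plateau between the true boundaries
convolved with a Gaussian PSF — error-function edges — sampled at pixel
centers with additive, zero-clipped Gaussian noise. `measure_ais()`
subtracts the profile minimum (without this, high backgrounds inflate
lengths), optionally smooths with a 3-pixel moving average (default on, for
noisy data), and finds the first and last positions surpassing the
threshold fraction of the maximum, linearly interpolated. For a blurred
edge the measured boundary sits $\sigma\,|\Phi^{-1}(f)|$ outside the true
edge; the tests verify this closed form across σ ∈ [0.2, 0.6] µm. When one
pixel step spans more than 45% of the dynamic range the edge is not
resolved by the sampling and interpolation across it is meaningless; the
boundary then snaps to the first suprathreshold pixel, which makes the
zero-blur case exact. With several disjoint suprathreshold runs (nodes of
Ranvier in the background) the longest run is measured and the result
flagged. The default threshold fraction is 0.3 with per-image override in
[0.1, 0.3], mirroring staining-dependent practice; length is monotone
non-increasing in the fraction and invariant to global intensity scaling.
Note that the 3-pixel smoothing trades a sub-pixel edge bias (worst ≈ 1.5
pixels at hard edges) for noise robustness; the oracle-exactness tests
therefore run with smoothing off.

Diameter is the interpolated FWHM of the background-subtracted profile
perpendicular to the AIS axis; profile extraction from images uses bilinear
interpolation along the polyline with optional perpendicular averaging.
"Distance to soma" is reported as the start position relative to the
user-drawn profile origin, since no sharper anatomical reference is
available in a line profile.

## Derived biophysics

AIS capacitance uses an open cylinder, $C_{AIS} = \pi d L c_m$ with
$c_m$ = 1 µF/cm² by default (configurable, echoed in the output); the
estimated AIS inward current is $C_{AIS}$ × IS in pA. The rheobase–$R_{In}$
relation is fitted in current space with the single free parameter $V$:
minimizing $\sum_i (I_i - V/R_i)^2$ gives the closed form
$V = \sum (I_i/R_i) / \sum (1/R_i^2)$. End-to-end, the +0…5 pA rheobase
quantization propagates into an upward bias of $V$ of at most
5 pA × mean($R_{In}$); the tests bracket the recovered $V$ between fits
against the continuous oracle and oracle + 5 pA. Because the printed
$R_{In}$ includes $R_s$, the end-to-end recovery of the generating
depolarization uses the corrected $R_{In} - R_s$.

## Group statistics

Technical replicates are collapsed according to the design: AIS lengths are
averaged per animal (the animal is the biological replicate), single-cell
recordings enter as independent samples. Every group is tested with
Shapiro–Wilk; only if all groups pass at α does the pipeline use one-way
ANOVA with Bonferroni-corrected pooled-SD pairwise t tests, otherwise
Kruskal–Wallis with Dunn's rank-based z tests (tie-corrected,
Bonferroni-adjusted). The all-groups-must-pass gate and the test choice are
documented, configurable conventions — the branching is a pure function of
the normality p-values and α. Post hoc tests are gated on a significant
omnibus by default. Under the null (5 × 20 normal samples, 1000
replications) the branching procedure's type-I error stays within
[0.03, 0.07]. Stars follow the printed cutoffs (p < 0.05/0.01/0.001).

## Synthetic cohorts and the pipeline

`generate_cohort()` draws per-cell ground truth from group-level normal
distributions (truncated away from non-physical values) and generates, per
cell, a noisy seal test, a 5 pA-step LIF protocol whose membrane time
constant is $R_m C_m$, an analytic AP waveform, and a blurred AIS profile;
everything derives from one master seed, with per-cell sub-seeds drawn up
front so the manifest is reproducible independent of which signals are
generated. The default young/adult regimes encode the maturation pattern at
realistic magnitudes (young: ~60 pF, ~600 MΩ, rest −58 mV, AIS ~13 µm,
monophasic IS ~150 V/s; adult: ~180 pF, ~150 MΩ, rest −70 mV, AIS ~27 µm,
biphasic IS ~320 V/s with IS/SD ~0.55; threshold depolarization 16 mV in
both). `run_pipeline()` analyzes each cell with failure isolation (a
corrupt file costs one cell, not the run), fits the rheobase hyperbola
across cells, and runs the group statistics per feature.

Problem sizes in the shipped validation — a 5×5×5 passive grid, 100 random
LIF cells, 5-point conductance sweeps, 12-point blur/threshold grids,
24-cell hyperbola cohorts, 1000-replication null calibration, and 4×5
cells/group cohorts — were chosen so each check exercises the full
physiological range while the whole suite runs in minutes on one core.

## What the synthetic validation does and does not show

The generators realize the package's own forward models: the RC circuit,
the leaky integrator with pasted stereotyped spikes (used solely for
rheobase/f–I logic, never waveform metrics), the designed-dV/dt AP, the
error-function edge model. Passing tests therefore demonstrate correct
estimator algebra, correct threshold/interpolation logic, quantization
behavior and statistical calibration — not robustness to everything real
recordings contain (electrode drift, seal instability, dendritic
filtering, curved or dim AISs, bleed-through). The two-compartment model
provides a mechanistic, model-independent check for the IS/SD analysis,
and additive-noise Monte Carlo covers first-order noise sensitivity, but
claims about real-data performance must come from real data. No further
filtering is applied during analysis by default (acquisition-time filtering
is assumed); Savitzky–Golay options exist where derivatives are involved.
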