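---
title: "Models and methods behind cardioclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardioclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioclamp)
```

cardioclamp analyzes the in-vitro electrophysiology of hiPSC-derived
cardiomyocytes: sodium-current gating from whole-cell voltage clamp,
action-potential (AP) features from current clamp, Ca²⁺ transient
morphology from fluorescence imaging, field potentials from microelectrode
arrays (MEA), and allelic imbalance from qPCR. This vignette explains the
models each stage assumes, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the underlying conventions are genuinely open.

## Voltage-clamp gating analysis

### Steady-state curves

Activation and availability (steady-state inactivation) are modeled by the
Boltzmann sigmoid

$$y(V) = \frac{A}{1 + \exp\!\big((V_{1/2} - V)/k\big)},$$

with the decreasing form for availability. `fit_boltzmann()` uses bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`) with data-driven starting values:
$V_{1/2}$ from the half-range crossing of the monotone envelope, $k$ from
the 10–90% span divided by $2\ln 9 \approx 4.39$ (exact for a noiseless
sigmoid), and $A$ from the response range. Up to five jittered restarts are
attempted on non-convergence. The slope factor is always reported positive;
orientation is handled by the model form, not by the sign of $k$. Because
the fit is least squares on the raw responses, $V_{1/2}$ and $k$ are
invariant to uniform scaling of the response — normalization conventions do
not move the gating parameters.

Conductance is obtained from peak current densities as
$g(V) = I(V)/(V - E_\mathrm{rev})$. Points within ±2.5 mV of the reversal
potential — half of the protocol's 5-mV increment — are excluded, because
the driving force vanishes there and the ratio becomes noise-dominated.

### Peak currents and capacitance

Peak currents are the signed extremum inside a search window after blanking
the first 0.5 ms following the step (capacitive artifact; configurable). A
0.25-ms moving average precedes the extremum search: picking the single
largest sample of a noisy trace is biased outward, and light smoothing
removes most of that bias without flattening a real peak. Membrane
capacitance integrates the baseline-subtracted capacitive transient of a
small step and divides by the step: with current in pA, time in ms and the
step in mV the result is in pF.

### Kinetics

Current decay after the peak, recovery from inactivation (P2/P1 vs
recovery interval), and entry into slow inactivation (P2/P1 vs conditioning
duration) are all biexponential forms fitted by `fit_biexp()`:

* decay: $y = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}$
* recovery: $y = 1 - A_f e^{-t/\tau_f} - A_s e^{-t/\tau_s}$
* entry: $y = C + A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}$

Initialization is by log-linear segments: the tail of the decaying quantity
gives $\tau_s$, the early residual after subtracting the slow component
gives $\tau_f$. Components are relabeled after fitting so that
$\tau_{fast} < \tau_{slow}$, which resolves the labeling ambiguity of the
sum-of-exponentials form. When the two time constants collapse (ratio below
1.5) or one amplitude carries less than 1% of the total, the fit falls back
to a monoexponential and flags it (`$mono`), rather than reporting two
meaningless near-equal constants. Recovery amplitudes are not constrained
to sum to one; the round-trip tests verify that the unconstrained fit
recovers generators that do satisfy $A_f + A_s = 1$.

The decay fit anchors its time base at the *last* sample attaining the
extremum, so a flat-topped peak contributes no artificial plateau to the
fitted decay.

## The synthetic generator as ground truth

Every analysis stage has a paired generator whose parameters are the
quantities the stage estimates, which turns parameter recovery into a
round-trip contract: noiseless data must be inverted to numerical
precision, and noisy data at realistic sample sizes must recover the
generating values within the corresponding dispersion.

* `simulate_iv_family()` builds step families (default −60 to 80 mV in 5-mV
  steps from −100 mV holding, 20 kHz) whose peak current is
  $G_{max}\,act_\infty(V)\,(V - E_\mathrm{rev})$ — availability is complete
  at the holding potential — with biexponential decay at the model's
  voltage-dependent time constants. The current holds its peak for a 1-ms
  latency before decaying, so artifact blanking shorter than the latency
  never clips the peak. Activation kinetics are not otherwise modeled.
* `simulate_activation_curve()` / `simulate_availability_curve()` emit the
  normalized steady-state points directly with additive Gaussian noise —
  the natural noise model for curve-level fits.
* `simulate_recovery_protocol()` / `simulate_slowentry_protocol()` evaluate
  the closed-form double-pulse curves (default intervals 5–1500 ms and
  durations 5–2000 ms, the standard series) plus noise, clipped at zero so
  noise cannot produce negative availability.
* `simulate_ap_train()` renders APs from target features, not biophysics:
  an exponential upstroke with time constant $APA/V_{max}$ multiplied by a
  logistic repolarization whose midpoint and slope place the 50% and 90%
  crossings at APD50 and APD90. Spike-and-dome morphology is a Gaussian
  notch in early repolarization; triggered activity (TA) is a raised-cosine
  diastolic hump (default 25 mV, 80 ms) at a chosen coupling interval.
* `simulate_ca_trace()` uses triangular transients (linear rise and decay
  sized so the 10–90% and 90–10% spans match the targets) at 25 Hz, with
  abnormality directives that elevate troughs (OS), insert fractional-
  amplitude events (LP), modulate amplitudes to a chosen coefficient of
  variation (VA), or stretch single events (PA/RD).
* `simulate_mea_trace()` places a biphasic derivative-of-Gaussian spike at
  each beat and a slow repolarization wave at the target FPD (10 kHz).
* `simulate_ct_table()` draws replicate Ct values from the log-linear
  amount model, under which $\Delta C_t = \log_2(\mathrm{WT/mut})$ at
  perfect efficiency.

All noise is additive, i.i.d. Gaussian, and every generator takes a seed;
the caller's RNG stream is never disturbed. What the generator does *not*
emulate: Markov-state channel gating, stochastic channel noise, baseline
drift and photobleaching in fluorescence, electrode motion artifacts,
cell-to-cell parameter heterogeneity beyond measurement noise, and
multicellular conduction. Passing round-trip tests therefore demonstrates
the correctness of the estimators under the stated signal models, not
robustness to every pathology of real recordings.

Defaults follow the study conditions the package targets: 20 kHz
patch-clamp sampling, 25 Hz Ca²⁺ imaging (within the typical 20–30 Hz),
10 kHz MEA, 60 fps video, wild-type gating constants
$V_{1/2,act} = -31$ mV, $k_{act} = 6$ mV, $V_{1/2,inact} = -71.5$ mV,
$k_{inact} = 9.9$ mV, recovery $\tau_f = 74.8$ ms / $\tau_s = 700.3$ ms
(`gating_model_preset()` carries the asymptomatic- and symptomatic-line
sets). Two quantities have no reported values and were fixed once as
package defaults: the recovery amplitude split ($A_f = 0.6$, complement on
the slow component, full recovery at long intervals) and the
slow-inactivation entry constants ($\tau_f = 100$ ms, $\tau_s = 1000$ ms,
steady availability 0.35). Both are configurable model fields.

## AP feature extraction

dV/dt is computed as a 0.5-ms span slope, which suppresses sample-to-sample
noise the way an acquisition low-pass filter would. Upstrokes require
dV/dt > 2 V/s sustained for 1 ms; events whose amplitude is below 40 mV are
rejected as subthreshold (TA humps rise at about 1 V/s and never pass).
APDx is measured from the time of maximal dV/dt to the downward crossing of
$MDP + (1 - x/100)\,APA$, with sub-sample linear interpolation; the MDP is
the diastolic minimum preceding each upstroke. These detection criteria and
the APD reference point are package conventions — acquisition software
vendors differ on both — and are exposed as arguments.

TA detection scans each diastolic interval (after the 90% repolarization
plus a 30-ms margin, up to 30 ms before the next upstroke) for excursions
more than 10 mV above the interval's median after 5-ms smoothing; contiguous
excursions count once. A cell is arrhythmic iff at least one TA event
fires. Spike-and-dome requires a local minimum within the first 25% of
APD90 followed by a local maximum exceeding it by more than 2 mV. The
ventricular-like call is strict on both boundaries: APD90/APD50 < 1.35 and
APA > 90 mV; ties classify as "other".

Contraction analysis measures, per motion event, the time from the
half-maximum crossing on the rising phase to the peak and from the peak to
the falling half-maximum crossing. Alignment to the AP time base uses the
first synchronization pulse; without pulses the analysis proceeds unaligned
with a warning.

## Ca²⁺ abnormality taxonomy

Preprocessing subtracts the background and normalizes to
$F_0$ = 10th percentile of the background-subtracted trace (a robust
baseline that tolerates up to ~90% of samples sitting on transients).
Events need prominence at least 4× the baseline noise SD (estimated from
the running-median residual) and 150-ms separation.

The five rules are deliberately ratio- and shape-based so that the calls
are invariant to uniform rescaling of the fluorescence:

* **OS** — two or more consecutive full-size peaks whose intervening
  troughs stay above baseline + 10% of the median amplitude. "Returning to
  baseline" needs a noise-robust band; 10% of the median amplitude is that
  band.
* **LP** — an event of at least 10% (strict boundary: 9.9% does not fire)
  and below 45% of the preceding full-size amplitude. Events under 10% are
  treated as sub-threshold deflections and excluded from all statistics;
  the 45% upper bound separates genuinely low-amplitude events from
  ordinary beat-to-beat amplitude variation, which reaches ratios near 0.5
  when the amplitude CV approaches 35%.
* **VA** — amplitude CV above 20% over any 5 consecutive full-size events.
  Amplitudes for this rule are peak heights above baseline, not
  trough-referenced amplitudes, so that OS trough elevation cannot
  masquerade as amplitude variation.
* **PA / RD** — decay 90–10% (resp. rise 10–90%) above 2× the cell's median.
  "Prolonged" has no published threshold; the factor-of-two default is an
  explicit knob, not a claim about the original criteria.

A cell is normal iff no rule fires; multiple labels are allowed, and the
cohort summary reports the percentage of abnormal cells per condition plus
the per-type breakdown and baseline-vs-drug deltas.

## MEA analysis

Depolarization spikes are the largest-magnitude deflections (above half the
trace maximum, 250-ms refractory). The FPD endpoint is the
largest-magnitude deflection in a polarity-agnostic window from 120 ms
after the spike to 92% of the median beat interval (capped before the next
spike) — the repolarization wave's sign depends on electrode position, so
polarity cannot be assumed. Bazett correction uses RR in seconds,
$FPD_c = FPD/\sqrt{RR}$, the identity at 60 BPM. Records with rates below
20 or above 90 BPM are excluded *before* any averaging, to avoid over- or
under-correction at extreme rates. Arrhythmia is an interbeat-interval CV
above 15% or any premature interval below half the median.

## qPCR

The standard curve regresses $\Delta C_t = C_t(\mathrm{mut}) -
C_t(\mathrm{WT})$ (the WT Ct subtracted from the mutant Ct) on
$\log_2(\mathrm{WT/mut})$ over the mixes with finite log-ratios; the pure
single-allele mixes (1/0, 0/1) have undefined log-ratios and are kept as
qualitative controls only. Replicate Cts are averaged per mix and allele
before differencing, and replicate SDs propagate to the curve points in
quadrature. Ratio interpolation inverts the line,
$r = 2^{(\Delta C_t - b)/m}$, flagging extrapolation beyond the calibrated
range. ΔΔCt expression supports both normalization modes — the endogenous
control (GAPDH) alone, or a second-stage normalization to a reference gene's
fold (TNNT2) — because published workflows are ambiguous between them; both
are returned and the caller chooses.

## Cohort statistics

`compare_groups()` delegates to `stats::kruskal.test` and
`stats::wilcox.test`; Dunn's pairwise rank test (z statistics on joint mean
ranks with tie correction) is implemented in the package and checked
against externally computed reference values. Bands follow the
ns / * / ** / *** convention at 0.05 / 0.01 / 0.001. A pooling helper
merges two lines into one label only when a rank-sum test finds no
difference, mirroring the practice of pooling indistinguishable control
lines before cross-line comparison.

## Problem sizes and limitations

The test suite and the acceptance script run entirely on synthetic data at
the per-group sample sizes typical of this experiment class: 16–19 cells
for steady-state curve fits, 8 replicates for double-pulse kinetics, cohorts
of tens of cells for AP/Ca²⁺/MEA summaries, recordings of 8–40 s. These
sizes keep the default end-to-end run in the seconds-to-minutes range on a
single CPU.

Known limitations: no leak subtraction or series-resistance/liquid-junction
correction is applied (hardware compensation is treated as metadata); no
temperature (Q10) correction; one MEA channel is analyzed at a time; the
Ca²⁺ event model assumes a stable baseline; and the AP template
parameterizes features directly rather than emerging from ionic currents,
so it cannot probe mechanisms — only the measurement pipeline.
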