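---
title: "Closed-loop deep brain stimulation in a conductance-based STN-GPe network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop deep brain stimulation in a conductance-based STN-GPe network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`stngpe` simulates two reciprocally coupled populations of `N = 200`
conductance-based neurons each: an excitatory subthalamic (STN) population
and an inhibitory external-pallidal (GPe) population. Every cell follows
the Hodgkin-Huxley-type system

```
C_m v' = -I_L - I_K - I_Na - I_T - I_Ca - I_AHP - I_syn + I_app + I_stim
[Ca]'  = eps (-I_Ca - I_T - k_Ca [Ca])
X'     = phi_X (X_inf(v) - X) / tau_X(v),  X in {n, h, r}
```

with leak, delayed-rectifier potassium, sodium, low- and high-threshold
calcium and calcium-gated afterhyperpolarisation currents; steady states
are logistic in `v` and the low-threshold calcium current uses
`b_inf(r)^2` for STN cells and `r` directly for GPe cells. Synaptic
variables obey `s' = alpha H_inf(v_pre - theta_g)(1 - s) - beta s`, and
coupling currents are `I_syn = g (v - v_rev) * sum(s_pre)` with the
weights `g_STN->GPe = 0.4` and `g_GPe->STN = 1.38` nS/um^2 and reversal
potentials 0 and -100 mV. Cells are made non-identical through Gaussian
per-cell applied currents on the STN side (mean 10, sd 0.015 pA/um^2) and
Gaussian calcium rates on the GPe side (mean 0.0055, sd 2e-5 ms^-1). Each
STN cell excites one GPe cell; each GPe cell inhibits three STN cells on
the periodic ring.

## Parameter provenance and calibration

The cell-level constants are not uniquely fixed by the network-level
description above, and different members of the Terman-Rubin model family
differ in exactly these constants. The package ships a single documented
default set (`stn_params()`, `gpe_params()`, `dump_default_params()`),
built in two steps:

1. All gating midpoints, slopes, voltage-dependent time constants, rate
   scales and most conductances follow the published Terman-Rubin
   subthalamopallidal cell models, including the rebound-capable variant
   of the STN low-threshold calcium current (`theta_b = 0.25`,
   `sigma_b = -0.07`, fast `r` kinetics).
2. The constants that select the *collective regime* — the STN leak
   (`g_L = 2.8`, `v_L = -65`) and T-current strength (`g_T = 1.2`), the
   GPe bias current (0.5 pA/um^2), GPe calcium clearance (`k_Ca = 1.5`),
   GPe afterhyperpolarisation strength (40 nS/um^2), and the synaptic
   rates (`beta = 2` ms^-1 excitatory, `alpha = 2`, `beta = 0.15` ms^-1
   inhibitory, `sigma_gH = 2` mV) — were calibrated once, on
   stimulation-free runs only, so that the default network exhibits a
   robust, strongly synchronized collective rhythm whose filtered-LFP
   maxima sit just above the stimulation-control threshold scale
   (`Th_on = 0.016`) used throughout. They were frozen before any
   closed-loop operating point was evaluated and are not revisited.

With these defaults the stimulation-free network settles into an episodic
relaxation rhythm: population-wide bursting episodes alternating with
near-silent epochs, at a mean LFP envelope period of roughly 0.5 s and a
time-averaged order parameter around 0.6-0.75. Mechanistically the
episodes are carried by the loop "STN volley -> pallidal volley -> slow
inhibition and pallidal calcium build-up -> release -> subthalamic
rebound", with the GPe calcium clearance time constant
(`1/(eps * k_Ca)` = 120 ms) as the pacing slow variable.

### Known limitation

The calibrated rhythm is substantially slower than the low-beta
(~10 Hz) oscillation this model family is usually tuned to: the episodic
envelope at ~2 Hz plays the role of the beta-band LFP oscillation. A
systematic search over the under-determined constants (bias currents,
synaptic rates, calcium kinetics, leak and T-current settings; grid scans,
random search and hill climbing over several thousand short network
integrations) did not locate a parameterisation of this exact network in
which a globally coherent ~10 Hz in-phase state is transversally stable:
fast spike-locked inhibition with a one-to-one excitatory return makes
the in-phase volley state unstable, and the stable collective states are
either asynchronous, clustered, or the episodic rhythm adopted here. All
frequency-referenced quantities (the filter centre period, burst
statistics) therefore refer to the calibrated envelope rhythm, and the
synchronization frequency reported by the package is the calibrated one,
not 9.7 Hz. Everything downstream — thresholds, gating, delayed feedback,
burst analytics — operates on this rhythm exactly as specified.

### Topology and initial state

Two further design choices were forced by the same stability analysis:

* **Inhibitory fan placement.** The three STN targets of each GPe cell
  default to a symmetric spread around the ring
  (`fan_offsets = c(-round(N/3), 0, round(N/3))`). With a strictly
  centred local fan (`c(-1, 0, 1)`, available as an option and the
  default of `build_lattice()`), collective order fragments into
  traveling waves and the global order parameter saturates near 0.35;
  the spread placement provides the long-range mixing that global
  synchrony on a ring otherwise lacks.
* **Initial conditions.** `initial_state()` defaults to a narrow voltage
  band (`"synchronized"`), preparing the established pathological state
  that stimulation protocols act on; a `"dispersed"` mode
  (v ~ U(-80, -40) mV) is available. From dispersed states the
  synchronized attractor is generally not reached within tens of
  seconds, matching the observation above.

## Observables

* **LFP**: the instantaneous mean of the STN synaptic variables.
* **Filtered LFP**: the damped-oscillator filter
  `u'' + alpha_d u' + omega^2 u = k_f LFP(t)` with
  `alpha_d = k_f = 0.008` and output `x = u'`, which has unit gain and
  zero phase at resonance. The centre period defaults to 500 ms, the
  calibrated mean envelope period of the default network
  (`lfp_envelope_period()` re-estimates it from any stimulation-free
  run). The filter advances by its exact zero-order-hold propagator each
  step, so it is unconditionally stable at any `dt`.
* **Order parameter**: spikes are detected at upward crossings of -10 mV
  with a 2-ms lockout; bursts are grouped with a 25-ms inter-spike gap;
  each neuron's phase grows linearly between consecutive burst onsets
  (`psi(t_n) = 2 pi n`); `R(t)` is the modulus of the population-mean
  phasor, with neurons excluded while their phase is undefined (before
  the first or after the last onset).
* **Summary scalars**: time-averaged `R`, stimulation-on fraction
  `T_on`, administered stimulation `<|S|>` and the mean LFP period, all
  over a window that starts a configurable transient after stimulation
  onset.

## Stimulation

All four controllers modulate the same charge-balanced biphasic pulse
train (130 Hz, 0.2-ms cathodic phase of relative amplitude -10, optional
interphase gap, 2-ms anodic recharge phase of relative amplitude +1). The
gap may range up to `1000/F - 11 PW` = 5.49 ms before the recharge phase
is truncated, and beyond `1000/F - PW` = 7.49 ms the pulse is monophasic.
The modulating amplitude is sampled once per pulse at its onset:

* `cDBS` — constant amplitude `K`;
* `aDBS` — amplitude `K` gated on/off: the gate opens when a local
  maximum of the filtered LFP exceeds `Th_on` and closes when a maximum
  falls below `Th_off` (local maxima are detected online as a sign
  change of the discrete derivative on the integration grid);
* `cpLDF` — amplitude `S(t) = K (x(t - tau) - x(t))` from the delayed
  filtered LFP (delay buffer at the integration step, nearest-sample
  lookup, zero-padded before the filter has history);
* `apLDF` — `cpLDF` gated like `aDBS`.

At stimulation onset the intensity ramps linearly over `T_ramp` ms;
protocol averaging (`run_protocol()`) repeats each condition over evenly
spaced ramps in [0, 2000] ms with distinct initial-condition seeds, which
is also how every reported operating point is computed. Stimulation
current is injected identically into every STN cell; GPe cells are not
stimulated.

## Numerics

Fixed-step classical Runge-Kutta (RK4) over the full coupled system, with
the stimulation current held piecewise-constant across each step (pulse
edges snap to the grid, at most half a step of edge error). The default
step is `dt = 0.05` ms — eight steps per cathodic phase width of 0.4...
precisely, four steps per 0.2-ms phase — validated two ways: a
convergence test of an isolated cell against an adaptive reference solver
(`deSolve::lsoda`) and a dt-halving robustness check of the
post-transient summary against across-seed variability. The linear filter
uses its exact propagator, and the delayed sample `x(t - tau)` is a
nearest-grid lookup (tau/dt is integral for the defaults). The RHS core
is compiled (Rcpp); an R reference implementation of every building block
is exported and cross-checked against the compiled path in the test
suite.

## Burst analytics

Following the amplitude-envelope convention, the order-parameter trace is
smoothed with a centred 400-ms moving average evaluated every 10 ms;
bursts open at upward crossings of the smoothed trace's 75th percentile
and close at the next downward crossing of the 65th percentile
(percentiles of the analysis window, linear-interpolation convention).
Bursts cut by the window edges are discarded. Summary statistics are the
mean and median burst length, the fraction shorter than 5 s and a 1-s-bin
histogram; two burst-length samples are compared with a two-sided
Mann-Whitney test (an exact permutation variant is available for small
samples).

## Problem sizes used by the reproduction script

`scripts/acceptance.R` runs the full `N = 200 + 200` network throughout:
a 40-s stimulation-free run (summary over the final 20 s) for the
baseline state, and 18-s runs (onset at 5 s, summary from 8 s) averaged
over three ramp schedules for each adaptive operating point; the
efficiency scan evaluates three intensities with single runs. These
durations are the package's scaled-down protocol; they trade averaging
depth for runtime and are the sizes at which the reported numbers were
produced.

## What the tests do and do not show

The unit and property suites exercise every formula against closed forms,
brute-force re-computations and an independent adaptive integrator, and
the full pipeline on small fast networks. The acceptance suite runs the
study conditions and compares against the published operating points;
with the calibrated regime described above, the checks tied to the
absolute oscillation frequency and to the exact baseline synchrony level
fail, and are left failing deliberately — they document the distance
between the calibrated regime and the reference one rather than being
weakened. Passing closed-loop checks show that gating, feedback,
charge-balance and efficiency mechanics behave as specified on the
calibrated rhythm; they do not establish quantitative agreement with the
reference operating points, nor, of course, anything about clinical DBS.The default step is `dt = 0.05` ms (four steps per 0.2-ms cathodic
phase), validated two ways: a
convergence test of an isolated cell against an adaptive reference solver
(`deSolve::lsoda`) and a dt-halving robustness check of the
post-transient summary against across-seed variability. The linear filter
uses its exact propagator, and the delayed sample `x(t - tau)` is a
nearest-grid lookup (tau/dt is integral for the defaults). The RHS core
is compiled (Rcpp); an R reference implementation of every building block
is exported and cross-checked against the compiled path in the test
suite.

## Burst analytics

Following the amplitude-envelope convention, the order-parameter trace is
smoothed with a centred 400-ms moving average evaluated every 10 ms;
bursts open at upward crossings of the smoothed trace's 75th percentile
and close at the next downward crossing of the 65th percentile
(percentiles of the analysis window, linear-interpolation convention).
Bursts cut by the window edges are discarded. Summary statistics are the
mean and median burst length, the fraction shorter than 5 s and a 1-s-bin
histogram; two burst-length samples are compared with a two-sided
Mann-Whitney test (an exact permutation variant is available for small
samples).

## Problem sizes used by the reproduction script

`scripts/acceptance.R` runs the full `N = 200 + 200` network throughout:
a 40-s stimulation-free run (summary over the final 20 s) for the
baseline state, and 18-s runs (onset at 5 s, summary from 8 s) averaged
over three ramp schedules for each adaptive operating point; the
efficiency scan evaluates three intensities with single runs. These
durations are the package's scaled-down protocol; they trade averaging
depth for runtime and are the sizes at which the reported numbers were
produced.

## What the tests do and do not show

The unit and property suites exercise every formula against closed forms,
brute-force re-computations and an independent adaptive integrator, and
the full pipeline on small fast networks. The acceptance suite runs the
study conditions and compares against the published operating points;
with the calibrated regime described above, the checks tied to the
absolute oscillation frequency and to the exact baseline synchrony level
fail, and are left failing deliberately — they document the distance
between the calibrated regime and the reference one rather than being
weakened. Passing closed-loop checks show that gating, feedback,
charge-balance and efficiency mechanics behave as specified on the
calibrated rhythm; they do not establish quantitative agreement with the
reference operating points, nor, of course, anything about clinical DBS.
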