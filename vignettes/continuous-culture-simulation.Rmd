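---
title: "Models and design of the virtuostat control engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the virtuostat control engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtuostat)
```

This vignette is the package's own account of what it simulates, which
assumptions those models make, and where the design was genuinely open.

## The optical chain

The detector is calibrated by two points: a dark signal (total obscurity,
0 % transmittance) and a blank signal (the cell-free reference liquid,
100 %). Everything downstream works on the calibrated percent transmittance

$$T = 100\,\frac{\mathrm{raw}-\mathrm{dark}}{\mathrm{blank}-\mathrm{dark}},$$

an affine, order-preserving map. Values outside [0, 100] are **flagged, not
clipped**: silent clipping would mask calibration drift, which on a real
instrument is the first symptom of a fouled blank or a failing emitter.

Absorbance $A=-\log_{10}(T/100)$ is additive across independent absorbers,
which gives the two forward models a common closure
$T = 100\cdot10^{-(A_\text{cells}+A_\text{medium})}$:

* **Turbidity**: $A_\text{cells} = k_\text{cell}\,X\,L$ with $X$ in CFU/mL
  and path length $L$ in cm. Linear in $X$ — the simulator stays in the
  pre-agglomeration, pre-stationary regime where Beer–Lambert holds.
* **Phenol red**: $A_\text{medium}(\mathrm{pH})$ is piecewise linear,
  $A_\min$ at or below pH 6 and $A_\max$ at or above pH 7, interpolated
  between. The linear window mirrors the range over which the 560 nm
  response of the indicator is empirically linear in pH; outside it the
  response is extrapolated *flat* rather than guessed.

Detector noise is additive Gaussian in **raw-signal space** (that is where a
real photoreceiver's noise lives), applied before calibration; `noise_sd = 0`
(the default for every preset and test) makes the chain exact. The boxcar
filter is a **trailing moving window**: at sample $k$ the mean of the last
$\min(k, n)$ samples. Whether the original instrument's averaging was a
moving window or a block average is not determinable from its description;
the moving window was chosen because it produces an output at every sample,
which the feedback modes need. Anyone matching the original acquisition
bit-for-bit should check this first.

## Culture dynamics

The vessel model is the minimal one that exhibits both continuous-culture
regimes:

$$\frac{dX}{dt}=\mu(S)X,\quad \frac{dS}{dt}=-\frac{\mu(S)X}{Y},\quad
\frac{dC}{dt}=q_\text{acid}\,\mu(S)X,\qquad
\mu(S)=\mu_\max\frac{S}{K_s+S}.$$

With $S\gg K_s$ growth is pinned at $\mu_\max$ (the turbidostat regime);
with limiting substrate the classical chemostat steady state
$S^\* = K_s D/(\mu_\max-D)$, $X^\* = Y(S_0-S^\*)$ emerges, and $D>\mu_\max$
washes the culture out. No particular kinetic law is implied by the
hardware being emulated; Monod is the field's default closure and the tests
hold the simulator to its closed forms.

pH is driven by a lumped acid state $C$ mixed volumetrically, with
$\mathrm{pH} = \max(\mathrm{pH}_\text{floor},\ \mathrm{pH}_0 - C/\beta)$ for
a linear buffer capacity $\beta$. Mixing pH values directly would be wrong —
pH is logarithmic — so dilution always mixes $C$ and re-derives pH. The
floor (default 4.0) only exists to keep pathological parameter choices
finite; it sits well below the phenol-red window.

**Integration** is classical RK4 with a fixed step of
$\min(\text{sample period}, 36\ \mathrm{s})$, no adaptive control, so runs
are deterministic and bit-reproducible. Halving the step moves a 12 h
trajectory endpoint by less than $10^{-6}$ relative, and the suite
cross-checks a 12 h trajectory against `deSolve::ode` (lsoda at
`rtol = 1e-10`) to $10^{-6}$. Substrate is clamped at zero inside the
derivative evaluations and floored after each step.

## Fluidics and the refresh cycle

Delivery is linear in valve-open time above a dead time,
$dV = r\,\max(0, t-\tau)$, defaulting to $r = 1$ mL/s and $\tau = 0$; the
dead time is exposed because real tubing has lag and flow calibration fits
an intercept. A refresh cycle is two steps: mix in the delivered volume,
then evacuate the excess above the working volume (removal of well-mixed
liquid changes no concentration). The concentration dilution factor per
cycle is therefore exactly $W/(W+dV)$. The overflow guard
$(C-W)/r+\tau$ is checked *before* any state change, and the simulated rig
enforces it independently, so no command sequence can push the vessel past
capacity.

Delivery is modeled as **instantaneous at the cycle's sample tick**: growth
is suspended while the valve is open and the simulated clock does not
advance during the cycle. Pinch times are at most 35 s against doubling
times of half an hour or more, so the neglected growth is below $10^{-3}$
relative per cycle; keeping dilution event-like keeps every log row on the
sampling grid.

## Controller semantics

All threshold comparisons are **inclusive** ($\geq$/$\leq$ at the
boundary), so in noise-free operation the trigger value itself is the
recorded extremum. Signal **polarity is an explicit configuration field**
(`growth_decreases_T` for turbidity, `growth_increases_T` for phenol red)
rather than being inferred from threshold ordering — in the time-interval
mode there is only one threshold, so inference would be ambiguous.

* *Real-time feedback*: on crossing the trigger in the growth direction the
  valve opens, and the calibrated signal is re-checked every 0.05 s of
  valve time (`valve_resolution`); the cycle closes at the release
  crossing. That makes the stop event-exact to within one 0.05 mL slice.
  Cycles are capped at `max_cycle_pinch_time`, with a one-sample settle and
  re-measurement between capped cycles.
* *Threshold-activated*: each activation runs exactly `n_cycles` calibrated
  cycles (one per sample tick, re-measuring between) and re-arms
  immediately; no refractory period is imposed because none is needed when
  the post-dilution signal sits clear of the trigger.
* *Time-interval*: once armed (at a fixed time, or at a transmittance
  crossing), a refresh runs every `period`; time-based stops split their
  total pinch time into overflow-safe cycles, threshold-based stops reuse
  the monitored cycle and give up after `cycle_cap` cycles (default 50)
  with a warning, since a stop threshold below the fresh-medium
  transmittance is unreachable. Whether the original controller also caps
  threshold-stopped refreshes is unknown; the cap is a safety choice.
* Filtering is applied to **calibrated transmittance**, not raw signal,
  before triggering; with an affine calibration the two are equivalent up
  to threshold units, and calibrated units are what the operator sets.

Channels are independent: a multi-channel run is executed as sequential
single-channel runs and the suite asserts log identity with individually
run channels. Each run seeds R's RNG from its recorded `seed`, so identical
configuration plus seed reproduces logs byte for byte.

## The simulated rig versus real cultures

The rig reproduces: exponential growth and its transmittance signature in
both polarities, substrate-limited slowdown, metabolic acidification,
volumetric dilution mixing, calibrated delivery with dead time, and
overflow. It deliberately does **not** reproduce: post-peak transmittance
decline from cell agglomeration, death phase, biofilm fouling of the
optical path, oxygen or temperature dynamics, plate-count (CFU) sampling
error, or flow-rate drift with bottle fill level. Passing tests therefore
demonstrate correctness of the control and analysis logic under the stated
growth model — not that a live culture will behave this cleanly; on
hardware, the same controller runs against a driver implementing the
three-function contract.

Preset parameter values are fixtures chosen once to match each scenario's
reported phenomenology, not measured constants: the turbidity preset uses
$\mu_\max = \ln 2/0.48\ \mathrm{h^{-1}}$ (≈25 doublings in 12 h) and
$k_\text{cell} = 6\times10^{-9}$ AU per CFU/mL (25 % transmittance at
$10^8$ CFU/mL); the phenol-red preset uses $\mu_\max = \ln 2/0.6$ (≈20
divisions in 12 h), $k_\text{cell}=0$, and an absorbance window mapping
fresh medium to 8 % and full acidification to 16 % transmittance; the yeast
preset slows $\mu_\max$ to $\ln 2/1.5$. Half-saturation constants are kept
at 0.02–0.05 g/L so the turbidostat regime is genuinely nutrient-unlimited
($\mu \geq 0.99\,\mu_\max$ between refreshes).

## Numerical conventions

* Quartiles: linear interpolation between order statistics
  (`quantile(type = 7)`); the box-plot ordering invariant
  (min ≤ whisker ≤ Q1 ≤ median ≤ Q3 ≤ whisker ≤ max) depends on the
  convention, so it is stated. Whiskers are 1.5·IQR fences clipped to data.
* Calibration fit windows (transmittance range, pH window) are explicit
  arguments, never hard-coded: which points belong to the exponential phase
  is an organism-specific judgment.
* Growth-rate estimation fits $\ln(-\log_{10}(T/100))$ against time in
  hours and refuses intervals containing refresh events.
* Generation accounting sums $\log_2((W+dV)/W)$ over refresh events; a log
  whose endpoints differ in transmittance gets a $\log_2(A_\text{end}/
  A_\text{start})$ correction (turbidity only — a phenol-red signal does
  not encode cell density) and a warning.
* YAML configs are written with 15 significant digits; log CSVs with 17
  (`%.17g`), so a written-and-reread log is bit-identical.

## Problem sizes

The test suite and the acceptance script run closed-loop simulations of 12
simulated hours at the scenarios' own sampling rates (0.5 s and 5 s:
86 400 and 8 640 control steps), a 60 h chemostat at 12 s sampling, and a
32 h washout run; the whole suite completes in well under a minute on one
core. These sizes were chosen as the smallest that exercise each regime's
steady state — the chemostat needs tens of dilution time-constants to
settle within 1 % of the Monod fixed point.

## Known limitations

Real-hardware pacing (`Sys.sleep` against the wall clock) is implemented
but untested against a physical driver. The fluorescence channel present in
some hardware is out of scope, as is any GUI. The time-interval mode's
threshold-stop cycle cap and the moving-window filter are the two places
where this implementation may deviate from the original instrument's
(undocumented) behavior; both are flagged above.
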