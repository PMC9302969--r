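---
title: "Quasi-linear characterization of cholinergic-interneuron membranes and dendrites: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-linear characterization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlincable)
```

## The scientific problem

Striatal cholinergic interneurons (CINs) pace-make autonomously and filter
their synaptic inputs through voltage-dependent subthreshold currents: the
persistent sodium current (NaP), a regenerative conductance that *amplifies*
slow inputs, and the HCN current, a restorative conductance that produces a
subhertz *resonance*. Because individual synaptic inputs are small, these
nonlinearities can be linearized around the holding potential — the
quasi-linear approximation — turning the membrane into a linear
time-invariant filter that is fully described by a complex admittance.
This package implements that description end to end: the forward models,
time-domain simulators that realize the same physics independently,
estimators that recover phase and impedance curves from sinusoidal sweep
recordings, least-squares fitting of the model parameters, and the
downstream analyses the framework feeds into (dendritic calcium profiles of
backpropagating spikes, sleep slow-wave/spindle detection with peri-event
firing statistics, and evoked synaptic response measures). A synthetic-data
generator with known ground truth backs every stage, so the entire pipeline
is testable without any recorded data.

## The membrane model

The normalized somatic admittance is

$$y(f) = \gamma_R + i\omega\tau_m + \frac{\mu_n}{1 + i\omega\tau_n}
       + \frac{\mu_h}{1 + i\omega\tau_h}, \qquad \omega = 2\pi f,$$

with $\alpha(f) = \operatorname{Re} y$ and $\beta(f) = \operatorname{Im} y$.
Here $\gamma_R$ is the total conductance relative to leak, $\tau_m$ the
membrane time constant, and each quasi-linear term has a dimensionless
weight $\mu$ (negative for an amplifying current such as NaP, positive for
a restorative current such as HCN) and an activation time constant. The
measured quantities are the phase $\phi_s = \tfrac{1}{2\pi}
\operatorname{atan2}(\beta, \alpha)$ (in cycles; positive when the clamp
current leads the voltage command) and the impedance magnitude
$|Z| = \mathrm{Amp}\,(\alpha^2 + \beta^2)^{-1/2}$. Construction of a
parameter set enforces DC stability, $\gamma_R + \mu_n + \mu_h > 0$.

Two hallmarks follow directly. With $\mu_n < 0$ alone, low frequencies are
amplified and $\phi_s > 0$ everywhere; adding $\mu_h > 0$ with a slow
$\tau_h$ produces a subhertz impedance peak and a negative phase lobe whose
zero crossing sits slightly *below* the peak frequency:

```{r resonance}
pp <- cin_presets()[["soma_m70"]]$params   # published -70 mV fit
f <- exp(seq(log(0.1), log(20), length.out = 2000))
f_peak <- f[which.max(somatic_impedance(f, pp))]
f_zero <- uniroot(function(x) admittance_components(x, pp)$beta,
                  c(0.1, 20))$root
c(peak_hz = f_peak, zero_crossing_hz = f_zero)
```

The dendrite is modeled as a semi-infinite cable with a homogeneous
quasi-linear membrane. When a proximal segment of electrotonic length $r$
is driven (by ChR2 photocurrent under partial illumination), the somatic
phase contribution is

$$\phi_d = \frac{1}{2\pi}\left[\operatorname{atan2}(q, p)
  - \operatorname{atan2}\!\big(\sin qr,\; e^{pr} - \cos qr\big)\right],$$

where $p + iq = \sqrt{\alpha + i\beta}$ (principal root, $p > 0$, $q$
carrying the sign of $\beta$). The equivalent complex form
$-\tfrac{1}{2\pi}\arg[(1 - e^{-(p+iq)r})/(p+iq)]$ is implemented as a
cross-check and the two agree to $10^{-12}$ cycles. The amplitude
counterpart $|1 - e^{-\gamma r}|/|\gamma|$ grows with $r$ at low
frequencies (more illuminated membrane, more current); at high frequencies
the complex exponential spirals, so small departures from monotone growth
exist, bounded by $e^{-pr}$ — this is a property of the physics, not an
artifact.

ChR2 kinetics are modeled by the alpha-function impulse response
$A(e^{-t/\tau_d} - e^{-t/\tau_r})$ — written decay-minus-rise so the kernel
is positive for positive $A$ — whose Fourier transform yields an amplitude
low-pass and a phase delay that passes continuously through 0.25 cycles at
$f = 1/(2\pi\sqrt{\tau_r\tau_d})$. The full optogenetic forward model is
the product/sum of the ChR2 and cable contributions.

## Time-domain oracles

Each closed-form model has a brute-force time-domain counterpart used as an
independent oracle and as the engine of the synthetic-data generators:

* an isopotential clamp integrator (exact exponential update of the gating
  variables under a piecewise-linear command, unconditionally stable
  despite $\tau_h \sim 1$ s against sub-millisecond steps);
* a compartmental cable (Crank–Nicolson with per-step algebraic
  elimination of the gates, one constant tridiagonal solve per step,
  sealed distal end; $L \ge 5$ electrotonic lengths approximates the
  semi-infinite cable because end effects decay as $e^{-2pL}$);
* a ChR2 photocurrent stage (threshold-rectified LED command convolved
  with the unit-area alpha kernel, sign-inverted because the photocurrent
  is inward).

The refinement contract is tested explicitly: simulated phases converge
monotonically to the analytic values as mesh, length and step are refined,
and at the standard mesh (400 compartments, length 5, 0.25 ms steps) the
phase agrees with the closed form to well under 0.005 cycles at every
frequency of the default grid.

## System identification

Experimental sweep protocols concatenate whole-cycle sinusoids (3 or 5 s
per frequency, whichever first holds an integer number of periods; 2 mV
amplitude for voltage clamp; LED commands ride on the 40 mV device
threshold). The exact frequency set of the original 83 s protocol is not
published; the package default is a 12-frequency grid spanning 0.2–20 Hz
(`default_frequency_grid()`), which is a configuration choice.

Phase and magnitude per frequency come from the circular cross-correlation
of command and response over whole cycles: the phase from the CCF peak
location (parabolic interpolation around the discrete peak; ties toward
zero lag; search limited to half a period), the impedance from
$|Z| = A^2 / (2\,\mathrm{max\,CCF})$ — the factor 2 makes a known resistor
come back exactly under the mean-product CCF normalization, which is the
unit anchor we adopt. Optogenetic phases are corrected by half a cycle
because the inward photocurrent is in antiphase with the LED command; sign
conventions are chosen so estimates match the forward models directly in
both modalities. The first cycle of each segment is discarded as a settling
transient, except at the lowest frequency whose segment holds exactly one
cycle — the synthetic generator therefore simulates a settling pre-roll so
that segment starts near periodic steady state, mirroring the fact that a
slow restorative gate ($\tau_h \sim 1$ s) needs seconds to settle.

## Fitting and identifiability

Fits minimize squared phase residuals (cycles, equal weight per frequency)
by multi-start L-BFGS-B (Latin-hypercube starts, the best candidates
polished to tight tolerance) within documented bounds: $\mu_n \in [-20,0]$,
$\mu_h \in [0,20]$, $\tau_n, \tau_h \in [1, 20000]$ ms, $\gamma_R \in
(0,50]$, $\tau_m \in [1,500]$ ms, $r \in (0,5]$; time constants and
conductances are searched in log space. A log-magnitude term can be added
(`lambda`), and the impedance scale is always profiled analytically rather
than searched.

Two identifiability properties deserve emphasis, found and characterized
during round-trip testing:

1. **Exact scale symmetry.** Scaling $(\gamma_R, \mu_n, \mu_h, \tau_m)$ and
   the impedance scale by a common factor leaves both the phase and $|Z|$
   unchanged (for the cable model the same holds with $r \to r/\sqrt{c}$).
   Published parameter values are therefore one representative of a ray,
   and any fit pins the scale only by convention. The package exposes
   `fixed = list(gamma_R = ...)` for this; free fits should be interpreted
   through the invariant combinations $\mu_n/\gamma_R$, $\mu_h/\gamma_R$,
   $\tau_m/\gamma_R$, $\tau_n$, $\tau_h$, $r\sqrt{\gamma_R}$.
2. **Slow-kinetics ridge.** When $\tau_h$ lies far above the longest
   sampled period (e.g. 9 s against a 5 s lowest-frequency segment), the
   resonant term reduces to $\mu_h/(i\omega\tau_h)$ and only the ratio
   $\mu_h/\tau_h$ is identifiable. Round-trip tests assert the ratio in
   that regime and full recovery when $\tau_h$ is inside the band.

Passive cable fits ($\gamma_R = 1$ by convention) have no scale freedom and
recover both $\tau_m$ and $r$ essentially exactly on noiseless input.
Fitting a passive scheme to data generated by a resonant dendrite leaves a
diagnostic negative residual at the lowest frequencies — the signature that
motivates the quasi-linear scheme. Proximal and full-field illumination
conditions are fitted independently.

Curve-level comparison uses ANCOVA on the natural log of frequency
(`y ~ ln f * group`), testing the group offset after the common slope and
the group-by-slope interaction.

## Calcium spike-triggered analysis

Line-scan $\Delta F/F_0$ traces are averaged around somatic spikes
(baseline = mean of a 200 ms pre-spike window; segments truncated at the
next spike when the pacemaker fires inside the post-window; spikes without
complete windows dropped and counted). The transient amplitude is the peak
of an alpha-function fit to the STA — less biased by noise than the raw
maximum. Amplitudes versus distance are smoothed with a 35 µm centered
moving average evaluated at the data points (edge windows shrink rather
than pad), and the decay onset ("breakpoint") is operationalized as the
first distance — at least half a smoothing window beyond the proximal
surface-to-volume rise — where the smoothed profile falls 10% below the
plateau median. On generator output with a 70 µm breakpoint this estimator
lands within ±10 µm at the default noise level. Note that at
pacemaker firing rates the indicator transients pile up; because the
system is linear this inflates all sites by a common factor and leaves the
distance profile shape, and hence the breakpoint, unchanged. The
proximal/distal comparison uses per-cell medians and a signed-rank test
when cell labels are present, a rank-sum test otherwise.

## Sleep LFP events and conditional rates

Slow waves: zero-phase 2nd-order Butterworth band-pass 0.5–4 Hz (order
unstated in the source method; forward–backward filtering preserves peak
times), half-waves between consecutive zero crossings of either polarity,
durations restricted to 0.25–2 s, artifacts above 5 SD of the candidate
amplitudes discarded, and exactly the top 30% by amplitude (floor) kept.
Spindles: 10–17 Hz band-pass, analytic-signal (FFT construction) envelope,
detection at mean + 3 SD with boundaries at mean + 0.5 SD, durations
0.5–3 s, and rejection of events whose 20–30 Hz control-band envelope
exceeds mean + 4.5 SD; a 4-pole 4–25 Hz Butterworth supplies reported
waveforms. All thresholds are SD-relative, so detection is invariant to
amplitude rescaling. SD baselines are computed over the sleep-stage-masked
signal when a mask is supplied.

Peri-event rates: spike counts in 20 ms bins over ±2.5 s around event
peaks, normalized to spikes/s. The 99% band is the 0.5th/99.5th percentile
(inverse-ECDF estimator) of the bin rates pooled from the flanks at
|lag| ≥ 1 s — 150 flank bins, enough that a stationary train's central
bins exit the band less than 2% of the time. This per-bin pooling is our
operationalization of a null built "from the rates 1 s before and after"
the trigger; a per-trigger resampling alternative would also be defensible
but is not what we implement.

## What the generators emulate — and what they do not

Every generator is a pure function of (configuration, seed); the
acceptance-grade conditions are: 2 mV sweeps on the published somatic
parameter sets with additive current noise; both illumination extents of
the cable driven through ChR2 kinetics from a single membrane truth;
trapezoidal calcium profiles (rise to 20 µm, plateau to 70 µm, then linear
decay at 2.5%/µm) sampled by a CV-0.1 gamma pacemaker at 5 Hz; pink-noise
LFP with half-cosine slow waves at deep-sleep density (~27/min, amplitude
8 SD in the detection band, soft edges) and Tukey-windowed 13 Hz spindle
bursts (~3/min, envelope peaking 6 SD above the background-envelope mean);
TAN-like trains with a Gaussian pause (depth 0.9, width 0.2 s) flanked by
excitation lobes and SPN-like unmodulated trains; alpha-shaped EPSP/EPSC
trial blocks with a multiplicative drug factor. Planted slow-wave and
spindle amplitudes are calibrated *after* the corresponding detection
filter, so the stated SNR refers to what the detector actually sees.

The generators do **not** emulate: branched or tapering dendrites, ChR2
desensitization, dye buffering or surface-to-volume mechanisms (the
proximal calcium dip is phenomenological), sleep-stage transitions, spike
sorting artifacts, or electrode drift. Passing tests on synthetic data
therefore validate the estimators and their calibration, not the biology
of any particular recording.

## Numerical choices and limitations

* Cable and isopotential integrators are A-stable (Crank–Nicolson /
  exponential update); the step bound `dt < min(tau)/20` is enforced only
  over gates actually present in the model.
* Steady-state extraction discards at least one cycle (or a stated
  settling period) before phase estimation; phase estimates carry a
  one-sample lag quantum plus interpolation error.
* The peak of a noisy mean trace is located on a 1 ms boxcar-smoothed
  copy and measured as the mean over ±0.5 ms around it; a small positive
  selection bias (<1.5% of the amplitude at standard noise and trial
  counts) remains and is documented rather than hidden.
* Problem sizes in the test suite (150 s LFP fixtures, 10-seed Monte
  Carlo replicates, 400-compartment meshes) were chosen as the smallest
  sizes at which the estimators' calibration claims are stable across
  seeds.
* The quasi-linear approximation itself is valid only for small
  perturbations; none of the machinery here addresses spiking dynamics,
  and the mapping from $(\mu, \tau)$ to channel densities is not
  invertible.
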