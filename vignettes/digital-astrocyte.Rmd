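---
title: "Emulating astrocytic calcium encoding in fixed-point hardware arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating astrocytic calcium encoding in fixed-point hardware arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(astromod)
```

## The model

Astrocytes do not fire action potentials; they respond to synaptic activity
with intracellular calcium elevations whose amplitude and frequency can carry
stimulus information. `astromod` implements the standard biophysical chain
for this, a De Pitta-type extension of the Li-Rinzel calcium model coupled to
a leaky integrate-and-fire (IF) neuron:

* **Neuron.** `tau_m dV/dt = -V + R_m I_syn`, reset to `V_reset` at the
  threshold `V_th`. With the default constants (`tau_m` = 0.1 s, `R_m` = 2.5,
  `I_syn` = 2, `V_th` = 1) the closed-form inter-spike interval is
  `tau_m log(R_m I_syn / (R_m I_syn - V_th)) = 0.1 log(1.25)` s, about
  22.3 ms.
* **Gliotransmission.** Each postsynaptic spike deposits `r_AG` = 0.018 uM of
  the endocannabinoid 2-AG, which decays with `tau_AG` = 10 s
  (`dAG/dt = -AG/tau_AG + r_AG delta(t - t_sp)`).
* **IP3 gatekeeper.** `dIP3/dt = (IP3* - IP3)/tau_ip3 + r_ip3 AG`: bound 2-AG
  drives IP3 production at `r_ip3` = 0.5 per second on top of a baseline
  `IP3*` = 0.16 uM with decay time 7 s. We read the published production term
  "r_ip3(AG)" as the product `r_ip3 * AG`, the usual linear gatekeeper form.
* **Calcium.** `dCa/dt = J_chan + J_leak - J_pump` with
  `J_chan = r_C m_inf^3 n_inf^3 h^3 (c0 - (1+c1) Ca)` (IP3-receptor channel:
  IP3-induced gate `m_inf = IP3/(IP3+d1)`, calcium-induced gate
  `n_inf = Ca/(Ca+d5)`), `J_leak = r_L (c0 - (1+c1) Ca)` (ER leak) and the
  SERCA pump `J_pump = v_ER Ca^2/(k_ER^2 + Ca^2)`. The slow IP3-receptor
  inactivation gate relaxes as `dh/dt = (h_inf - h)/tau_h` with
  `h_inf = Q2/(Q2+Ca)`, `tau_h = 1/(a2 (Q2+Ca))` and
  `Q2 = d2 (IP3+d1)/(IP3+d3)`.

Defaults for all constants are the published table values (see
`astro_params()`). Two of them need interpretation:

* `r_C` is used by the channel flux but missing from the published constant
  table; we default it to 6 per second, the standard maximal
  calcium-induced-calcium-release rate of this model family, and expose it
  as an ordinary parameter.
* `a2` is printed as "0.2 uM"; dimensional consistency of `tau_h` (seconds)
  requires per-micromolar-per-second, so we use 0.2 1/(uM s).

The printed initial pair (Ca = 0.071006 uM, h = 0.7791) is not an exact
fixed point of the model (h_inf at that state is about 0.795); we treat it
as an initial condition only, never as an equilibrium oracle, and every
statistic discards a 100 s burn-in.

## Stimulation protocols

Three protocol families (`protocol_clamp()`, `protocol_spike_driven()`,
`protocol_spike_times()` / `protocol_spike_file()`):

* **IP3 clamp**: IP3 is forced to a piecewise-constant waveform and the
  2-AG/IP3 equations are bypassed — the classical bifurcation-scan
  stimulus. The five-level staircase preset applies increments 0.125,
  0.275, 0.13125, 0.09375, 0.575 uM (100 s each), i.e. cumulative levels
  0.125, 0.4, 0.53125, 0.625 and 1.2 uM; we read the published increment
  list as per-interval increments because the cumulative levels match the
  level names quoted alongside it (0.125, 0.4, 1.2). `protocol_staircase()`
  also accepts absolute levels.
* **Spike-driven**: IF spikes (exact closed-form times) release 2-AG and the
  full chain runs. The published account does not state the time scaling of
  its spike-driven run; at the table's constants the raw ~45 Hz IF train
  drives IP3 far above the oscillatory window, so the preset exposes a
  `rate_scale` parameter (default 0.01, i.e. ~0.45 Hz effective drive, which
  settles IP3 near 0.44 uM — mid-oscillatory). This default is a choice,
  flagged as such.
* **Spike file**: plain text, one spike time (seconds) per line.

## The digital emulator

The emulator reproduces, bit for bit, a multiplierless fixed-point datapath:

* **Format.** Signed two's-complement Q4.34 (1 sign + 4 integer + 34
  fractional bits, 39 total; range [-16, 16 - 2^-34], resolution 2^-34).
  Quantization rounds to nearest, ties to even; every operation saturates
  instead of wrapping, and saturation events are counted and reported —
  wrap-around would corrupt the dynamics silently.
* **PWL tables.** The non-affine scalar factors — `m_inf(IP3)`,
  `n_inf(Ca)`, the SERCA Hill curve and `Q2(IP3)` — are replaced by
  continuous piecewise-linear interpolants (`build_pwl()`). The default
  budget refines each table until its certified dense-grid error is at most
  `1e-4` on the physiological domains (IP3 in [0, 2] uM, Ca in [0, 1.7] uM);
  the `minimax-greedy` strategy splits the worst segment at its error
  maximum, which needs roughly 3x fewer segments than uniform spacing at
  equal error. Inputs outside a table's domain evaluate the boundary
  endpoint (clamping, never extrapolation).
* **Cubing.** `m^3`, `n^3`, `h^3` are formed by two full fixed-point
  multiplies after the PWL stage, matching a datapath whose named signals
  are the cubed gates; linearizing the cubed curves directly is available
  as `build_designs(cube = "of-cubed")` and agrees within 2% NRMSE.
* **SCM plans.** Every multiplication by a constant becomes a signed sum of
  shifted copies of the operand (`scm_decompose()`), with right shifts
  capped at 19 bits. Constants above one (e.g. `R_m I_syn` = 5, `r_C` = 6)
  additionally use left shifts up to the 4 integer bits. The greedy
  signed-digit search picks the power of two nearest the residual, breaking
  ties toward the smaller power; on every model constant it matches the
  exhaustive-search optimum at equal term count (verified in the tests).
  Rates folded with the Euler step (such as `dt/tau_AG` = 1e-4) sit so far
  below one that the 19-bit cap would leave ~1% relative error, enough to
  detune oscillation frequency visibly; they are therefore realized as two
  cascaded shift-add stages — the step first (so intermediates shrink
  before any rate above one could saturate them), then the rate — each of
  which is well-conditioned under the cap.
* **h-gate update.** Rather than tabulating the two-input `h_inf(Q2, Ca)`,
  the emulator uses the exact algebraic expansion
  `(h_inf - h)/tau_h = a2 (Q2 - h (Q2 + Ca))`, which needs one generic
  multiply and no division. This is an identity, not an approximation.
* **Stepping.** Forward Euler at `dt` = 1 ms (config-exposed). The step is
  unprinted in the published account; 1 ms is comfortably stable for every
  time constant in the model (`tau_m` = 0.1 s is the fastest) and halving
  it moves the calcium trace by well under 2% NRMSE. The update order per
  step follows the hardware scheduling: IF voltage (raw-integer threshold
  compare), 2-AG, IP3, h gate, gating/flux signals, calcium.

The emulator core runs in C++ on exact 64/128-bit integers; identical
configurations produce identical raw integer streams (`run_digital(raw =
TRUE)` exposes them for regression testing).

In spike-driven comparisons both pipelines consume the same protocol spike
list, so the error metrics isolate arithmetic and approximation error
rather than spike-timing offsets between two IF integrators. The digital IF
voltage is still emulated for its own trace; because its Euler threshold
crossings quantize to whole steps, the digital spike train slowly dephases
against the closed-form reference and the V row of a comparison report is
dominated by that dephasing — a presentation artifact of comparing
sawtooths, not an astrocyte-path error.

## Oscillation analysis

* `detect_peaks()`: local maxima after burn-in, each measured against the
  preceding trough; peaks below a prominence threshold (default 0.05 uM,
  small relative to the 0.4-1 uM oscillations of this model) are discarded.
* `classify_regime()`: *steady* (no ringing at all), *damped* (monotone
  decaying peaks and a final-quarter excursion below 10% of the first peak
  amplitude — the ring-down may sit entirely inside the burn-in window,
  since a strong clamp rings down within seconds), *oscillatory* otherwise.
* `classify_modulation()`: relative changes of mean peak amplitude and mean
  frequency between two stimulus levels, thresholded at 15% each (the
  published narrative separates "practically constant" from "increases"
  but gives no number; 15% is this package's operationalization, exposed as
  arguments). AM = only amplitude moves, FM = only frequency, AFM = both.
  Windows with fewer than two peaks yield `none` with a diagnostic.
  Per-level windows exclude 30 s after each clamp edge; per-segment regime
  calls apply no such guard because the post-edge transient is exactly the
  evidence that distinguishes damped from steady.
* `phase_plane()` and `hausdorff_distance()` support limit-cycle overlap
  checks between pipelines.

## Validation

`compare_traces()` reports RMSE and range-normalized RMSE (normalized by
the *reference* range — the reference is ground truth) for the eight
datapath signals, evaluated over the window ending at the tenth reference
calcium peak so accumulated error has settled; records with fewer than ten
cycles fall back to the full window with a warning and the report states
which policy applied. The window starts at t = 0; starting post-transient
changes the calcium numbers by less than their headroom, so only the t = 0
variant is reported.

Problem sizes used throughout: 500 s protocols at 1 ms steps (5e5 Euler
steps per digital run), adaptive reference integration at `rtol` 1e-8 /
`atol` 1e-10 restarted at clamp edges with spike impulses as solver events.

## What the tests do and do not show

The simulations here are noiseless ordinary differential equations driven
by idealized stimuli: deterministic spike trains or perfect IP3 clamps. The
generator does not emulate stochastic IP3-receptor gating, spatial calcium
microdomains, receptor-level glutamate kinetics upstream of 2-AG, or
astrocyte networks — so a passing suite demonstrates fidelity of the
arithmetic and the dynamics, not biological realism of any single trace.

Known limitations found while validating:

* Under the published step protocol (0.4 uM -> 0.6 uM -> 0.4 uM) the AM
  (`r_L` = 0.014) and FM (`k_ER` = 0.064) parameter presets have a *stable*
  fixed point at the 0.4 uM level — the oscillation onset for both sits
  near 0.5 uM — so the low-level window is quiescent and the classifier
  reports `none` rather than AM/FM; only the AFM preset (onset ~0.40 uM)
  reproduces its published call. No admissible `r_C` repairs this: raising
  it far enough to move the onset below 0.4 uM collapses the staircase's
  oscillatory window at 0.625 uM and still leaves the AM preset
  frequency-coded. The corresponding acceptance expectations are kept
  faithful to the published claim and fail; the AFM one passes.
* The damped regime at a 1.2 uM clamp rings down within ~20 s, which is why
  regime classification looks for ring-down evidence over the whole record
  rather than only after the burn-in.
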