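---
title: "A conductance-based model of high-frequency electrocyte firing and its sodium budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of high-frequency electrocyte firing and its sodium budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrocyte)
```

## The biological problem

Wave-type weakly electric fish such as *Eigenmannia* emit a continuous
electric organ discharge (EOD) at an individual-specific frequency between
200 and 600 Hz, sustained without interruption for the life of the fish.
Each EOD cycle is an action potential (AP) fired synchronously by the
electrocytes of the electric organ, triggered one-for-one by cholinergic
synapses on each cell's excitable posterior membrane.  Because every Na⁺
ion that enters during an AP must eventually be pumped back out by the
3Na⁺/2K⁺-ATPase (one ATP per three Na⁺), the per-AP Na⁺ entry is a direct
proxy for the metabolic cost of the discharge.  This package implements a
single-compartment conductance model of the posterior membrane, drives it
with current-clamp or synaptic stimuli, and tallies the per-AP Na⁺ entry
split by pathway — voltage-gated Na⁺ (Nav) channels versus the synaptic
acetylcholine receptor (AChR) channels — across the full frequency range.

## The membrane model

The state is $(V, m, h, n)$ and the membrane equation is

$$C\frac{dV}{dt} = -I_{NaT} - I_{NaP} - I_K - I_L + I_{stim},$$

with

$$I_{NaT} = \bar g_{Na}\, m^3 h\,(1-\gamma)(V - E_{Na}), \qquad
  I_{NaP} = \bar g_{Na}\, m^3 \gamma\,(V - E_{Na}),$$
$$I_K = \bar g_K\, n^4 (V - E_K), \qquad I_L = g_L (V - E_L),$$

and first-order gating $dj/dt = \alpha_j(1-j) - \beta_j j$ for
$j \in \{m, h, n\}$.  All rate coefficients are exponential in voltage,
$k\,e^{\eta V}$, except the backward inactivation rate, which is
sigmoidal:

$$\beta_h(V) = \frac{3.33}{e^{-(V+30)/9} + 1} \;\mathrm{ms^{-1}}.$$

The sigmoidal form is a deliberate design choice: it is the only reading
of the backward-rate constants under which the inactivation time constant
$\tau_h$ settles at $1/3.33 \approx 0.3$ ms under strong depolarization,
the value reported for electrocyte Na⁺ channels, and the fast $\tau_h$ is
what makes AP trains at 600 Hz possible at all.  (An additive reading of
the same constants would leave $\tau_h$ near 1 ms, too slow for the upper
half of the EOD range.)

The persistent Na⁺ current is a non-inactivating fraction $\gamma = 0.02$
of the Na⁺ conductance with the same activation.  With the default rate
constants the $m^3$ open-fraction curve has its midpoint at $-28$ mV, and
the $n^4$ curve has midpoint $-2.6$ mV with slope $0.017\ \mathrm{mV^{-1}}$
— a delayed rectifier that stays closed during the upstroke and then
repolarizes the cell rapidly once the AP overshoots 0 mV.

$E_{Na} = 55$ mV and $E_K = E_L = -94$ mV are **fixed**: the model assumes
that homeostasis holds the gradients invariant, so the conductance
currents never recompute reversals from concentrations.  The
concentrations enter only through the synapse (next section).

## The synapse

Synaptic activation is a dimensionless, time-varying scale factor
`syn_clamp` on the cation permeability of the AChR population.  Each
ionic component is a Goldman–Hodgkin–Katz flux,

$$I_{AChR}(X) = P_X F \frac{u}{1 - e^{-u}}
  \left([X]_{in} - [X]_{out} e^{-u}\right), \qquad u = \frac{zFV}{RT},$$

for $X \in \{Na, K\}$ with $P_K / P_{Na} = 1.11$, evaluated in SI units
and converted to nA.  With $[Na]_i = 13.5$, $[Na]_o = 120$, $[K]_i = 89$,
$[K]_o = 2.16$ mM the two-ion reversal sits at $+2.2$ mV, so the synaptic
current is monotonically depolarizing over the entire subthreshold range
and the Na⁺ component stays inward throughout the AP (the peak never
reaches $E_{Na}$).

Two reconstruction choices deserve note, both recorded here because the
printed parameter set alone does not fix them:

* **Temperature.** $T = 293.15$ K is used, because at 20 °C the Nernst
  potential of the stated K⁺ concentrations reproduces the fixed
  $E_K = -94$ mV (and the Na⁺ concentrations reproduce $E_{Na} = 55$ mV).
  `validate_params()` enforces this consistency to 0.5 mV.
* **Intracellular sodium.** $[Na]_i = 13.5$ mM.  The value 1.35 mM that
  sometimes circulates for this preparation is inconsistent with both
  $E_{Na} = 55$ mV and an AChR reversal of $+2.2$ mV, while 13.5 mM
  reproduces both simultaneously; we treat the former as a decimal slip.
  The value is an ordinary parameter and can be overridden in any config.

**Sign convention.**  All membrane currents, including the GHK fluxes,
are positive outward; the injected clamp current is positive
depolarizing.  The synaptic term enters the membrane equation as
$-\,\mathrm{syn}(t)\,(I_{AChR}(Na) + I_{AChR}(K))$, i.e. net inward
cation flux depolarizes.  The trajectory object records the full
breakdown, and the test suite asserts at sampled instants that
$-C\,dV/dt$ equals the signed sum of the recorded currents.

## Stimuli

The standard pulsatile waveform rises linearly for 0.05 ms, holds a
plateau for 0.200 ms and decays exponentially with $\tau = 0.1$ ms,
restarting at each stimulus period; its unit-amplitude integral is
0.325 ms.  The decay tail is truncated at the period boundary rather than
summed across periods — with $\tau = 0.1$ ms the carried-over tail is
below $e^{-10}$ even at 600 Hz, so the distinction is numerically
irrelevant but is stated here for completeness.  Mixed regimes compose
**additively**: pulses ride on top of a constant background level.
Current-clamp drives (steps, ramps, brief pulse trains) are provided for
the classical excitability protocols.

## Numerics

* **Integration.**  The right-hand side is compiled C, integrated with
  `lsoda` (stiff-capable, adaptive) at `rtol = atol = 1e-8` with the
  internal step capped at 0.01 ms so that 0.05 ms stimulus rises are
  never stepped over; output is sampled every 0.005 ms.  Halving the
  tolerances and the step cap moves AP peaks by less than 0.01 mV (this
  self-convergence check is part of the test suite).  A pure-R
  implementation of the same right-hand side is exported
  (`membrane_rhs()`) and the suite verifies C/R agreement along
  trajectories.
* **GHK singularity.**  $u/(1-e^{-u})$ is replaced by its four-term
  Taylor expansion for $|u| < 10^{-4}$; the series agrees with the direct
  expression to better than $10^{-9}$ relative well beyond the switch
  point.
* **Resting state.**  Found by 200 ms of unforced relaxation, refined by
  root-finding on the steady-state current balance with gates at their
  voltage equilibria; the returned state has all derivatives below
  $10^{-9}$.  At defaults it is $-93.84$ mV, just above $E_K$, set by the
  leak against the small depolarizing Na⁺ window current.
* **Spike detection.**  An AP is an upward crossing of $-20$ mV (well
  above the apparent firing threshold near $-45$ mV, below all observed
  peaks) followed by a local maximum, with a 0.5 ms lockout; $V_{peak}$
  is refined by a quadratic through the three bracketing samples.
* **Measurement windows.**  The first five stimulus periods (pulsatile
  drive) or 25 ms (steady drive) are discarded as onset transient;
  per-AP tallies integrate whole stimulus periods (pulsatile) or
  spike-midpoint windows (steady) and divide by the spike count, which
  also handles sub-harmonically locked trains.  Per-period entries are
  stationary to well under 1% after the transient.
* **Searches.**  Conductance calibration bisects $\bar g_{Na}$ to 0.5 µS
  on the monotone relation between conductance and $V_{peak}$; threshold
  searches bisect the steady level to $10^{-4}$.  Because firing onset is
  a saddle-node-on-invariant-circle bifurcation, the inter-spike interval
  diverges at threshold; the threshold search therefore uses a 2000 ms
  detection window (three spikes required) so that the measured value
  approximates the bifurcation point rather than an artifact of a short
  observation window.
* **Staircase.**  The entrainment scan uses an amplitude step of 0.005,
  300 ms per point with a 100 ms transient, a 1% relative tolerance for
  calling a point locked at $f/k$, and requires plateaus to span at least
  two grid points; the critical amplitude is the smallest grid point from
  which 1:1 locking is sustained to the top of the grid.  The simulation
  is noise-free, so period-doubled and period-tripled plateaus are
  cleanly visible.

## Protocol conventions

The per-AP cost table (`cost_matrix()` over `cost_table_regimes()`)
follows these conventions: for each target frequency the subthreshold
background is 80% of the 0 Hz firing threshold of the
$V_{peak}$-calibrated system (using 75% or 85% instead changes $V_{peak}$
by ≤ 0.01 mV and the Na⁺ entry by ≤ 0.2%, a robustness the suite checks);
the suprathreshold background is the steady level whose free-running rate
is roughly 70% of the target.  The shipped regime table stores the
resolved levels themselves (e.g. 0.03, 0.12, 0.18) rather than the
fractions, since the levels are the actual inputs of the protocol.  The
cost-versus-frequency fold change fits $A e^{bf}$ by unweighted least
squares in log space to the calibrated pure-pulsatile totals at 300, 400
and 500 Hz and reports $e^{200b}$.

## Problem sizes

Default runs are sized for a desk-scale laptop budget: calibration and
tally runs cover 25 stimulus periods (5 transient + 20 analysed, at least
15 of which must contain APs), threshold searches watch a 2 s window,
frequency curves 400 ms per point, and the staircase 300 ms per
amplitude.  The complete test suite runs in well under a minute; the
headline-reproduction script in `scripts/acceptance.R` takes a few
seconds.

## What the model does and does not capture

The model is a single isopotential compartment representing only the
innervated posterior membrane: no cable geometry, no anterior membrane,
no inward rectifier, no Na⁺-activated K⁺ conductance, and no explicit
Na⁺/K⁺ pump current — the pump is represented implicitly by the
assumption of perfectly maintained gradients, which is exactly what makes
Na⁺ entry a clean cost proxy.  Synaptic activation is deterministic and
noise-free; real cholinergic release is quantal and stochastic, which
would blur the staircase plateaus and push the practically required 1:1
drive amplitude above the noise-free critical value.  Ion concentrations
do not feed back on the fixed reversals.  These simplifications mean that
passing tests demonstrate the internal consistency of this idealized
membrane, not a validated reproduction of in-vivo electrocyte recordings.

## Known limitations

* At 700 Hz stimulation the model produces irregular AP amplitudes and
  timing for any Na⁺ conductance in a wide range — the 1:1 regime ends
  between 650 and 700 Hz.  This is a property of the gating kinetics
  (incomplete recovery from inactivation), not a solver artifact.
* Quantities defined by bifurcations (firing threshold, staircase
  critical amplitude) depend mildly on the observation window and grid;
  the defaults above state the conventions used.
* The GHK synapse uses a single permeability-area product for the whole
  AChR population; saturation, desensitization and single-channel
  statistics are out of scope.
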