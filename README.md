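# electrocyte

Conductance-based modelling of sustained high-frequency firing in the
*Eigenmannia* electrocyte, and of what it costs in sodium.

Wave-type weakly electric fish hold a continuous 200–600 Hz electric organ
discharge (EOD) for their entire lives.  Every discharge cycle is an action
potential (AP) in the electrocytes of the electric organ, triggered 1:1 by a
cholinergic synapse on each cell's excitable posterior membrane.  Because
each Na⁺ ion admitted during an AP must be pumped back out by the
3Na⁺/2K⁺-ATPase (1 ATP per 3 Na⁺), the **per-AP Na⁺-entry budget** is a
direct proxy for the metabolic cost of the discharge.  This package is for
computational neurophysiologists who want to simulate that membrane, drive
it with realistic synaptic or current-clamp stimuli, and account for where
the sodium comes in.

## The model

A single-compartment Hodgkin–Huxley-type membrane,

```
C dV/dt = −I_NaT − I_NaP − I_K − I_L + I_stim
I_NaT = gNa_max m³h (1−γ)(V−E_Na)     I_NaP = gNa_max m³ γ (V−E_Na)
I_K   = gK_max n⁴ (V−E_K)             I_L   = g_L (V−E_L)
dj/dt = α_j(1−j) − β_j j,   j = m, h, n
```

with exponential rate laws `k·exp(ηV)` (the backward inactivation rate is
sigmoidal, saturating so that τ_h → 0.3 ms under depolarization — the
property that makes 600 Hz trains possible).  Synaptic drive is a
dimensionless "cation permeability clamp" `syn_clamp(t)` scaling a
Goldman–Hodgkin–Katz Na⁺/K⁺ flux through the AChR population
(P_K/P_Na = 1.11, reversal +2.2 mV):

```
I_stim = syn_clamp(t) · (I_AChR(Na) + I_AChR(K))
I_AChR(X) = P_X F · u/(1−e^(−u)) · ([X]in − [X]out e^(−u)),  u = FV/RT
```

The standard pulse rises linearly for 0.05 ms, holds 1 for 0.2 ms, and
decays with τ = 0.1 ms; pulses may ride on a steady background level.
`E_Na` and `E_K` are held fixed (perfect homeostasis), which is exactly
what makes Na⁺ entry a clean cost measure.  The right-hand side is
compiled C integrated with `deSolve::lsoda`.

Protocol drivers reproduce the full study design: `calibrate_gna_max()`
(the one parameter that must grow with frequency to keep V_peak at the
12.86 mV standard), `steady_threshold()`, `frequency_curve()`,
`devil_staircase()` (rational locking plateaus under pulses atop a
subthreshold background), `cost_matrix()` (18 stimulus regimes),
`cost_fold_change()` (exponential cost-vs-frequency fit), `jar_sweep()`
(jamming-avoidance excursions) and `pulse_amplitude_scan()`.

## Worked example

```r
library(electrocyte)
params <- electrocyte_params()          # the standard parameter set

# Standard drive: 200 Hz pulses, amplitude 1, gNa_max = 700 uS
run <- run_train(params, stimulus_regime(amplitude = 1, frequency = 200))
round(run$v_peak, 2)
#> [1] 12.81

tally_na_entry(run$traj, run$train)
#> Na+ entry per AP (x1e9 ions): total 59.16 = Nav 48.63 (T 46.20 + P 2.43) + AChR 10.53  [20 APs]

# What conductance does a 600 Hz fish need for the same AP amplitude?
cal <- calibrate_gna_max(params, frequency = 600)
round(cal$g_na_max)
#> [1] 1130

# Steady (0 Hz) synaptic activation: rate and peak vs intensity
frequency_curve(params, levels = c(0.03, 0.05, 0.4))
#>   intensity frequency    v_peak
#> 1      0.03  136.3863  8.906936
#> 2      0.05  202.1572  9.083726
#> 3      0.40  539.7996 -4.661319
```

Reading the numbers: a 200 Hz train of full-amplitude APs costs
59×10⁹ Na⁺ per AP, of which only ~10.5×10⁹ enters through the synapse —
and that synaptic share stays nearly constant at every frequency, while
the Nav share grows with the conductance needed to keep the peak at
12.86 mV (700 µS at 200 Hz → ~1130 µS at 600 Hz).  Steady activation can
also drive firing across the species range (0.05 → 202 Hz, 0.4 → 540 Hz),
but with smaller, declining peaks and a higher per-AP cost — one reason a
pulsatile drive is the energetically sensible design.

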