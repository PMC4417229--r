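---
title: "A two-compartment biophysical model of the cerebellar Purkinje neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment biophysical model of the cerebellar Purkinje neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purkinje2c)
```

## The model

Cerebellar Purkinje neurons recorded in slices fire spontaneously in a
repeating *trimodal* motif — tonic sodium spiking, then bursting driven by
high-threshold dendritic Ca^2+^ spikes, then quiescence — and the
electrogenic Na^+^/K^+^ pump is a strong candidate for the slow engine
behind this cycling.  `purkinje2c` implements a deliberately small
biophysical model built to express this repertoire: a cylindrical soma
(22 µm × 22 µm) and a single equivalent-cylinder dendrite
(529.29 µm × 3.22 µm), each carrying its own set of voltage- and
Ca^2+^-gated membrane currents, coupled by the axial resistance

$$R_{DS} = \frac{R_a\,(L_S/2)}{\pi r_S^2} + \frac{R_a\,(L_D/2)}{\pi r_D^2},$$

with $R_a$ = 35.4 Ω·cm.  Each compartment obeys a current-balance
membrane equation $C_m\,dV/dt = -\sum_i I_i$, with densities in mS/cm²
and µA/cm² (the internal unit system is mV/ms/mM/µm throughout; pump and
exchanger densities are tabulated in mA/cm² and converted on use).

The somatic inventory: a 13-state Markov resurgent Na^+^ channel, three
voltage-gated K^+^ currents of increasing TEA resistance, BK and SK
Ca^2+^-gated K^+^ currents, a P-type Ca^2+^ current with
Goldman–Hodgkin–Katz flux, a hyperpolarization-activated cation current,
a leak, a saturating Na^+^/K^+^ pump, and an exchanger/pump
counterbalance pair.  The dendritic inventory: T-, E- and P-type Ca^2+^
currents, A-, D-, M-type, delayed-rectifier and Kv1.2 K^+^ currents, BK
and K2 Ca^2+^-gated K^+^ currents, a hyperpolarization-activated
current, a leak, the dendritic saturating pump and counterbalance pair,
and (optionally) an ERG K^+^ current.

### Dendritic reduction

The dendrite compartment stands in for a full arbour.  `collapse_tree()`
merges branches into one cylinder conserving axial resistance
($R = \sqrt{\sum_i r_i^2}$, $l = \sum_i l_i r_i / \sum_i r_i$);
`relength_cylinder()` then restores electrotonic separation by setting a
longer length at constant volume ($R = \sqrt{V/\pi l}$).  Because the
collapse conserves axial resistance but not membrane area, a dendritic
correction factor $C_d$ — the ratio of the arbour's membrane area to the
cylinder's lateral area — multiplies every dendritic conductance
density, the dendritic specific capacitance and the dendritic Ca^2+^
shell depth (`apply_cd()`).  The default parameterisation uses
$C_d$ = 6.16 (42,310 µm² / 6,874 µm²), and the published equivalent
cylinder: collapsed 120.9 µm × 6.74 µm, re-lengthed to 529.29 µm which
fixes the radius at 1.61 µm.  `reduce_morphology()` wires these together
so the target length is the single tuning knob: changing it updates the
radius (volume conservation) and $C_d$ automatically.

Two bookkeeping notes.  The printed cylinder area 6,874 µm² of the
default $C_d$ is an externally supplied measurement, not equal to
$\pi d l$ of the printed cylinder; `compute_cd()` therefore accepts
external areas verbatim and never forces recomputation.  Surface areas
are lateral only (no end caps), which reproduces the 1,521 µm² soma
area of the 22 µm × 22 µm cylinder.

### Gating

Hodgkin–Huxley gates follow $dx/dt = (x_\infty - x)/\tau_x$, specified
either as $(x_\infty, \tau_x)$ pairs or as $(\alpha, \beta)$ rate pairs
with $x_\infty = \alpha/(\alpha+\beta)$, $\tau_x = 1/(\alpha+\beta)$.
Somatic time-constant tables are given in seconds and converted to ms on
evaluation; dendritic rates are per-ms and carry temperature factors
($3^{(T-37)/10}$ at $T$ = 36 °C for most dendritic channels,
$3^{(T-22)/10}$ for Kv1.2, $2.3^{(T-36)/10} = 1$ for the M-current).
Several dendritic channels are specified directly through their
per-step update factors (e.g. $1 - e^{-dt\,m_t(\alpha+\beta)/4}$ for the
E-type activation gate); these are implemented as the equivalent
effective time constants, which reproduces the printed updates exactly.
Voltage sigmoids are implemented as Boltzmann functions
$1/(1+e^{-(V-V_{1/2})/k})$; an audit flag (`literal_sigmoid`) reproduces
the raw $1/e^{-(V-V_{1/2})/k}$ typography of some source tables, which
exceeds 1 above $V_{1/2}$ and is not usable for simulation.

The resurgent Na^+^ channel is a 13-state Markov scheme: five closed
states linked by scaled activation rates $4\alpha \dots \alpha$
($\alpha = 150\,e^{V/20}$, deactivation $\beta = 3\,e^{-V/20}$), an open
state reached via fixed rates $\gamma$ = 150, $\delta$ = 40, an
open-blocked state (entry $\varepsilon$ = 1.75, exit
$\zeta = 0.03\,e^{-V/25}$) representing the blocking particle whose
unbinding on repolarization produces the resurgent current, and six
inactivated states with allosteric factors $a = (O_{on}/C_{on})^{1/4}$,
$b = (O_{off}/C_{off})^{1/4}$.  The current is
$I = g_{max}\,O\,(V - E_{Na})$.

The somatic P-type Ca^2+^ current uses the GHK flux at fixed
concentrations ([Ca]~i~ = 100 nM, [Ca]~o~ = 2 mM, *T* = 295 K,
*P* = 5·10^−5^ cm/s); its tabulated `g_max` acts as a dimensionless
multiplier of that flux.  The removable singularity at *V* = 0 is
handled by the analytic limit $2PF([Ca]_i - [Ca]_o)$.

### Ion dynamics and pumps

Four slow variables close the loop between firing and excitability:

* **Somatic shell Ca^2+^** (`step_soma_ca()`): driven by the P-type
  current into a 0.1-µm sub-membrane shell, first-order decay
  (β = 1/ms), hard floor at 100 nM.  It gates BK and SK.
* **Dendritic shell Ca^2+^** (`step_dend_ca()`): influx rectified at
  zero, saturable extrusion ($k_t$ = $k_d$ = 4·10^−5^), 2-ms relaxation
  to 40 nM; the shell depth carries $C_d$, which exactly offsets the
  $C_d$-scaled Ca^2+^ current densities so shell concentrations match
  the unreduced model.  It gates the dendritic BK and K2 currents.
* **Intracellular Na^+^** (`step_na_i()`): integrates the net somatic
  Na^+^ flux — resurgent-channel influx plus the constant exchanger
  influx (3 × 0.511 mA/cm²) minus pump efflux — *delayed by τ = 5 s*
  through a fixed-capacity FIFO (`na_delay_line()`), emulating diffusion
  from channels to pumps.  Floors: [Na]~i~ ≥ 10 mM, E~Na~ ≥ +70 mV.
  The longitudinal diffusion term is negligible at this geometry and is
  omitted.
* **Extracellular K^+^** (`step_k_o()`): a 70-nm shell around the
  dendrite integrates gated K^+^ efflux minus pump uptake with
  accumulation factor *Q* = 0.0119, clamped to [2, 3.03] mM; the
  dendritic K^+^ reversal follows it through the Nernst relation.

The somatic saturating pump
$i = d_{pump}(V+75) / [(V+80)(1 + e^{K_{Na} - [Na]_i})]$ switches on
sharply as [Na]~i~ approaches the affinity constant $K_{Na}$ (40 mM by
default) and moves 3 Na^+^ out per 2 K^+^ in (net hyperpolarizing).
Together with the 5-s lag this forms a relaxation oscillator: firing
loads the cell with Na^+^, the pump engages and silences it, Na^+^ is
cleared, and firing resumes.  The exchanger/pump counterbalance pair is
deliberately mismatched at the soma
($g_{ex} = g_{pump} + 0.011$ mA/cm²), providing the small tonic Na^+^
influx and depolarizing bias that keeps the cycle going.

Closure choices the source tables do not pin down, decided once:

* **Dendritic K^+^ Nernst anchor.**  [K]~i~ is fixed so that
  $E_K$ = −77 mV at the initial [K]~o~ = 2 mM (K~i~ ≈ 36 mM),
  honouring the stated initial value; the somatic $E_K$ stays at
  −88 mV.  The alternative anchor K~i~ = 54.4 mM (which makes the
  dendritic $E_K$ start at −88 mV and reach −77 mV at the
  [K]~o~ ceiling) was implemented and evaluated: it produces a less
  excitable dendrite that never reaches Ca^2+^-spike threshold and a
  model that takes ~35 s to begin firing.  `k_i` is an explicit
  parameter, so both closures are available.
* **Na^+^ book-keeping signs.**  Influx/efflux terms enter as positive
  magnitudes; a signed-current reading would make [Na]~i~ *fall* during
  influx and break the pump feedback loop.
* **Pump singularity.**  The $(V+80)$ denominator is guarded within
  0.01 mV of its zero; in addition the pump's slope conductance
  $d i/dV = 5 d_{pump}/[(V+80)^2(1+e^{K_{Na}-[Na]_i})] \ge 0$ is folded
  into the implicit voltage update — without this the ~0.5 mA/cm² pump
  current near its null at −75 mV destabilises any explicit treatment.

### Integration

Fixed-step integration at dt = 25 µs (0.025 ms), deterministic by
construction.  Within a step: (1) gates relax exponentially and the
Markov chain advances by backward Euler (a 13 × 13 solve with partial
pivoting and occupancy renormalization — at spike peaks
$4\alpha\,dt \approx 70$, so any explicit occupancy update diverges);
(2) currents are evaluated; (3) both voltages advance by a linearized
implicit 2 × 2 solve with conductances frozen and non-ohmic currents
(GHK, pumps) held at their start-of-step values, the somatic pump
entering through its linearization; (4) ion pools advance by explicit
Euler and their clamps are applied; (5) reversal potentials are
refreshed.  The scheme is first-order: halving dt leaves early-tonic
spike times within a fraction of a millisecond, while phase drift
accumulates linearly across a full second of ~100-Hz firing (as it must
for any first-order fixed-step method).  A 60-s default simulation takes
a few seconds of CPU time.

## Protocols

* `set_kna(cell, 12)`: lowering the pump's Na^+^ affinity constant from
  40 to 12 mM activates the pump at resting Na^+^ and switches the model
  from spontaneous firing into quiescence.
* `alcohol_protocol(cell)`: emulates a progressing pump block by ramping
  the somatic saturating pump density down at 0.014 mA·cm^−2^·s^−1^ from
  t = 0, and the dendritic saturating pump and both counterbalance pump
  densities at 0.005 mA·cm^−2^·s^−1^ for t > 50 s (evaluated as
  base − M·t, hence with a step at onset), all floored at zero; the
  exchangers do not ramp.  Defaults to the K~Na~ = 12 starting condition
  so the run begins from quiescence.
* `bk_knockout(cell)`: zeroes BK in both compartments.  Without its
  principal repolarizer the dendrite locks into a depolarized plateau
  (the P-type window current balancing Kv1.2/DR), dragging the soma
  to a distinct depolarized level.
* `add_erg(cell)`: inserts a dendritic ERG K^+^ current
  (m-gate half-activation −5 mV) at 0.5·$C_d$ mS/cm².

## Trace analysis

`detect_spikes()` marks upward threshold crossings (−20 mV somatic,
−30 mV dendritic defaults) with a 1-ms lockout.  `classify_activity()`
labels every sample: silence longer than 1 s is *quiescent* below
−50 mV and *depolarization_block* above it; spiking stretches are
*burst* where inter-spike intervals drop below 30 ms in coincidence
(±60 ms) with dendritic Ca^2+^ spikes, else *tonic*; mode runs shorter
than 0.5 s are absorbed.  All thresholds are arguments.  Because only
spike times and mean potentials enter, the labels are invariant to
output stride and uniform time shifts.  `trimodal_period()` averages
the interval between successive tonic onsets over complete
tonic→burst→quiescent cycles and reports `NA` (undetermined) when no
complete cycle exists.

## Synthetic fixtures

`gen_synthetic_tree()` builds seeded random branch trees whose collapse
has a closed-form result (used to exercise the reduction and the SWC
round trip).  `gen_synthetic_trace()` assembles two-channel voltage
traces from a segment plan — regular tonic spikes, burst clusters
aligned with dendritic Ca^2+^ humps, quiescent and
depolarization-block plateaus with sub-5-mV ripple — and emits the
ground-truth labels, giving the classifier a known construction to
recover.  Synthetic traces are idealized: spikes are stereotyped
single-sample events, noise is Gaussian and stationary, and mode
boundaries are sharp, so classifier tests on them demonstrate correct
segmentation logic, not robustness to real recording artefacts.

## Emergent behaviour, verified and not

Everything quantitative in this section is computed by the test suite
or the acceptance script; problem sizes there (60-s default runs, a
120-s pump-block run, 10^6^-step occupancy scans, a 5-ms passive
cross-check at dt = 2·10^−6^ ms) were chosen as the smallest runs that
exercise each claim.

Verified by the suite: the reduction arithmetic and $C_d$ scaling of
every dendritic conductance; gate midpoints, monotonicity and the
removable singularities; Markov occupancy conservation and agreement of
its stationary distribution with a dense null-space solve; pump
stoichiometry and half-activations; all four ion clamps at every
recorded sample; the exact 5-s Na^+^ feedback lag; agreement of an
all-passive configuration with the closed-form two-compartment RC
solution to 10^−6^; bitwise determinism; spontaneous firing with
overshooting spikes and Purkinje-like rates; the K~Na~ 40→12 switch
into quiescence; dendritic Ca^2+^-spike-driven bursting; pump-driven
quiescent phases giving a spontaneous motif that repeats every ~23 s;
a pump-block run that proceeds from quiescence through firing into a
terminal depolarization block whose somatic trace is furrowed by
time-locked sub-threshold deflections from the still-firing dendrite;
and the dendritic depolarization-block plateau under BK knockout.

Known deviations, kept and documented rather than tuned away: after the
first full tonic→burst→quiescent cycle the tonic lead of later cycles
shrinks below 0.1 s, because with the tabulated pump densities the
extracellular-K^+^ shell cannot unload below the dendritic burst
threshold during a quiescent phase (uptake ≈ 5 µA/cm² against a 3.03-mM
ceiling reached in every active phase); the soma is not an intrinsic
pacemaker in this parameterisation (a ≈ 2 µA/cm² standing SK current at
the Ca^2+^ floor out-balances the subthreshold depolarizers), so the
pump-block run skips the alternating tonic/quiescent (bimodal) window
and the BK-knockout soma shows intermittent spike epochs rather than
clean block; and the inserted ERG current at 0.5·$C_d$ mS/cm² is two
orders of magnitude too small against the $C_d$-scaled P-type plateau
current to repolarize the BK-knockout dendrite, under either sign
reading of its inactivation gate (both were evaluated).  The
corresponding acceptance expectations are intentionally left failing.

## Limitations

Two electrical points cannot represent gradients along the arbour;
synaptic input is absent (all activity is intrinsic); the Ca^2+^ pools
are single well-mixed shells without buffers or stores; temperature is
fixed at the tabulated values; and the fixed-step first-order scheme
trades long-horizon phase accuracy for robustness and speed.
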