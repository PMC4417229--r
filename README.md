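# purkinje2c

A two-compartment biophysical model of the cerebellar Purkinje neuron,
with the dendritic-tree reduction that produces its dendrite
compartment, in-silico experimental protocols, and firing-state trace
analysis. It is aimed at computational neuroscientists who want a
Purkinje cell description cheap enough for network-scale or
long-duration (minutes) simulation while keeping the ionic machinery —
not an integrate-and-fire abstraction — and at anyone studying how the
electrogenic Na⁺/K⁺ pump shapes intrinsic firing.

## The model in brief

A cylindrical soma (22 × 22 µm) and an equivalent-cylinder dendrite
(529.29 × 3.22 µm) are coupled through the axial resistance
`R_DS = Ra·(L_s/2)/(π r_s²) + Ra·(L_d/2)/(π r_d²)` (Ra = 35.4 Ω·cm) and
each obeys a membrane current balance `C_m dV/dt = −Σ I_i`. The soma
carries a 13-state Markov resurgent Na⁺ channel
(`I = g_max · O · (V − E_Na)`), three voltage-gated K⁺ currents, BK and
SK Ca²⁺-gated K⁺ currents, a GHK-flux P-type Ca²⁺ current, I_h, leak,
a saturating Na⁺/K⁺ pump
`i = d_pump (V+75) / [(V+80)(1 + exp(K_Na − [Na]_i))]` and a
counterbalanced Na⁺/Ca²⁺ exchanger / Na⁺/K⁺ pump pair. The dendrite
carries T-, E- and P-type Ca²⁺ currents, A/D/M/DR/Kv1.2 K⁺ currents, BK
and K2 Ca²⁺-gated K⁺ currents, I_h, leak, its own pump set and an
optional ERG K⁺ current. Slow variables — sub-membrane Ca²⁺ in both
compartments, intracellular Na⁺ with a 5-s feedback lag onto the pump,
and extracellular K⁺ in a 70-nm shell that moves the dendritic E_K —
close the loop between spiking and excitability, so the model fires
spontaneously in alternating active and pump-silenced phases.

The dendrite compartment is built by collapsing a full arbour into one
cylinder conserving axial resistance (`R = sqrt(Σ r_i²)`,
`l = Σ l_i r_i / Σ r_i`), re-lengthing it at constant volume
(`R = sqrt(V/(π l))`), and rescaling every dendritic density,
capacitance and Ca²⁺ shell depth by the dendritic correction factor
`C_d` (arbour area / cylinder area = 42,310/6,874 ≈ 6.16).

Integration is fixed-step (25 µs default): exponential gate relaxation,
backward-Euler Markov occupancies with renormalization, and a
linearized-implicit 2×2 voltage update. Everything is deterministic.

## Worked example

```r
library(purkinje2c)

# reduce a small arbour to an equivalent cylinder, re-lengthed to 400 um
tree <- morph_tree(data.frame(id = 1:3, parent_id = c(NA, 1, 1),
                              radius_um = c(2, 1.5, 1),
                              length_um = c(120, 90, 60)))
reduce_morphology(tree, target_length_um = 400)
#> Dendritic reduction
#>   collapsed: L = 96.67 um, D = 5.385 um
#>   re-lengthed: L = 400 um, R = 1.324 um (volume kept)
#>   arbour area = 2733.19 um2, cylinder area = 3326.73 um2
#>   C_d = 0.8216

# simulate the default cell for 10 s and summarize its firing
cell <- purkinje_cell()
tr <- simulate_cell(cell, duration_s = 10)
summary(tr)
#> 10 s simulated; 1239 somatic spikes (mean rate 123.9 Hz)
#> activity segments:
#> tonic
#>     1
#> trimodal period: undetermined (no complete cycle)
```

The collapsed cylinder is the root-sum-square of the branch radii
(`sqrt(4 + 2.25 + 1) ≈ 2.69` µm radius) at the radius-weighted mean
length; stretching it to 400 µm thins it to 1.324 µm to keep the volume,
and `C_d` is the area ratio of arbour to cylinder (here < 1 because
this toy arbour is smaller than its stretched cylinder). The 10-s
default run is one tonic stretch at 124 Hz — the quiescent and burst
phases of the spontaneous motif appear on longer runs (the full cycle
repeats roughly every 23 s; see the vignette), which is why the
trimodal period is still undetermined at 10 s.

Protocols are one-liners on top of a cell:

```r
simulate_cell(set_kna(cell, 12), 20)            # pump-driven quiescence
simulate_cell(alcohol_protocol(cell), 120)      # progressive pump block
simulate_cell(bk_knockout(cell), 60)            # depolarization block
simulate_cell(add_erg(bk_knockout(cell)), 30)   # dendritic ERG insertion
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/purkinje.R reduce --swc cell.swc --length 529.29 --out out/
Rscript inst/cli/purkinje.R simulate --config run.yaml --duration 60 --out out/
Rscript inst/cli/purkinje.R protocol alcohol --duration 120 --out out/
Rscript inst/cli/purkinje.R analyze --trace out/trace.csv --report out/
Rscript inst/cli/purkinje.R fixtures tree --seed 1 --out out/
```

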