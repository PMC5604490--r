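# mitocarrier

Kinetic modelling of mitochondrial carrier transport from the free-energy
profile of its conformational change.

## The problem

The mitochondrial ADP/ATP carrier imports cytosolic ADP and exports
matrix ATP by alternating access: one binding site, alternately exposed
to the two sides of the membrane by a conformational change. Two
inter-domain salt-bridge networks (matrix and cytoplasmic) gate that
change — sequentially breaking one and forming the other imposes a
free-energy barrier that stops the *empty* carrier from switching sides,
while tighter substrate binding in the intermediate conformation (an
induced fit) lowers the barrier and couples conformational change to
substrate occupancy. This package is for anyone who wants to explore,
quantitatively, how those interaction energies set turnover numbers,
Michaelis constants, and the exchanger-versus-uniporter character of a
carrier.

## The model

The carrier is a continuous-time Markov chain over states ⟨c, s⟩: a
conformational coordinate discretised as c = −10 (cytoplasmic) … +10
(matrix), crossed with the occupancy s of the single binding site
(21(N+1) states for N substrates). The standard chemical potential of a
state is additive and Gaussian along c:

    μ⁰(c,s) = ΔE_M·exp(−((c+10)/5)²) + ΔE_C·exp(−((c−10)/5)²)
              + [ ΔE_S·exp(−(c/4)²) + ΔE_B ]   (bound states only)

with ΔE_B = −k_BT·ln([S]/K_d). Energies are in mV (1 kJ/mol = 10.36 mV;
k_BT = 26.7 mV at 37 °C). Neighbouring conformations are connected with
rates split symmetrically about the step free energy,
k± = k_c·exp(∓ΔG⁰/2k_BT), so detailed balance is exact and no net flux
exists without a concentration gradient. Binding is allowed only at the
end conformations, first order in concentration.

The steady state is solved exactly from the chemical master equation
(dense linear solve), or sampled stochastically with Gillespie's
algorithm with each bind–release episode classified by its (binding
side, release side) fate. Analytic companions — Boltzmann conformational
distributions, max-minus-min energy barriers, and the partition-function
decomposition K_M = (Z_c/Z_s)·K_d — come alongside the full model, and
Michaelis–Menten parameters are fitted to simulated uptake curves by
Levenberg–Marquardt.

## Worked example

```r
library(mitocarrier)

m <- carrier_model()   # published wild-type calibration
m
#> Free-energy-profile carrier model
#>   dE_M = -550, dE_C = -550, dE_S = -550 mV; kc = 5.66e+06 /s; T = 37 C
#>   63 states, 64 reaction pairs
#>   steady-state transport (labelled): 41.2944 /s
```

With all three interaction energies at −550 mV and the published rate
constants, the carrier exchanges 5 mM cytoplasmic labelled ADP against
5 mM matrix unlabelled ADP at ≈ 41 s⁻¹ per carrier — the measured
wild-type turnover is approximately 40 ADP/s. Fitting a simulated uptake
curve gives the kinetic constants:

```r
conc <- seq(0, 100e-6, by = 2e-6)
fit_michaelis_menten(conc, predict(m, conc, side = "cytoplasmic"))
#> Michaelis-Menten fit: kcat = 41.37 /s, KM = 8.874 uM (rms 5.8e-11)
```

`summary(m)` reports the energy barriers behind those numbers: 529.9 mV
for the empty carrier (transport blocked) against 252.5 mV with
substrate bound (the induced fit has lowered the barrier), and the
carrier is almost always substrate-loaded at 5 mM:

```r
summary(m)
#>   energy barrier (empty): 529.9 mV; (bound, net): 252.5 mV
#>   occupancy by binding-site state (0 = empty):
#>      0      1      2
#> 0.0035 0.4982 0.4982
```

A short stochastic trajectory shows the same physics event by event: in
2 × 10⁴ jumps (~2 ms) the labelled substrate binds and returns to the
cytoplasmic side 1427 times without a single crossing — transport events
(~40 s⁻¹) are rare on this timescale:

```r
simulate(m, seed = 1, n_events = 2e4)$counts
#>    substrate transport_cyt_to_mat returned_to_cyt ...
#> 1   labelled                    0            1427
```

Sweeps reproduce the headline structure–function results: uniport influx
requires a weakened cytoplasmic network and peaks near −330 mV
(≈ 0.7 salt bridges under the linear registration ΔE ≈ −130·N − 240):

```r
uniport_scenarios()$fixed$summary[c("influx_argmax_mV", "influx_argmax_saltbridges")]
#> $influx_argmax_mV      [1] -330
#> $influx_argmax_saltbridges  [1] 0.6923077
```

See the vignette (`vignettes/carrier-kinetics.Rmd`) for the model's
assumptions, numerical choices, and limitations, and
`inst/cli/mitocarrier.R` for the command-line front end
(`steady`, `gillespie`, `profile`, `sweep`, `mmfit`, `approximate`).

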