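---
title: "A free-energy-profile kinetic model of mitochondrial carrier transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A free-energy-profile kinetic model of mitochondrial carrier transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocarrier)
```

## The model

The mitochondrial ADP/ATP carrier exchanges cytosolic ADP for matrix ATP
by an alternating-access mechanism: a single binding site is exposed
alternately to the intermembrane space and the matrix through a
conformational change. Two inter-domain salt-bridge networks gate this
change — the matrix network closes the carrier on the matrix side when
the carrier faces the cytoplasm, and the cytoplasmic network closes the
cytoplasmic side when it faces the matrix. Breaking one network before
forming the other creates a free-energy barrier that prevents the empty
carrier from changing conformation; tighter substrate binding in the
intermediate conformation (an induced fit) lowers that barrier and makes
transport substrate-conditional.

`mitocarrier` treats the carrier as a nanomachine performing a thermal
random walk along a discretised conformational coordinate, `c = -10`
(cytoplasmic conformation) to `c = +10` (matrix conformation) in 21
steps. The system state is the pair (conformation, binding-site
occupancy), giving `21(N+1)` states for `N` mutually exclusive
substrates. The standard chemical potential of each state is additive,

$$\mu^0_{c,s} = \Delta E_M\, e^{-\left(\frac{c+10}{5}\right)^2}
             + \Delta E_C\, e^{-\left(\frac{c-10}{5}\right)^2}
             + \left[\Delta E_S\, e^{-\left(\frac{c}{4}\right)^2}
             + \Delta E_B\right]_{\text{bound only}},$$

with the matrix-network Gaussian peaking at the cytoplasmic conformation
(the network is engaged there) and vice versa, and the induced-fit term
peaking at the intermediate conformation. The binding energy
$\Delta E_B = -k_BT \ln([S]/K_d)$ carries the concentration dependence.
All energies are in millivolts (1 kJ/mol = 10.36 mV), so they compare
directly with membrane-potential scales; $k_BT$ is 26.73 mV at 37 °C and
is recomputed from the temperature rather than hard-coded at its printed
rounding of 26.7.

Neighbouring conformations are connected with rates split symmetrically
about the step free energy, $k_\pm = k_c e^{\mp \Delta G^0/2k_BT}$, so
that $-k_BT\ln(k_+/k_-) = \Delta G^0$ holds exactly and every closed
cycle at equal concentrations has zero affinity: the model can do no
work without a concentration gradient, which the tests verify via the
Kolmogorov cycle criterion. Binding is allowed only at the two end
conformations, first order in concentration (`kf * [S]` on, `kr` off).

## Parameters and calibration

The defaults are the published wild-type calibration:

| parameter | default | meaning |
|---|---|---|
| `dE_M`, `dE_C`, `dE_S` | −550 mV each | matrix network, cytoplasmic network, induced fit |
| `Kd` | 40 µM | dissociation constant without induced fit |
| `kf` | 2.5 × 10¹⁰ M⁻¹s⁻¹ | binding rate (mean binding time 40 ns at 1 mM) |
| `kr` | 10⁶ s⁻¹ | release rate, constrained to `kf * Kd` |
| `kc` | 5.66 × 10⁶ s⁻¹ | conformational base rate, calibrated so the wild-type turnover is ≈ 40 ADP/s |
| `temperature` | 37 °C | assay temperature |
| substrates | 5 mM labelled (cyt) vs 5 mM unlabelled (mat) | the radio-labelled exchange assay |

The labelled/unlabelled pair are chemically identical (same `Kd`, `kf`,
`kr`); the label only lets the bookkeeping distinguish substrate that
crossed the membrane from substrate that returned to its own side. The
constraint `kr = kf * Kd` is enforced at construction to one part in
10⁶ so the binding edge is thermodynamically consistent with the stated
dissociation constant.

```{r}
m <- carrier_model()
m
```

## Numerical choices

**Steady state.** The chemical master equation generator is a dense
63×63 matrix (for two substrates); one balance row is replaced by the
normalisation row and the system solved by partial-pivoting LU. Rate
entries stay within a factor of about `exp(1)` of `kc` per step, so
conditioning is benign even when probabilities span twelve orders of
magnitude; the residual of the replaced row is reported rather than
assumed. Substrates absent from both compartments leave unreachable
bound ladders, which are pruned with a warning instead of failing the
solve.

**Binding edges.** Binding uses the literal first-order rates. This
leaves a residual $\Delta E_S e^{-(10/4)^2}$ (≈ −1 mV at −550 mV)
mismatch between the bound-edge potential implied by the rates and the
additive profile; the `consistent_binding_edges` flag folds that tail
into the binding step for exact agreement. The default is off: cycle
affinities vanish either way, and the literal rates are the plainer
reading of the published kinetics.

**Gillespie simulation.** Because concentrations are clamped, the jump
process has constant per-state propensities, precomputed once; the SSA
is then an exact embedded-chain simulation. Trajectories discard a 10%
burn-in before counting, and completed bind–release episodes are
classified by (binding side, release side) into transported vs returned
fates; episodes truncated by the window are counted separately.
Occupancy agreement with the master equation is assessed with
batch-means standard errors, not binomial ones, because the trajectory
is autocorrelated. The stochastic cross-validation runs at
ΔE_M/C/S = −300 mV, where transport (~1200 s⁻¹) gives hundreds of
barrier crossings per 10⁶ events; at the wild-type point the slow
transport mode (~40 s⁻¹ against ~10⁷ jumps/s) would need ~10⁸ events to
mix, and the code path exercised is identical.

**Forward-flux estimate.** The analytic forward flux is
$J_F = \tfrac12 P_I k_c$ with the intermediate-state probability taken
from the full 21-term Boltzmann partition function (`method =
"partition"`). The coarser two-term closed form
$P_I \approx \tfrac12 e^{-(\mu_I^0-\mu_N^0)/k_BT}$ is kept as
`method = "two_state"`; it overstates $P_I$ by the neighbour terms it
drops (about 40% at −700 mV). With the partition form, $J_F$ exceeds
the full-model net flux by about 60% averaged over the strong end
(|ΔE| ≥ 600 mV) of the symmetric sweep.

**Partition decomposition.** Unbound conformations are assigned to the
cytoplasmic sum for `c < 0` and the matrix sum for `c > 0`, with `c = 0`
split equally; unbound probability concentrates at the ends, and the
split choice moves the derived Michaelis constants by under 1% (asserted
in the tests). Sums use log-sum-exp so deep profiles cannot overflow.

**Michaelis–Menten fits.** Uptake curves vary the substrate resident on
one side over 0–100 µM (0.1 µM steps for the headline numbers, coarser
in fast-running tests) against 5 mM counter-substrate, and are fitted
unweighted by Levenberg–Marquardt. The zero-concentration point (rate
exactly 0) is included. Comparisons between fitted and
partition-function Michaelis constants are made only where the fitted
value exceeds the concentration-grid step (0.1–1 µM depending on the
grid): below that the fit cannot resolve the constant and neither
number is meaningful.

**Sweeps.** Panorama sweeps use 10 mV steps; optima that matter at the
millivolt scale (the cytoplasmic-network optimum sits 5–10 mV weaker
than the matrix network) are refined on a 1 mV grid around the coarse
argmax.

## Design choices that were genuinely open

* The published rendering of the Gaussian exponents is typographically
  ambiguous; the implemented reading
  $e^{-((c\pm10)/5)^2}$, $e^{-(c/4)^2}$ is the only one that engages
  the matrix network in the cytoplasmic conformation with the stated
  widths.
* The conformational base rate was calibrated with the induced-fit
  strength (not the concentration-dependent binding energy) at
  −550 mV; the two are easily conflated in the published wording, but
  only the induced-fit reading reproduces the ≈ 40 ADP/s turnover.
* "High network strength" for the forward-flux comparison is taken as
  the |ΔE| ≥ 600 mV points of the symmetric sweep.
* Weak and strong cytoplasmic networks for the Michaelis-constant
  structure are pinned to −300 mV and −700 mV, the ends of the
  0.5–3.5 salt-bridge experimental range under the linear registration
  ΔE_C ≈ −130·N − 240.

## What the model does and does not capture

The model is electroneutral and single-species: no membrane potential,
no ADP³⁻/ATP⁴⁻ charge asymmetry, no per-substrate dissociation
constants, and no temperature dependence of the energy scales. The
21-step grid and Gaussian profile shapes are modelling choices, not
measurements — doubling the grid with widths scaled to preserve the
profile changes transport by a bounded factor (the tests log it), but
changing the widths alone changes the physics. Agreement of the
simulated kinetics with published turnover and Michaelis constants
therefore shows that the free-energy-profile picture is sufficient to
reproduce the measured structure–function relationship, not that the
profile is uniquely determined by it.

## A worked tour

```{r, fig.width = 6, fig.height = 4}
plot(m)                      # energy profile, empty vs bound
summary(m)
```

Turnover and Michaelis constant of the calibrated carrier (coarse grid
for speed; the headline numbers use 0.1 µM steps):

```{r}
conc <- seq(0, 100e-6, by = 2e-6)
fit <- fit_michaelis_menten(conc, predict(m, conc, side = "cytoplasmic"))
fit
```

Uniport requires a weak cytoplasmic network:

```{r}
sw <- uniport_scenarios(grid = seq(-650, -150, by = 50))
sw$fixed$summary[c("influx_argmax_mV", "influx_argmax_saltbridges")]
```

A short stochastic trajectory, classified:

```{r}
log <- simulate(m, seed = 1, n_events = 2e4)
log$counts
```
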