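---
title: "Mechanistic basis and numerical methods of thrombosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic basis and numerical methods of thrombosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intravenous thrombolysis for acute ischemic stroke delivers a plasminogen
activator (PA) into systemic circulation, where it is distributed,
eliminated, and inactivated by the plasminogen activator inhibitor PAI-1,
while the fraction that reaches the occluded artery must penetrate the
fibrin clot, convert fibrin-bound plasminogen (PLG) to plasmin (PLS), and
degrade the fibrin network. The four licensed or commonly used agents —
alteplase, tenecteplase, reteplase and urokinase — differ in fibrin
affinity, catalytic constants, PAI-1 susceptibility, half-life and dose
regimen, so their efficacy (how fast the clot opens) and their safety
(how much systemic fibrinogen is consumed, a proxy for intracranial
haemorrhage risk) cannot be ranked by any single in-vitro constant.
`thrombosim` couples a systemic pharmacokinetic–pharmacodynamic model of
the plasma fibrinolytic proteome with a one-dimensional porous-medium
model of the clot, and derives comparable efficacy and safety read-outs
for all four drugs.

## Systemic model

The drug follows a two-compartment model. In the central compartment
(volume $V_c$, set per body weight):

$$\frac{dC_c}{dt} = \frac{IV(t)}{V_c M_w} - k_{el}C_c - k_{cp}C_c +
  k_{pc}C_p + S_{PA} - k_{PAI} C_c C_{PAI}$$

$$\frac{dC_p}{dt} = k_{cp}C_c - k_{pc}C_p$$

$IV(t)$ is the piecewise-constant infusion schedule (mg/s); boluses are
finite infusions at their clinically stated durations (5 s, 1 min, 2 min),
never impulses. $S_{PA} = k_{el} C_0$ maintains the endogenous baseline of
the natural activators (tPA for alteplase, uPA for urokinase); the
engineered variants have no endogenous pool. Note that $C_p$ is expressed
per central volume, so the exchange terms are symmetric and the conserved
drug amount is $V_c (C_c + C_p)$.

Six fibrinolytic proteins are tracked in plasma — plasminogen, plasmin,
$\alpha_2$-antiplasmin (AP), $\alpha_2$-macroglobulin (MG), fibrinogen
(FBG) and PAI-1 — each with homeostatic turnover
($S_i = k_{el,i} C_{i,0}$, so the drug-free plasma is a steady state) plus
the reaction network: Michaelis–Menten PLG activation by the drug
(catalytic, the activator is not consumed), second-order inhibition of PLS
by AP and MG, second-order fibrinogenolysis by PLS, and second-order 1:1
inactivation of the drug by PAI-1.

The stiff system is integrated with `deSolve::lsoda`, restarting at every
infusion-segment boundary so the discontinuous source is never smoothed
across a jump. The absolute tolerance (1e-12 uM) sits far below the PAI-1
excursions, which traverse several orders of magnitude.

## Local clot model

The clot is a porous fibre network of length $L_{clot}$ along the flow
axis. Plasma seeps through it at the Darcy superficial velocity
$U = k \, \Delta p / \mu$ with the Davis fibrous-media permeability

$$k = \frac{r_f^2}{16 (1-\varepsilon)^{1.5}\,(1 + 56 (1-\varepsilon)^3)}.$$

Cells in series compose like resistances (harmonic-mean permeability), so
one uniform $U$ holds at all times and flow recovers as the clot opens. A
velocity cap (`U_max`) represents the downstream vascular resistance: the
configured pressure gradient is only valid while the occlusion dominates
the circuit, and the uncapped post-lysis Darcy velocity would be
unphysically large.

Each of the seven mobile species (drug + six proteins) obeys a
convection–diffusion–reaction balance on the pore fluid,
$\partial(\varepsilon n_i)/\partial t = -\partial(U n_i)/\partial x +
D\,\partial^2 n_i/\partial x^2 + \varepsilon R_i$, discretized as a
conservative finite volume: first-order upwind convection (the flow is
unidirectional; upwind avoids oscillations at the lysis front), central
diffusion, Dirichlet inlet at the instantaneous systemic composition
(one-way coupling — the clot volume is negligible against the plasma
volume), and zero-diffusive-flux outflow.

The immobile phase per cell comprises fibrin binding sites $n_{tot}$ and
bound species: bound drug (except urokinase, which has no fibrin
affinity), bound PLG and bound PLS. Adsorption follows mass-action
($k_a C n_{free} - k_d n_b$). Bound-phase plasmin generation follows the
saturable law

$$r_{PLS} = \frac{k_{cat}\, n_{PLG}\, \theta}
  {K_M (1-\varepsilon_{clot}) + n_{PLG}},$$

where the driver $\theta$ is the bound drug for the fibrin-binding
agents and the free drug concentration for urokinase. Sites degrade as
$\partial n_{tot}/\partial t = -k_{deg}\,\gamma\,n_{PLS}$, porosity
follows the remaining sites linearly between the intact clot and the open
lumen, and bound species on destroyed sites are released to the pore
fluid in proportion to the loss (destroying them would silently delete
plasmin mass).

### Clot-resident PAI-1

The clot also carries an immobile stock of matrix-bound PAI-1
(`PAI_clot_init`), representing platelet-released PAI-1 retained on
fibrin/vitronectin — the classic mechanism of clot lysis resistance. It
inactivates incoming free activator 1:1 at the drug's own $k_{PAI}$.
Because the stock is immobile it is *titrated* away cell by cell, so the
delay it imposes scales with each drug's $k_{PAI}$ and with the cumulative
drug delivery: urokinase ($k_{PAI} = 160\ \mu M^{-1} s^{-1}$, slow
infusion ramp) is delayed most, tenecteplase
($k_{PAI} = 0.15$) passes essentially unhindered. A freely dissolved
initial pool would simply wash out within one transit time and delay
nothing — the immobility is essential.

## What drives the cross-drug contrasts

Three mechanisms, all emerging from the equations rather than from
drug-specific tuning, produce the characteristic rankings:

* **Plasminogen delivery limits lysis.** The clot's own plasminogen
  (pore fluid plus fibrin-bound) is finite, and resupply rides on the
  slow Darcy seepage. Fibrin-binding drugs concentrate plasmin
  generation in the few cells where bound drug has accumulated — the
  front cells lyse fast and a sharp front marches inward. Urokinase acts
  wherever its free concentration reaches, spreading the same limited
  plasminogen budget over the whole clot: every cell degrades slowly and
  nearly in parallel.
* **PAI-1 titration sets the activation delay.** See above.
* **Systemic PAI-1 balance.** The quasi-steady plasma PAI-1 level under
  drug pressure is $k_{el,PAI} C_{PAI,0} / (k_{PAI} C_c)$, which orders
  the drugs by $k_{PAI} C_c$ — tenecteplase retains the most PAI-1,
  urokinase the least.

## Calibration surface

The drug-specific constants (kinetics, PK, binding) are published values
and are never touched. Everything that is *not* drug-specific — plasma
protein levels and turnover, the PLS inhibition and fibrinogenolysis
constants, clot porosity, fibre radius, binding-site density, pressure
gradient, diffusivity, $k_{deg}\gamma$, PLG/PLS fibrin affinities, and
the matrix-bound PAI-1 stock — lives in
`inst/extdata/defaults.yaml`, explicitly marked as the calibration
surface. These constants were set once, to physiologically defensible
values that reproduce the qualitative clinical picture, and the file is
the only thing a recalibration may touch. Choices worth noting:

* Plasminogen's effective turnover is fast (half-life ~2 h) compared to
  its resting catabolic half-life of ~2 days: during massive activation,
  hepatic synthesis and extravascular exchange buffer the plasma pool.
  This matters for slow sustained activators (urokinase), whose late
  plasmin production would otherwise be starved.
* The plasminogen–fibrin dissociation constant is weak (hundreds of uM),
  in line with Glu-plasminogen on *intact* fibrin before C-terminal
  lysines are exposed. Plasmin, by contrast, is modelled as nearly
  irreversibly bound and protected from AP/MG while bound
  (`bound_PLS_protected`), consistent with the protected-plasmin
  hypothesis; both assumptions are configurable.
* Urokinase's molar mass uses the low-molecular-weight two-chain form
  (33 kDa), the form consistent with 1.5 MU ≈ 11.3 mg dosing.

## Numerics

Operator splitting per outer step (default 0.5 s): transport first
(sub-cycled to the CFL and diffusive limits), then reactions, then the
porosity/velocity update. Within the reaction step every process that is
linear in one species for frozen partners — desorption, Michaelis–Menten
consumption of bound PLG, PAI-1 inhibition, plasmin inhibition,
fibrinogenolysis — is advanced by its exact exponential solution, so the
step is stable regardless of how stiff those rates become (bound-PLG
consumption alone can exceed 40 s$^{-1}$). Only the adsorption loading
terms are explicit, with sub-cycling tied to their first-order
coefficients. Negative concentrations are never clipped into the mass
balance; transport raises an error if a genuine negative appears, and
reaction updates are constructed non-negative.

Default problem sizes: 50 finite-volume cells over a 15 mm clot, 0.5 s
outer step, 15 s recording cadence, and a 3 h horizon; a full four-drug
comparison completes in under a minute on one core. Doubling the grid
moves the reported lysis times by about 2% or less.

## Metrics

* **Lysis time**: first recorded time at which *every* clot cell is at or
  below `lysis_threshold` (default 5%) of its initial binding sites. The
  clot-opening criterion is not defined sharply by clinical imaging
  either; the ordering of the four drugs is stable across thresholds
  0.01–0.10.
* **Activation time**: first time the cell at `x_monitor` (default 5 mm,
  mid-clot) has lost `activation_drop` (default 10%) of its sites.
* **Front lysis duration**: activation-to-threshold interval of the
  inlet-face cell — how fast the face dissolves once attacked.
* **Exposure AUC**: trapezoidal integral of the central drug
  concentration.
* **Safety**: systemic fibrinogen nadir (absolute and fraction of
  baseline) and minimum systemic PAI-1.

## What the model does and does not emulate

The simulator represents an idealized, fully occluded artery with a
homogeneous clot, a single deterministic 80 kg patient, and one-way
systemic-to-clot coupling. It does not represent patient variability,
pulsatile or collateral flow, clot heterogeneity or mechanical
fragmentation, intra-arterial delivery, or combination therapy. Passing
its tests therefore demonstrates internal consistency and faithfulness to
the stated reaction-transport mechanism — not clinical predictive
accuracy for any individual patient.

Two known limitations of the calibrated default scenario, visible in the
acceptance test suite, are worth stating plainly. First, urokinase
completes lysis a few minutes *after* the fibrin-specific agents rather
than a few minutes before: every mechanism in this model that delays
urokinase's activation (the 30-min infusion ramp, PAI-1 titration) also
delays its completion, so its relative activation delay and its relative
completion advantage cannot both be large. Second, the per-cell
front-dissolution times of the four drugs have the right ordering
(tenecteplase ≈ alteplase fastest, urokinase intermediate, reteplase by
far the slowest) but a compressed dynamic range; with the shared
physiological constants fixed, that contrast is bounded by the published
per-drug kinetic constants. Reteplase's activation at the monitor is
correspondingly late (~26 min) even though its overall lysis time and
safety profile are reproduced.

## Worked example

```{r example}
library(thrombosim)
cmp <- compare_presets(t_end = 10800)
print(cmp)
```
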