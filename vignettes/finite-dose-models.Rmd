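---
title: "Finite-dose skin penetration under volatile vehicles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-dose skin penetration under volatile vehicles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermavol)
```

## The problem

When a chemical is applied to skin in a small volume of solvent (a
*finite dose*), its fate over the following 24 hours is governed by a
competition between three processes: uptake into the stratum corneum
(SC), evaporation of the permeant from the surface, and evaporation of
the solvent itself. For volatile vehicles — ethanol most prominently —
solvent dry-out can terminate absorption within minutes, leaving most
of the dose stranded (and eventually crystallised) on the surface.
In vitro permeation tests (IVPTs) summarise the outcome at 24 h by
three masses per unit area: the *skin wash* (what is recovered from the
surface), the *SC accumulation*, and the *cumulative dermal delivery*
(everything that crossed the SC).

`dermavol` implements two mechanistic models of this process as 1-D
diffusion problems in the SC with different surface conditions,
together with the weighted error metrics used to score predictions
against IVPT tables, maximum-likelihood calibration of the
vehicle-specific parameters, and a synthetic IVPT generator with known
ground truth.

## Shared structure

The SC is a homogeneous slab of thickness $h_{sc}$ (default 13 µm, a
partially hydrated SC). Diffusion follows Fick's law with diffusivity
$D_{sc}$; the base of the SC is a perfect sink (the viable-tissue
clearance models that could replace it are out of scope, and a sink
maximises comparability of "dermal delivery" with experimental
aggregates of epidermis + dermis + receptor).

On application, convection instantaneously loads a *deposition layer*
— the upper fraction $\eta_{dep}$ of the SC — up to its saturation
capacity:

$$M_{sat} = \eta_{dep}\, h_{sc}\, C_{sat}, \qquad C_{sat} = K_{sc/w} S_w,$$

where $K_{sc/w}$ is the SC/water partition coefficient and $S_w$ the
water solubility. Dose in excess of $M_{sat}$ starts on the surface:
$M_{surf}(0) = \max(0, M_0 - M_{sat})$, and the initial SC profile is
uniform at $\min(M_0/(\eta_{dep} h_{sc}),\, C_{sat})$ inside the
deposition layer, zero below. These initial conditions close the mass
balance exactly, which the test suite verifies by quadrature.

Permeant evaporation is a zeroth-order surface flux $k_{evap\text{-}per}$
active while surface mass remains. It may be given directly or supplied
by a plug-in correlation in the wind velocity $u$; the packaged
power-law plug-in ($k = c\,u^p$, default $p = 0.78$) is a generic
stand-in for boundary-layer mass-transfer correlations, and any
monotone non-decreasing callable is accepted. The correlations that
estimate $K_{sc/w}$, $D_{sc}$ and the evaporation rate from compound
descriptors live in cited literature rather than here, so all three are
direct inputs by design.

## Model A: fixed deposition layer, saturated reservoir

Model A fixes $\eta_{dep} = 0.1$ for solvent-applied doses. While
surface mass remains, the deposition layer is held saturated at
$C_{sat}$: the surface replaces whatever diffuses across the interface
at $z = \eta_{dep} h_{sc}$ and additionally loses $k_{evap\text{-}per}$
to air. When the surface is exhausted, the clamp is released, the top
boundary becomes zero-flux, and the profile relaxes towards the sink.
The choice of a zero-flux (rather than still-evaporating) top boundary
after depletion is a genuinely open point — the governing equation is
silent once $M_{surf}=0$ — and we adopt no continued evaporation from
within the SC.

## Model B: evaporating vehicle, solubility-limited uptake

Model B treats $\eta_{dep}$ as a vehicle-specific parameter and gives
the solvent film an explicit thickness $h_v(t)$ thinning at the
constant rate $k_{evap\text{-}veh}$, so the film dries at
$t_{dry} = h_v(0)/k_{evap\text{-}veh}$. Only dissolved permeant can
enter the SC: the dissolved concentration is
$c_v = \min(S_v, M_{surf}/h_v)$ (the excess is precipitated solid,
tracked implicitly as $M_{surf} - c_v h_v$), and the SC surface is held
in partition equilibrium, $c_{sc}(0,t) = c_v / K_{v/sc}$ with
$K_{v/sc} = (S_v/S_w)/K_{sc/w}$. A saturated film therefore pins the
surface at exactly $C_{sat}$ — an algebraic identity the tests check on
simulated trajectories. Once the film has dried, uptake ceases
(surface mass is lost to evaporation only), and once the surface is
exhausted the interior merely drains into the sink.

A consequence worth knowing: when the film is *unsaturated*
($c_v < S_v$), the donor boundary sits below $C_{sat}$ while the
deposition layer was loaded at $C_{sat}$, so early in the run the SC
back-diffuses into the film. In that regime faster solvent evaporation
can *increase* dermal delivery by cutting the back-diffusion short; the
intuitive "more volatile, less delivered" monotonicity holds only for
saturated donors, and the test suite asserts it only there.

## Numerical scheme

Space is discretised by a conservative finite-volume scheme on a
two-zone grid with a cell boundary exactly at the deposition interface,
so the initial mass bookkeeping is exact. The deposition layer gets at
least four uniform cells; the free zone below is graded geometrically,
its first cell matching the deposition cell width. The grading exists
because the diffusive boundary layer that forms below the interface
during a short donor phase ($\sqrt{D_{sc} t_{dry}}$, often a few
hundred nanometres) would otherwise be under-resolved at coarse
resolutions; with it, terminal outputs move by less than 0.1% when the
default 100 cells are halved, comfortably inside the 0.5% the
acceptance tests require.

Time integration is delegated to `deSolve`'s `lsoda`/`lsodar` with a
banded Jacobian — the state is ordered (surface mass, concentrations,
delivered, evaporated) so the system is tridiagonal. The right-hand
side is discontinuous across regimes, so each regime has its own
branch-free RHS and integration restarts at the analytic dry-out time
and at the surface-depletion root found by `lsodar`. (A single RHS
with internal `if (M_surf > 0)` branches stalls the step-size
controller when the surface mass hovers near zero.) Default tolerances
are `rtol = 1e-8`, `atol = 1e-10`; trajectories conserve mass to
around 1e-14 relative, audited on every result object. Output is
sampled every minute plus event times by default.

## Error metrics and calibration

Predictions are scored per IVPT by SD-standardised squared residuals,
$e^2 = ((y - \hat y)/\sigma)^2$, summed over the three outputs into
$E^2_{Total}$ and aggregated per solvent. This weighting is pinned by
two published anchors that the acceptance tests recompute (the
testosterone IVPT yields 615.5 under Model A and 7.77 under Model B);
no alternative weighting reproduces both. Observation tables sometimes
print an SD of 0.00 — a rounding artefact; the bundled table stores
these as missing and the metrics exclude such terms with a warning
rather than divide by zero. Mass-balance error is the difference, in
percentage points of dose, between modelled and observed recovery
(skin wash + SC + delivery)/dose; its antisymmetry and the fold-ratio
and overprediction counters are property-tested.

Calibration maximises a likelihood whose negation is, up to an additive
constant, the model's objective: summed squared mass-balance errors
for Model A (one parameter, $u$), summed $E^2_{Total}$ for Model B
(five parameters: $u$ and per-solvent $\eta_{dep}$,
$k_{evap\text{-}veh}$). Minimisation uses `stats::optim`'s Nelder-Mead
over log-transformed rates and logit-transformed fractions so every
iterate is feasible; one-parameter problems use golden-section
bracketing instead, Nelder-Mead being unreliable in one dimension.
Simulation failures inside the objective return a 1e12 penalty and are
logged, letting the simplex route around pathological corners.
Multistart jitter is available but off by default, keeping fits
bit-reproducible. Because the minimised objective plays the role of
$-2\log L$, the AIC difference between the models is
$(2k_B + E^2_B) - (2k_A + E^2_A)$, with the common constant cancelling.

The shipped defaults for the calibrated quantities are: wind velocity
43 cm/min (Model A) and 0.68 cm/min (Model B);
$\eta_{dep} = 0.03$ (saline) and 0.05 (ethanol) — the larger ethanol
value reflecting its penetration-enhancing effect; and
$k_{evap\text{-}veh} = 0.0055$ cm/min (saline) and 0.014 cm/min
(ethanol), which for a 10 µL/cm² film (0.01 cm) give drying times of
109 s and 43 s respectively.

## The synthetic generator

`generate_synthetic_ivpt()` emulates the replicate structure of a
multi-donor IVPT: the designated model is simulated at known
parameters and each terminal output is replicated with multiplicative,
mean-preserving lognormal noise at a chosen CV (default 12 replicates,
i.e. three sections from four donors). All randomness flows from one
recorded seed. What it deliberately does not emulate: donor-level
variance components (a single-level noise model stands in for the
unreported donor/section split), inter-compound correlation, and any
misspecification between generating and fitting model — so parameter
recovery on synthetic data demonstrates identifiability and optimiser
correctness, not accuracy on real skin.

The recovery study used in the tests covers three synthetic compounds
in both solvents with slow diffusivities
($10^{-10}$–$1.2\times10^{-9}$ cm²/min, i.e. $h_{sc}^2/D_{sc}$ beyond
24 h — the regime in which real IVPTs retain measurable skin wash and
all three outputs stay informative). Noise-free observations receive
nominal 5%-of-mean weighting SDs (floor $10^{-3}$), since the weighted
objective is undefined at literal zero SDs. Fits recover the
vehicle parameters to well under 5% and the wind velocity under 15%,
on a 40-cell grid with terminal-only output to keep each of the few
thousand embedded simulations around 50 ms.

## Limitations

Single homogeneous SC layer; no viable-tissue clearance, follicular
transport, ionisation or temperature dependence; one common
evaporation rate per solvent (solvent-permeant interactions that alter
volatility are not represented); $\eta_{dep}$ is an empirical
aggregate of fast initial processes and is only meaningful for
solvents it has been calibrated against. The deposition layer is
loaded at $t=0$ regardless of how short the drying time is, following
the models' stated initial conditions.
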