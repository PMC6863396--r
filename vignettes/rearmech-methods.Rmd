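---
title: "A mechanochemical mass-action model of cell rear retraction"
author: "rearmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical mass-action model of cell rear retraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rearmech)
```

## The biological problem

Cells migrating through aligned extracellular matrix move persistently up
stiffness gradients (durotaxis). Persistence requires the *rear* of the cell
to keep up: membrane tension drops at the trailing edge, caveolae assemble
there, recruit the RhoA machinery (the GEF Ect2, countered by p190RhoGAP),
and RhoA's effector kinases ROCK1 and PKN2 drive actomyosin contractility
through myosin light-chain phosphorylation and aligned rear F-actin. The
contractility further lowers rear membrane tension, closing a positive
feedback loop that keeps the rear retracting even when the external gradient
is transient.

`rearmech` implements this axis as a declarative wiring diagram (19
variables: 12 proteins, the caveolae complex, and 6 biophysical entities)
that compiles into a deterministic mass-action ODE system, together with the
in-silico experiment catalogue, scaled parameter sensitivity analysis,
halve/double robustness sweeps, a seeded parameter-ensemble classifier and
SBML Level 3 import/export.

## Formulation rules

The compiler expands every interaction edge under fixed rules:

* **Mass action everywhere.** Each elementary reaction's flux is its rate
  constant times the product of its reactant pools.
* **Conserved moieties on a 0--100 scale.** Every variable has an active
  pool, an inactive pool, and (for proteins engaged in two-step reactions)
  transient binding complexes; their sum is constant. For biophysical
  entities "active" means the *high* state of interest -- for membrane
  tension the active pool encodes *decreased* rear tension, for rear
  retraction it is the instantaneous rear speed expressed as % activity.
* **Two-step protein--protein reactions.** A activates B via binding
  (`A_a + B_i -> A:B`) then conversion (`A:B -> A_a + B_a`); inhibition
  consumes `B_a` and releases `B_i`. Reversible edges carry the two reverse
  steps at exactly 10% of the forward rates (the rules bound reversibility
  at "at most 10%"; we fix the single point 10% rather than introduce an
  extra free parameter per edge).
* **One-step reactions wherever a biophysical entity takes part**, with the
  catalyst regenerated (`X_a + Y_i -> X_a + Y_a`). Phospho-MLC is the one
  protein-state exception: it is activated in one step and carries no
  turnover term, because its dedicated phosphatase MLCP is explicit in the
  network.
* **Irreversibility** of the designated edges (decreased tension activating
  caveolae; aligned actin and pMLC activating contractility) and of every
  edge mixing protein and biophysical endpoints.
* **Turnover.** Every species except pMLC and the clamped input has a
  first-order active-to-inactive flux.
* **The input is clamped.** Polarized substrate stiffness is a boundary
  condition: no turnover, never consumed, changed only by events.

The canonical diagram carries 28 edges; compilation yields 55 pools
(19 x 2 state pools plus 17 binding complexes), 100 elementary reactions
and 100 rate parameters.

## Parameters: the order-of-magnitude grid

No kinetic constants are available for this pathway, so every rate is an
order-of-magnitude choice `1e-n` (integer `n >= 1`). Class windows keep the
choices interpretable: protein--protein steps live in `1e-6..1e-1`,
one-step biophysical couplings in `1e-6..1e-2`, turnover in `1e-4..1e-2`
with the four turnover rates that the perturbation events scale (membrane
tension, F-actin, ROCK1, PKN2) anchored at the `0.01 s^-1` baseline the
event protocol quotes. Protein windows sit above biophysical ones --
protein--protein binding is fast, mechanochemical transduction slow -- but
the windows overlap: a strict global ordering combined with the grid would
leave a single admissible exponent per class.

`check_parameter_constraints()` enforces the grid, the 10% reversibility
bound and the class windows; `compile_model()` refuses profiles that
violate them.

### Why the shipped profile looks the way it does

The calibrated default profile (in `default_parameters()`) was chosen, on
the grid and within the windows, so that the canonical model reproduces the
qualitative phenotype catalogue (below). Three structural facts drove the
calibration:

1. **Any activation stage strong enough to self-sustain is strong enough to
   amplify noise.** With turnover fixed at `0.01`, a stage that keeps its
   target high at steady state necessarily has a small-signal gain above
   one. A chain of such stages makes the resting network unstable: any
   residue of activity regrows to full activation. The resting (quiescent)
   state is therefore stabilised by the *antagonists*, not by weak coupling.
2. **The persistent brakes carry the bistability.** Cofilin and MLCP start
   fully active, have no activators, and are modelled as long-lived
   (turnover `1e-4 s^-1`): they hold actin and pMLC down in the resting
   state. Src (half active initially, also long-lived) keeps p190RhoGAP
   active, which clamps RhoA. In the retracting state the cascade silences
   all three brakes -- LIMK phosphorylates cofilin, CPI-17 inhibits MLCP,
   caveolae (via Csk) shut down Src -- so the same stages that are braked
   at rest run freely once the input has switched the system on. This
   asymmetry, not fine-tuned rate values, is what makes "retracting" and
   "quiescent" both stable.
3. **The initial Src transient must not trip the latch.** Src starts at 50
   and transiently activates caveolae; the Src-to-caveolae rates sit at the
   slow end of the protein window so that this pulse stays below the
   threshold separating the two basins, while the tension-driven caveolae
   route (the physiological trigger) is fast.

Within those constraints the remaining exponents were tuned by a discrete
search over the grid until the full in-silico experiment catalogue passed;
the profile is shipped as data, and any alternative profile on the grid can
be supplied to `compile_model()`.

## Simulation

`simulate_model()` integrates with `deSolve`'s LSODA (automatic
stiff/non-stiff switching) over 10000 s reported every 25 s (401 points),
matching the reference protocol. Events -- timed parameter changes or species
reassignments -- split the integration exactly at their time stamps; the
state at a grid point coinciding with an event is the pre-event
(left-limit) value. Defaults: relative tolerance `1e-8`, absolute `1e-10`,
tight because pools span 0--100 and sensitivity finite-differencing needs
headroom. A pool undershooting below `-100 x atol` aborts the run rather
than being clipped. Steady state is declared when every pool's trailing
1000 s peak-to-peak excursion is within 1% (behaviour classification) or
`1e-6` (sensitivity analysis) of its final value, with a one-unit floor on
the denominator so near-empty pools are judged on the activity scale.

## The experiment catalogue

Ten parameter-free scenarios encode the in-silico experiment catalogue:
input present/absent, gradient-to-uniform and uniform-to-gradient switches
at t = 4000 s, 12% RhoA and caveolae knockdowns (initial-condition moiety
rescales), reversible osmotic shock (membrane-tension turnover
0.01 -> 10 at 4000 s, restored at 7000 s), Y-27632 (ROCK1/PKN2 turnover
x1000 at 5000 s) and global/caged cytochalasin-D (F-actin turnover x100 /
x20 at 5000 s). Thresholds operationalising the qualitative claims are
configuration, not constants: responsive >= 50, negligible <= 5,
"severely reduced" <= 50% of unperturbed, "near identical" <= 5 units of
maximum divergence, shock recovery >= 80% of the pre-shock plateau.

## Sensitivity and robustness

`scaled_sensitivities()` estimates the dimensionless elasticities
S = (k/R) dR/dk of steady-state rear retraction by central differences
(delta = 1%; the differencing scheme is our choice, matching common
practice) at the steady state of the unperturbed scenario. Because
uniformly rescaling all mass-action rates only rescales time, the
steady state is invariant and the elasticities must sum to zero; the
reported sum is an end-to-end accuracy check, and |sum| <= 1e-2 at
delta = 1% in the shipped configuration. "Critical parameters" are the top
5 by |S| (the count is our choice); `robustness_sweep()` halves and doubles
each and re-classifies the input/no-input behaviour pair, which is
unchanged for the shipped profile.

## The synthetic ensemble

`sample_parameter_profiles()` draws rate profiles with the statistical
structure the analysis assumes -- exponents uniform on the per-class ranges
protein `{1..3}`, biophysical `{2..4}`, turnover `{2..3}`, reverse rates at
10% of forwards, event-scaled turnovers anchored at 0.01 -- deterministically
given a seed. `ensemble_summary()` classifies each profile by the
input/no-input pair (`faithful`, `non_responsive`, `constitutive`,
`non_convergent`). The ensemble quantifies how special the calibrated
profile is under the declared uncertainty model; it does not reproduce the
original manual calibration path, which is not reconstructible. Random draws ignore the brake-timescale structure described above, so
most sampled profiles are not faithful; the reported fraction should be
read as a measure of how strongly the phenotype constrains the rates, not
as a failure rate of the topology.

## What the generator does and does not emulate

The synthetic stage emulates parameter uncertainty on the stated grid only.
It does not emulate cell-to-cell variability, spatial organisation (the
model is a single well-mixed compartment standing in for the cell rear),
stochastic caveolae assembly, or measurement noise in the imaging readouts
wet-lab imaging assays quantify. A passing suite therefore shows
that the wiring plus formulation rules can produce the reported phenotype
catalogue robustly in a deterministic, well-mixed setting -- not that real
rear retraction has these rate constants.

## Numerical and design choices

* Reverse rates exactly 10% of forwards (bound: at most 10%).
* Mixed protein/biophysical one-step reactions are irreversible; turnover
  supplies the return flux.
* Caveolae formation by decreased tension is a one-step catalysed change;
  Src's promotion of caveolae is a separate two-step edge.
* Knockdowns rescale both pools of a bound-free state proportionally;
  composing knockdowns multiplies fractions.
* Simultaneous events apply in list order; event times must divide into
  the grid for exact reporting (all catalogue events do).
* The steady-state detector uses a one-unit floor, so "relative" tolerance
  degrades gracefully to absolute for pools near zero.
* Reaction order is deterministic (edges in diagram order, then turnover),
  so compiled models, SBML exports and CSV outputs are diff-stable.
* Whether formins are activated by RhoA, ROCK1 or both is not decided by
  the source text; the canonical diagram includes both edges, at the slow
  end of the window so the doubled drive does not distort the cascade.
* The deposited exchange-format model for this pathway was not available
  during development; `from_sbml()`/`model_diff()` exist so a locally
  supplied copy can be diffed against the canonical reconstruction instead
  of asserting equality.

## Problem sizes used in the shipped analyses

The packaged checks run the full 10000 s protocol at 25 s output for the
scenario catalogue, 50-profile ensembles at 250 s output for the ensemble
fraction, and steady-state extensions (doubling the horizon up to a cap)
for the sensitivity analysis. These sizes follow the reference protocol
exactly where it is stated (10000 s / 25 s) and are otherwise chosen to
keep a full reproduction run in the minutes range on a laptop.

## Known limitations

* Single compartment; no rear/front spatial gradient within the cell.
* Mass action only -- no saturating (Michaelis--Menten) or cooperative
  kinetics; the binding-complex bottlenecks play the saturating role.
* The 0--100 normalisation makes all moieties equal; relative expression
  levels are not modelled.
* The quiescent state is metastable on very long horizons: with all brakes
  subject to (slow) turnover, residual activity eventually erodes them.
  Within the 10000 s protocol this is invisible, but extrapolation far
  beyond it is not meaningful.
* EHD2 is not a separate node; the caveolae knockdown stands for the
  caveolin-1/EHD2 interventions jointly.
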