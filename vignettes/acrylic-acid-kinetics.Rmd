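---
title: "Kinetic modelling of acrylic-acid production: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of acrylic-acid production: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aakin)
```

## The modelling problem

Acrylic acid (AA) can be made biologically in *Escherichia coli* by
extending central carbon metabolism (CCM) towards
3-hydroxypropionate (3-HP) and oxidising 3-HP to AA through a shared
CoA-dependent trio of enzymes. Three routes to 3-HP are established: the
glycerol route (glycerol dehydratase + aldehyde dehydrogenase, vitamin-B12
dependent), the malonyl-CoA route (malonyl-CoA reductase + malonic
semialdehyde reductase) and the beta-alanine route (beta-alanine
aminotransferase + the same semialdehyde reductase). `aakin` builds
deterministic kinetic ODE models of these systems, estimates the maximal
rates the literature does not report, simulates batch fermentations, runs
metabolic control analysis (MCA), and executes an iterative,
control-coefficient-guided search for over-/under-expression targets.

The package works on any chassis model that exposes the attachment
species of the pathway extension (triose phosphate, PEP, pyruvate,
acetyl-CoA, oxaloacetate, 2-oxoglutarate, the NAD(P) and adenylate pools,
phosphate, ammonium, bicarbonate and free CoA). Published chassis models
can be imported from SBML; a synthetic chassis generator provides a small,
fully controlled stand-in so that every stage of the pipeline runs and is
testable offline.

## Rate-law library

Every mechanism used by the extension and the heterologous routes is
available as a closed-form rate law (`list_mechanisms()`): Michaelis-Menten
with one to three substrates, a random bi-bi denominator form, ordered
bi-bi with competitive product inhibition, reversible rapid-equilibrium
random bi-bi and reversible ping-pong bi-bi (both parameterised with an
equilibrium constant so the rate vanishes exactly on the equilibrium
manifold), ping-pong with substrate inhibition, two-substrate Hill
kinetics, specific activation (used for the B12-dependent dehydratase) and
elementary mass action. Units are fixed throughout: concentrations mM,
rates mM/s, turnover numbers 1/s, time in seconds internally with hours
only at reporting.

Native enzymes carry an explicit `Vmax`; heterologous enzymes are
parameterised as `Kcat * E_total` with the enzyme pool deliberately in
surplus (100 mM) so that no heterologous step is artificially limiting —
the point of the analysis is to find bottlenecks in the host metabolism,
not in the inserted pathway. The surplus can be lowered (10 or 1 mM) for
sensitivity analyses.

Two conventions deserve a note. Rate-law tables in the
metabolic-engineering literature print these mechanisms in many
typographic variants, so the package always canonicalises to the standard
closed form of the named mechanism. And the random bi-bi constants of the
reductase enzymes are tabulated with `Km_a * Km_b` as the constant
denominator term where glycerol kinase carries a separate dissociation
constant `Kd_a * Km_b`; the reductases are therefore bound with
`Kd_a = Km_a`.

Numerically, all denominators are strictly positive for non-negative
concentrations — with one exception: the ping-pong substrate-inhibition
form has no constant term and is 0/0 at the origin, where the
implementation returns its limit, zero. During stiff integration,
concentrations are allowed microscopic negative excursions (within the
integrator's absolute tolerance) rather than being clamped at zero: the
rational rate laws continue smoothly there, whereas a hard clamp puts a
derivative kink exactly where the implicit solver needs a consistent
Jacobian, collapsing step sizes. The Hill exponent is the only power law
and is guarded separately.

## Vmax estimation

Literature rarely reports `Vmax` directly, so two estimators are
provided.

**Method 1 (native-metabolism reactions).** A steady-state flux
distribution of the chassis is computed (continuous variant, see below).
The reactions shared with a stoichiometric model are pinned to those
fluxes within a half-width `tol`, and the maximum feasible flux `v` of the
new reaction is found by flux variability analysis (LP). The estimate is
`Vmax = v / F`, where `F` is the rate law's saturation factor at the
reference state — chassis species at their steady-state concentrations and
newly added metabolites at 1 mM. The default pin half-width is 0.01 mM/s,
appropriate for full-size CCM models whose fluxes are of order 1 mM/s; on
the synthetic chassis (uptake about 0.014 mM/s) the proportional analogue
is about 1e-4 mM/s, and the closed-loop tests use that value. Only the
pins constrain the LP; no biomass-optimum fraction is imposed (an optional
objective is accepted but off by default).

The LPs are small but highly degenerate (many exact-zero right-hand
sides). The general-purpose simplex implementations available in the
environment either cycle or silently mishandle negative right-hand sides
on these problems, so the estimation module carries its own dense
two-phase simplex with Bland's anti-cycling rule; its answers are checked
in the test suite against exhaustive vertex enumeration on small networks.

**Method 2 (heterologous enzymes).** `Vmax = Kcat * E_total` with the
100 mM surplus described above.

**Synth drains.** Newly added metabolites are consumed by pathways
outside the model. Each gets a first-order "synth" pseudo-reaction whose
constant is the summed consuming flux of that metabolite in the
stoichiometric model divided by the 1 mM reference concentration, so the
drain reproduces exactly the reference consumption. The flux distribution
used for this is the pinned LP solution with the biosynthetic demand
reactions maximised. Drains of CoA thioesters return the free carrier,
and the triose-phosphate drain returns its phosphate: only carbon leaves
the model through a synth reaction, the conserved carrier and phosphate
moieties stay.

One deliberate deviation from pure Method 1: the default pipeline sets
the aspartate-carboxylase `Vmax` by the turnover-number method
(0.57 1/s x 100 mM = 57 mM/s) rather than by its demand-limited FVA
estimate. The FVA estimate throttles the whole beta-alanine route to
negligible flux — the demand bound for beta-alanine in any stoichiometric
model is tiny — so a functional route needs this step parameterised like
the heterologous enzymes. The override is a visible argument
(`pipeline_defaults(aspc_kcat = NULL)` restores the strict estimate).

## Model variants

Nine reactions extend the chassis (glycerol-3-phosphate dehydrogenase
and phosphatase, glycerol kinase, glycerol dehydrogenase, the PTS-linked
dihydroxyacetone kinase, acetyl-CoA carboxylase, glutamate dehydrogenase,
aspartate aminotransferase, aspartate carboxylase). Two of the printed
equilibria are reversible (G3pD with Keq = 900, AspAT with Keq = 3.2); the
glycerol dehydrogenase is parameterised in the dihydroxyacetone-forming
direction only, which is why glucose-fed variants omit it (and the
downstream dihydroxyacetone kinase): with only that direction available
the pair would deflect freshly synthesised glycerol straight back into
central metabolism. The dihydroxyacetone-kinase mass-action constant has
no literature value; it is mandatory configuration with no default, and
the synthetic pipeline fills it by Method 1 like the other extension
steps.

Combining {glucose, glycerol} x {glycerol, malonyl-CoA, beta-alanine}
x {3-HP, AA} yields twelve variants (`variant_specs()`), assembled by
`build_variant()` deterministically: chassis + extension + synth drains +
heterologous route + a first-order export step for the end product.
Initial carbon is 55.5 mM glucose (10 g/L) or 217.2 mM glycerol (20 g/L) —
equal carbon on both sources. The vitamin-B12 coenzyme appears as a fixed
boundary species at a saturating 1 mM by default, since only the
activation constant (Ka = 0.008 mM) is known. The G3pD stoichiometry is
kept NADPH-linked as printed, although the *E. coli* enzyme is usually
NADH-linked; users can rebind the role if they prefer the NADH convention.

## Simulation, steady states and control analysis

Batch time courses run under LSODA (stiff/non-stiff switching) for 3 or
6 hours by default; final titers are reported in g/L through exact molar
conversions (glucose 180.16, glycerol 92.09, 3-HP 90.08, AA 72.06 g/mol).

MCA needs a steady state, which a batch model does not have, so
`make_continuous()` adds a constant-rate feed for the carbon source —
defaulting to the batch model's own mid-exponential uptake flux (measured
where half the carbon is consumed) scaled by a 0.9 safety margin, so the
operating point sits strictly inside the uptake capacity — and
first-order drains (k = 0.01 1/s)
for glycerol, malonyl-CoA, beta-alanine, the end product and its
extracellular pool. Thioester drains return free CoA. All feed/drain
constants are recorded in the model annotations.

`find_steady_state()` integrates towards equilibrium and polishes the
root with a damped Newton iteration on the conservation-reduced system:
the cofactor pools (NAD(H), NADP(H), adenylates, CoA, phosphate) are
conserved moieties, so the reduction uses the link matrix `L` with
`N = L N_R` over an independent row set of the stoichiometric matrix.
Stability is judged by the spectrum of the reduced Jacobian; unstable
states are refused for control analysis, which is also the loop's
"no steady state" stop condition.

Flux control coefficients for a target flux are computed two ways and
reported side by side: structurally,
`C = I - (dv/ds) L M^{-1} N_R` scaled by `v_j / J` (with
`M = N_R (dv/ds) L`), and by central finite differences (1% enzyme
perturbations with the steady state re-solved). The summation theorem
(`sum C = 1`) is asserted on every table to 1e-3. The two routes agree to
well under 1% on all coefficients of meaningful size; on coefficients
near zero a relative comparison is meaningless (the finite-difference
noise floor dominates), so agreement there is checked absolutely.

## The design loop

`design_loop()` alternates MCA on the continuous variant with a bounded
one-dimensional search on the batch variant: the reaction with the largest
absolute control coefficient over AA formation (excluding feed/drain/
export/synth plumbing and the reporter flux itself) is selected — positive
coefficient means over-expression, negative means under-expression — and
its `Vmax` is optimised over `[Vmax/50, 50 Vmax]` by deterministic Brent
search in log space (the per-step problem is one-dimensional, so a
deterministic bracketing search reproduces exactly across runs where a
stochastic metaheuristic would not). Knock-outs are represented by the
1/50 floor of the bounded space rather than zero. The loop stops when the
carbon feed is limiting (carbon exhausted before the horizon and no
further gain available at the bound), when the selected bottleneck was
already optimised, or when the mutant fails to reach a stable steady
state.

## The synthetic chassis

`make_chassis()` generates a deliberately simple CCM-like kinetic model
(13 lumped reactions: PTS uptake, glycerol transport, a two-step
glycolytic backbone, pyruvate dehydrogenase, two lumped TCA segments,
anaplerosis, oxidative phosphorylation, a transhydrogenase-like NADPH
overflow, an anabolic oxaloacetate drain, maintenance ATPase and
reversible adenylate kinase) together with a stoichiometric twin that
contains the same reactions plus the pathway-extension columns,
biosynthetic demand reactions for the six synth-target metabolites, and
exchange columns for the boundary species. Consistency is by
construction: the kinetic steady-state flux vector satisfies the twin's
balance equations exactly, which the test suite verifies by pinning every
shared reaction at once.

The generator's constants were chosen once for realism at laboratory
batch scale: 10 g/L glucose is exhausted within a 3-hour batch, cofactor
pools sit at typical intracellular values (NAD pool 1.65 mM, NADP pool
0.2 mM, adenylates 3.4 mM), and the continuous variant has a unique
stable positive steady state. Kinetics are irreversible Michaelis-Menten
and mass action so that closed-loop oracles stay tractable. What the
chassis deliberately does not reproduce: realistic flux ratios of the
real CCM, allosteric regulation, PTS crosstalk, or the experimental
titers of any published strain — passing tests on this chassis
demonstrates the correctness of the machinery (assembly, estimation,
integration, control analysis, optimisation), not quantitative agreement
with measured *E. coli* fermentations, which requires importing a
published chassis model via `read_sbml()`.

A seed jitters all rate constants log-uniformly (+/-10% by default) to
generate families of chassis instances for robustness checks, e.g. the
recovery property: throttle one reaction 20-fold, and control analysis
should name it as the top actionable target across jittered instances.

Batch models of this size run in a second or two; the full test suite
and the analysis script each complete in a few minutes on one CPU. The
problem sizes used there (a 22-species chassis, 33-reaction producing
variants, six jittered instances for the recovery property) were chosen to
keep a full pipeline run interactive while still exercising every stage.

## Known limitations

* The replay tests of model sizes, batch titers, mutant titers and
  bottleneck identities require the deposited BioModels SBML files,
  which are not redistributable inside the package; point
  `options(aakin.biomodels_dir = ...)` at a local copy to run them.
* SBML support covers Level 2/3 core with kinetic laws (the subset the
  deposited models use); events, rules and the FBC extension are out of
  scope, and stoichiometric models for Method 1 are built or supplied as
  matrices.
* The continuous-culture feed/drain parameterisation is a modelling
  choice of this package; control-coefficient magnitudes depend on it,
  and the rank order of the coefficients is the robust output.
* Intracellular products reach the medium through a first-order export
  stand-in; no transporter kinetics are modelled.
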