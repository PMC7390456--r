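---
title: "Modelling CaMKII phosphorylation as a leaky integrator of calcium signals"
author: "CaMKIIsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CaMKII phosphorylation as a leaky integrator of calcium signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's methods account: the model and its
assumptions, the numerical choices, the synthetic calcium inputs, and the
places where the design was genuinely open and a decision had to be made.

# The reaction system

Five molecule kinds interact in a single well-mixed compartment representing
a postsynaptic density of volume V = 0.0156 μm³ (9.39 molecules per μM):

* **Ca²⁺** — free ion pool, driven by influx/efflux (below).
* **CaM** — two lobes (C, N), two Ca²⁺ sites each. The two sites within a
  lobe are treated as indistinguishable, so a CaM state is the pair of lobe
  counts: nine states. The printed stepwise on/off constants are used
  exactly as given, with no additional statistical factor for the two sites
  of a lobe — the rates are taken to be the lumped stepwise constants.
* **Ng** — binds Ca²⁺-free CaM only; CaM bound to Ng can bind neither Ca²⁺
  nor CaMKII (mutual exclusivity).
* **CaMKII** — monomers (model 1) or dodecameric holoenzymes (model 2).
  A subunit is *active* when CaM-bound (any Ca²⁺ load) or phosphorylated at
  T286; phosphorylation requires the substrate's CaM to carry at least one
  Ca²⁺ ion, and the phosphorylation rate is indexed by the substrate's CaM
  state (there is deliberately no rate for a Ca²⁺-free substrate CaM).
  The slower T305/6 site, subunit exchange between holoenzymes, and compact
  or dimerised subunit conformations are outside the model's scope.
* **PP1** — dephosphorylates via an explicit enzyme–substrate complex
  (below).

All kinetics live in a single versioned plain-text rate table
(`inst/extdata/rate_table_v1.tsv`), loaded by `loadRateTable()`; every
reaction in either model traces to a named row. One units decision is
recorded in the table itself: the on-rate of CaM binding to unphosphorylated
Ca²⁺-free CaMKII is printed in the source literature with M⁻¹s⁻¹ units while
every sibling row uses μM⁻¹s⁻¹; we read it as 3.8·10⁻³ μM⁻¹s⁻¹ for
consistency with its siblings and with the upstream study it derives from.

# Rules, not reactions

Reactions are written as *rules* over partial states: a rule names only the
features it cares about ("don't care, don't write"), and `generateNetwork()`
closes the rule set over seed species into a concrete network in which each
canonical species appears once. The closure is breadth-first and
deterministic; identical instantiations arising from two embeddings into a
symmetric species are merged by summing statistical factors, and a
bimolecular reaction between two copies of one species carries the usual
factor 1/2.

For the monomer model the closure yields 421 species and ~3800 reactions.
The combinatorially expensive part is the transient kinase–substrate pair:
two CaM-bound monomers associate reversibly (konCaMKII/koffCaMKII) and the
pair is the context in which phosphorylation happens. Two decisions were
genuinely open here:

* **CaM residence in a pair.** Members of a pair keep their CaM for the
  pair's lifetime. At koffCaMKII = 60 s⁻¹ a pair lives ~17 ms against CaM
  off-rates of 0.07–6.7 s⁻¹, so fewer than ~10% of pairs would see a CaM
  unbinding anyway, and allowing it would roughly double the dimer state
  space again. Ca²⁺ exchange on a member's CaM *is* allowed (it is fast and
  changes the phosphorylation rate).
* **PP1 access to paired members.** PP1 must reach phosphorylated monomers
  inside pairs. Under the rule semantics the dephosphorylation rule matches
  a phosphorylated, CaM-bound CaMKII regardless of the pairing bond; and
  quantitatively, at physiological CaM a majority of CaM-bound monomers are
  paired at any instant, so excluding paired members would shield most of
  the phosphorylated pool from PP1 and qualitatively distort the
  dose–response (the first local maximum disappears and the second is
  grossly inflated). Pair members therefore carry a PP1-engagement flag.

PP1 itself is modelled as the explicit two-step scheme: binding at a
configurable on-rate (default konPP1 = 10 μM⁻¹s⁻¹), unbinding at
koffPP1 = konPP1·K_m − k_cat so that (koffPP1 + k_cat)/konPP1 equals the
printed K_m = 11 μM, and catalysis at k_cat = 0.41 s⁻¹. A shared, finite
PP1 pool makes substrates compete, which matters at high phosphorylation.
PP1 binds phosphorylated CaMKII with or without CaM attached.

**PP1 concentration.** No measured PSD value is available to this model;
`PP1` is a required configuration field with a documented repository default
of **1.25 μM**, chosen once so that the deterministic single-spike
phosphorylation lifetime (time from peak to 10% of peak) is on the order of
minutes. Every quantity downstream of dephosphorylation — in particular the
leaky-integrator capacity and rate — inherits this choice; see "Sensitivity"
below.

# Model 1: deterministic monomer network

`massActionRHS()`/`simulateODE()` integrate the generated network with a
stiff solver (lsoda) and an analytic sparse Jacobian; conservation groups
(total CaM, CaMKII, Ng, PP1, and Ca when influx/efflux are off) are exact
left null vectors of the stoichiometric matrix and are checked symbolically
in the tests. Three calcium bookkeeping modes are used:

* **Free-Ca clamp** (`equilibrate`, baseline states): free Ca²⁺ is held at a
  target (100 nM at rest) as an algebraic constraint; bound calcium evolves
  and the implied total calcium is reported, since it differs between
  conditions. Steady state is declared when the maximum relative derivative
  falls below tolerance (default 1e−8) on a geometrically growing
  integration horizon.
* **Closed system** (`doseResponseScan`): total calcium is fixed (default
  10 μM) with no source or sink, so raising total CaM depletes free Ca²⁺.
  This is the regime in which Ng — by sequestering CaM and so raising the
  free-Ca:free-CaM ratio — *increases* the 3- and 4-Ca²⁺ CaM species over a
  mid-range of CaM, producing the crossover, the die-out of multi-Ca forms,
  and the double-peaked total-phosphorylation dose–response. A free-Ca
  clamp cannot produce any of these (free-CaM loading would be independent
  of total CaM), which is why the scan is closed.
* **Pulse mode** (spikes and trains): influx = baseline influx k_e·[Ca]_rest
  plus the pulse envelope; efflux first-order at k_e.

# Synthetic calcium inputs

A pulse injects calcium at rate A·((t−t₀)/τ_R)·e^(−(t−t₀)/τ_F) from onset
t₀; overlapping pulses sum. Trains place onsets at k/f (default f = 0.5 Hz,
10 or 30 pulses). The stated input conditions are: resting free Ca ≈ 100 nM,
pulse peaks ≈ 10 μM free Ca, decay back to near rest within ~100 ms.
The shape parameters are not printed anywhere, so they are part of this
package's calibration:

* τ_R = 5 ms, τ_F = 15 ms (fixed defaults).
* **A is calibrated per condition** by bisection on the deterministic
  monomer model for that condition's composition, because CaM, Ng and
  CaMKII buffer incoming calcium (the same target peak needs a different
  amplitude with and without Ng). Stochastic achieved peaks are then
  reported per ensemble as mean ± sd.
* **k_e = 1000 s⁻¹** (first-order efflux; a constant influx k_e·0.1 μM
  balances it at rest). This default was chosen from the decay constraint:
  at k_e = 100 s⁻¹ the slow release of buffer-bound calcium leaves free Ca
  at ~2.7 μM a full 100 ms after the pulse and ~0.2–0.3 μM between train
  pulses, which violates the ~100 ms return-to-baseline condition and
  sustains spurious CaM loading between pulses. At 1000 s⁻¹ free Ca is back
  within twice baseline by ~0.2 s and within 10% of its peak by ~90 ms.
  The residual sub-μM tail from buffered release is reported by
  `calibratePulse()` (fields `returnTime`, `nearBaselineTime`), not
  enforced away: a first-order efflux cannot clear buffer-released calcium
  arbitrarily fast, and we regard the efflux law itself as a stand-in for
  the unspecified buffering mathematics of the original inputs.

# Model 2: network-free stochastic holoenzymes

At 80 μM in V the model holds 752 CaMKII monomers; 752 is not divisible by
12, so the simulator instantiates the rounded 63 complete holoenzymes (756
subunits) and reports both numbers. Each holoenzyme is two independent
rings of six; the kinase at ring position i targets position i+1 (mod 6) —
the direction is unobservable under symmetry and fixed once. CaM, Ng and
PP1 molecules and Ca²⁺ ions are discrete agents.

The simulator (C++ core) is an exact SSA over aggregated channels: agents
are grouped into equivalence classes (free CaM by lobe state, subunit-bound
CaM by state and host phosphorylation, free/engaged PP1, subunits by
CaM/phospho/PP1 status), channel propensities are class counts times
per-pair rates (kon/(N_A·V·10⁻⁶)), and the fired event picks a uniform
member of its class. Neighbour phosphorylation keeps a per-subunit
propensity (zero unless the substrate is unphosphorylated, CaM-bound with
≥1 Ca²⁺, and its ring predecessor is active) updated incrementally. The
time-inhomogeneous pulse-influx channel is simulated by thinning against a
piecewise-constant envelope bound (single-pulse peak near each onset, the
decreasing envelope value per τ_F-segment afterwards), with event-free
jumps where the bound changes; the bound is rigorous, so the channel stays
exact. All randomness comes from R's RNG: a run is fully determined by
(state, protocol, seed).

Runs start from CaM/Ng occupancies sampled from the deterministic baseline
equilibrium marginals and are burned in at baseline (default 10–20 s) before
the protocol starts at t = 0; observables (phosphorylated subunits,
CaM-bound subunits, CaM-bound unphosphorylated subunits, free Ca, Ng-bound
CaM, free CaM, PP1 engagement — all in μM) are recorded on a fixed grid. An
optional audit mode re-verifies agent-level invariants (molecule totals,
bond symmetry, no PP1 on unphosphorylated subunits) during simulation and
aborts on any violation; the tests run with it enabled.

# Response analysis

* `deltaCurve()` subtracts the pre-pulse baseline average (default window
  5 s before the first onset), because baseline phosphorylation differs
  between conditions.
* `computeMetrics()`: AUC by trapezoid over t ≥ 0; peak; peak time;
  lifetime = time from the peak to the first crossing of 10% of peak, with
  linear interpolation between samples and censoring at the record end if
  the level is never reached.
* **Responders.** A stochastic run is a responder when at least one
  phosphorylation event fires during the protocol window (threshold
  configurable). Spontaneous baseline events are rare (≲1 per 40 s run), so
  the definition discriminates cleanly. Following the source conventions,
  single-spike summaries average responders only, train summaries average
  all runs; the policy is recorded in the output.
* `fitLeakyIntegrator()` fits x(t) = k(1 − e^(−a·t)) by nonlinear least
  squares (Levenberg–Marquardt), initialised at k₀ = the late-curve level
  and a₀ = ln 2 / t_half, with k ≥ 0, a > 0. R² is computed on the fitted
  grid with uniform weights. The fit window runs from the first onset to
  the end of the train (60 s for 30 pulses at 0.5 Hz), not into the
  post-train decay, since the fitted form is monotone.

# Problem sizes

The test suite uses 30 stochastic runs per condition for train and
single-spike ensembles (matching the averaging protocol of the study
conditions); the acceptance script averages 100 runs per condition for a
stabler estimate of the fitted parameters. The reduced Ca/CaM
SSA-versus-ODE check uses 100 runs; dose–response grids of ~18 CaM values from 1.5 μM to
3·10⁴ μM; and deterministic horizons of 50–50 000 s for equilibration.
These sizes were chosen as the smallest at which the respective estimators
are stable; they are package choices and can be raised in configuration.

# Sensitivity and known limitations

* **The (k, a) pair is a PP1 readout.** Across conditions the initial
  integration rate r = k·a is insensitive to PP1, while the capacity obeys
  the Michaelis–Menten balance k ≈ r·K_m/(k_cat·[PP1] − r). A ±20% change
  in [PP1] moves k by ∓~30%. Since [PP1] is a documented default rather
  than a measurement, fitted capacities should be read with that caveat;
  the Ng-driven collapse of k (an order of magnitude) is robust to it.
* **Efflux stand-in.** First-order efflux with constant baseline influx is
  the package's stand-in for unspecified calcium-buffering mathematics; the
  inter-pulse free-Ca tail it leaves (~0.1–0.14 μM) slightly elevates CaM
  loading between pulses.
* **Synthetic inputs are idealised.** The generator emulates the stated
  statistics of spine transients (peak, decay, frequency, baseline) but not
  NMDA-receptor/VDCC channel kinetics, explicit endogenous buffers, or
  spatial gradients — passing tests say nothing about those features of
  real data.
* **Monomer pairs lock their CaM** for the (short) pair lifetime, as
  discussed above.
* Holoenzyme rings do not interact, there is no subunit exchange or
  holoenzyme disintegration, no T305/6 phosphorylation, and no
  PKC-mediated Ng phosphorylation.
* At 100 nM free Ca the model is monostable: an all-phosphorylated start
  relaxes to the unperturbed baseline in both the deterministic and the
  stochastic model (verified in the tests). This is a property of the
  measured K_m = 11 μM; bistable variants in the literature require a much
  smaller K_m.
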