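---
title: "Constraint-based modeling of heterofermentative lactic acid bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of heterofermentative lactic acid bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oenoflux)
```

## The model and its assumptions

`oenoflux` analyses stoichiometric metabolic models under the steady-state
assumption: with $S$ the stoichiometric matrix (rows = metabolites, columns =
reactions) and $v$ the flux vector (mmol gDW$^{-1}$ h$^{-1}$), every analysis
operates on the polytope

$$ P = \{\, v : S v = 0,\; v_l \le v \le v_u \,\}. $$

Flux balance analysis (FBA) maximizes the flux of a designated biomass
reaction over $P$; the optimum is the specific growth rate $\mu$ (h$^{-1}$).
Uptake is negative flux through an exchange reaction, secretion positive —
an *in silico* medium is therefore nothing but a set of lower bounds on
exchange fluxes.

All linear programs are solved by a bounded-variable two-phase primal
simplex implemented in the package (`lp_solve()`). A simplex method was
chosen deliberately over interior-point approaches: it terminates on a
vertex with a well-defined optimal basis, so the reduced costs
$z_j = c_j - y^\top S_j$ needed by the sensitivity analysis are always
available. Feasibility and optimality tolerances are $10^{-9}$; Dantzig
pricing switches to Bland's rule after a run of degenerate steps so the
method cannot cycle. When alternative optima exist, the reported reduced
costs are those of the returned basis; `scaled_reduced_costs()` can flag
exchanges whose flux is non-unique at the optimum (via an FVA pass at the
fixed optimum), because their dual values are basis-dependent.

## The analyses

* **Screens.** A nutrient is *essential* when omitting it from the medium
  drops growth below a fraction (default 0.20) of the wild-type optimum.
  Sole-carbon-source calls use an absolute zero-growth tolerance
  ($10^{-6}$ h$^{-1}$) instead, because that screen has no wild type.
  Gene and reaction knockouts close both flux bounds (the reaction stays in
  the model); a knockout is essential when growth falls by at least 80%.
  Predictions against observed growth calls are tallied into a confusion
  matrix and summarized as sensitivity, specificity, precision, negative
  predictive value, accuracy and F-score (harmonic mean of precision and
  sensitivity); a metric with a zero denominator is reported as `NaN`,
  never as zero.
* **Variability.** FVA minimizes and maximizes each reaction's flux (two
  LPs per reaction), optionally after bounding the objective below by a
  fraction of its optimum. *Blocked* reactions are those that cannot carry
  flux with every exchange opened to $\pm 1000$ (the conventional
  unbounded proxy); the blocked tolerance is $10^{-9}$ — solver scale, not
  the growth scale — so tiny feasible loops are not misclassified.
  *Structural* dead-end metabolites appear only as products or only as
  substrates after expanding reversible reactions in both directions.
  *Functional* dead-ends are probed with temporary drain and source
  reactions: a metabolite is dead when the network cannot produce it **or**
  cannot consume it. The disjunctive reading (rather than requiring both)
  is what makes structural dead-ends a subset of functional ones and what
  ties dead-ends to blocked reactions: a metabolite that cannot be consumed
  forces all of its producers to zero flux.
* **Maintenance (NGAM).** Non-growth-associated maintenance is an explicit
  ATP-hydrolysis reaction (ATP + H2O -> ADP + Pi + H+). `fit_ngam()` fixes
  measured exchange rates as equality bounds, sweeps the maintenance flux
  over 0–5 mmol ATP gDW$^{-1}$ h$^{-1}$ (coarse step 0.1, then 0.01 around
  the coarse argmin), maximizes growth at each value, and picks the value
  minimizing the relative error against the observed growth rate.
  Relative error was chosen as the error metric because the quantity of
  interest is the proportional accuracy of biomass prediction. Grid points
  where the constrained model is infeasible are recorded and excluded, and
  infeasibility at high maintenance is expected, not fatal.
* **Sensitivity.** For exchange reactions with a binding bound, the scaled
  reduced cost $W = w\,q/\mu$ is the elasticity of growth with respect to
  the exchanged compound's rate ($q$ = flux magnitude, $w$ = reduced cost
  expressed as $d\mu/d(\text{rate})$, so positive $W$ always means "more of
  the current activity helps"). Records with zero $w$ or zero $W$ are
  omitted. Across conditions, summaries report mean ± sample standard
  deviation (the spread definition is a package choice and is labelled).
* **Sampling.** Hit-and-run over $P$: directions are drawn uniformly on
  the unit sphere of the null space of $S$ restricted to non-fixed
  reactions, chord endpoints come from exact line–box intersection, and the
  next point is uniform on the chord, so no proposal is ever rejected.
  The chain starts from the average of a handful of FVA extreme-point
  solutions, discards a warm-up prefix, and keeps every $k$-th point
  (reference configuration 100\,000 points at thinning 500; desk-scale work
  and the test suite use a few thousand points at thinning 3–20, which is
  enough for the calibration checks on box polytopes). Rankings of flux
  ranges break ties by reaction id so reports are reproducible.

## The synthetic network

`make_toy_lab_model()` generates a miniature (~65-reaction) model of a
heterofermentative, wine-associated lactic acid bacterium with recorded
ground truth. It carries the features the analyses exercise:

* hexose catabolism through the 6-phosphogluconate/phosphoketolase route to
  D-lactate, acetate, ethanol and CO2, with substrate-level ATP at
  phosphoglycerate kinase, pyruvate kinase and acetate kinase;
* NAD$^+$-regenerating mannitol and erythritol branches fed by fructose,
  plus an acetoin/2,3-butanediol branch and a water-forming NADH oxidase;
* proton-consuming malolactic decarboxylation, with L-lactic and carbonic
  acid efflux as the only proton-exporting steps, a proton-neutral CO2
  diffusion route, and an F0F1 ATP synthase (default 3 H$^+$/ATP,
  configurable over 2–4 because conclusions about proton-driven ATP should
  be checked against that stoichiometry);
* a lumped citrate lyase, a malate dehydrogenase shunt to oxaloacetate,
  pyruvate oxidase, exopolysaccharide synthesis from sugar phosphate, and
  reversible adenylate/NAD salvage from adenine and nicotinate (without a
  turnover route, conserved cofactor pools would be false positives of the
  dead-end probes);
* a biomass reaction over amino acids, pyruvate and ATP (default
  growth-associated requirement 40 mmol ATP per gDW), an ATP-hydrolysis
  maintenance reaction, exchanges for every boundary species, and a mix of
  essential (uptake-only) and synthesizable (reversible transamination
  shunt) amino acids;
* optional planted orphan metabolites — products with no consumer — as
  ground truth for the dead-end detectors, and a glycerol exchange with no
  catabolic route as a disconnected carbon source for the screens.

Two capacity caps shape the fermentation phenotype: the lumped
ethanol-forming branch (default 4 mmol gDW$^{-1}$ h$^{-1}$) and
phosphoketolase (default 12). The ethanol cap encodes the limited
ethanol-forming capacity that makes the polyol branches valuable for
NAD$^+$ regeneration: without it, fructose-only growth would never need
the mannitol branch.

### Why the maintenance fit is identifiable here

Fitting NGAM from measured rates only works when the rate-constrained model
still has the freedom to convert maintenance ATP into growth and back.
Three design features provide it, and each corresponds to something the
real organism has:

1. growth is energy-limited at the generating condition (high
   growth-associated ATP demand, ATP synthase drawing on a finite proton
   export), so the predicted growth rate falls linearly as maintenance
   rises;
2. unmeasured nutrients with uptake slack — amino acids — supply the carbon
   for extra growth when maintenance is lowered, mirroring the role of
   measured-but-degradable amino acids in real cultures;
3. unmeasured by-product routes (butanediol, pyruvate, exopolysaccharide,
   the CO2t/CO2 diffusion split) absorb carbon, redox and protons when
   growth falls.

Without these valves the measured-rate polytope is a knife edge: feasible
only at the generating maintenance value, and infeasible for any perturbed
rate table.

### The noise model

`make_synthetic_rates(noise_sd_rel = s)` perturbs the generating condition
(the medium's uptake capacities) with multiplicative Gaussian noise and
re-extracts the rates from the re-solved optimum, rather than jittering
each rate independently. Rates measured on a real culture are produced by a
real, mass-conserving flux distribution: they satisfy the network's
conservation laws up to measurement error on each *independent* quantity.
In a network this small, most measured rates are tied by exact
stoichiometric couplings (acetate to phosphoketolase plus citrate lyase
flux, for instance), and independent per-rate noise violates those
couplings outright, making every equality-constrained fit infeasible.
Condition-level noise keeps the tables consistent while still moving each
rate by about `noise_sd_rel`. The observed growth rate stays at its
noiseless value, so the fit must absorb a genuine discrepancy, as with
real data.

### What the generator does not emulate

The toy network is a caricature: single lumped reactions stand for whole
pathways, biomass has no macromolecular composition, cofactor specificity
(NADH vs NADPH) is collapsed, there is no fatty-acid or cell-wall
metabolism, and its ~65 reactions cannot reproduce genome-scale statistics
(blocked-reaction counts, connectivity tables, essential-pathway
distributions of a 660-reaction reconstruction). Tests passing on it show
that the algorithms are correct on networks whose ground truth is known by
construction — not that any particular biological conclusion transfers to a
real organism.

## Numerical choices

* All flux bounds are finite; $\pm 1000$ is the conventional proxy for
  "unbounded". Formats that omit bounds get reversibility defaults
  ($-1000..1000$ reversible, $0..1000$ irreversible) with a warning.
* Growth below $10^{-6}$ h$^{-1}$ is treated as zero everywhere.
* Blocked/dead-end tolerances are $10^{-9}$; sampler feasibility is
  asserted at $10^{-6}$.
* Ties in variable-reaction rankings are broken by reaction id; the NGAM
  argmin takes the first minimizing feasible grid point (the refined error
  curve is V-shaped on this generator, so the choice only matters at exact
  ties).
* Degenerate inputs fail loudly: empty media starve, infeasible fixed
  rates are reported per grid point, screens on a non-growing wild type
  raise an error rather than returning all-essential calls.

## Problem sizes

The test suite and the acceptance script run entirely on generated models:
the default ~65-reaction network (about 130 LPs for a full
essentiality ground truth, ~60 LPs per maintenance fit), 100-model batches
for property checks, and $10^4$ sampler points at desk-scale thinning.
These sizes were chosen so each analysis stays in the regime where its
brute-force oracle (vertex enumeration, exhaustive truth tables, direct
residual checks) is exact.

## Known limitations

* The simplex is dense and refactorizes the basis each iteration — ideal
  up to a few hundred reactions, not for genome-scale models with tens of
  thousands of columns.
* Reduced costs under degenerate optima are basis-dependent; the package
  flags non-unique exchanges but does not enumerate alternative bases.
* FVA reports raw ranges; no thermodynamic loop correction is applied.
* The maintenance fit assumes rates measured at (pseudo-)steady state and
  applies them as equalities; measurement windows are not modelled.
* SBML support covers Level 3 + fbc flux bounds and Level 2 kinetic-law
  bounds with notes-based gene associations; arbitrary annotations are not
  round-tripped.
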