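---
title: "Constraint-based analysis of succinate fermentation with capnoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of succinate fermentation with capnoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnoflux)
```

## The model class and its assumptions

capnoflux works on stoichiometric metabolic models at steady state. A model
is a set of metabolites (with elemental formula and charge), reactions
(signed stoichiometry, flux bounds in mmol·gDCW⁻¹·h⁻¹) and one objective
reaction. Every analysis in the package reduces to linear programs over

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \;\; l \le v \le u,$$

where $S$ is the metabolite-by-reaction stoichiometric matrix. The standard
assumptions apply: balanced growth (no metabolite accumulation), flux bounds
as the only kinetic information, and exchange reactions — reactions touching
exactly one metabolite — as the interface to the environment, with negative
flux meaning uptake. "Unconstrained" bounds use a finite sentinel of
±1000 mmol·gDCW⁻¹·h⁻¹ (`UNBOUNDED_FLUX`), the common convention in this
field; it keeps every LP bounded and is configurable per model. The LPs are
solved by a bounded-variable two-phase primal simplex built into the
package, with deterministic pivoting (largest reduced cost, lowest-index
tie-break, Bland's rule fallback), feasibility/optimality tolerances of
1e-9, and dense refactorisation — entirely adequate at the problem sizes
the package targets (tens to ~1000 reactions). Repeated solves of the same
problem are bit-identical; reported objectives and FVA ranges are therefore
reproducible even where alternate optima leave individual fluxes degenerate.

Three analyses sit on top of `fba()`:

* **pFBA** (`pfba()`) re-solves with the objective pinned at 100% of its
  optimum and minimises total absolute flux via the usual forward/backward
  splitting. No relaxation of the optimum is applied.
* **FVA** (`fva()`) minimises and maximises each reaction's flux while the
  objective is held at a fraction γ of its optimum. Because the objective
  is a single reaction here, the γ-floor is imposed as a bound rather than
  an extra constraint row. Figure-style growth scenarios use γ = 0.95 or
  0.99; both are arguments, not constants.
* **Theoretical maximum yields** (`max_theoretical_yield()`) fix the
  substrate uptake to a unit basis, silence biomass formation, drop any
  *forced* maintenance flux, and maximise the product exchange. The
  maintenance reaction keeps its hydrolysis *capacity*: fermentative routes
  generate surplus ATP, and a steady state with no ATP sink would make the
  fixed-uptake LP infeasible. Removing the requirement (lower bound zero)
  rather than the capacity is the reading that leaves yields meaningful;
  the dissipated ATP carries neither carbon nor electrons, so it cannot
  alter a yield.

Yield bookkeeping is explicit about units: molar yields are
mol product per mol substrate at a fixed uptake basis, mass yields use the
neutral (fully protonated) species masses — succinic acid 118.09, glucose
180.16, sorbitol 182.17, xylose 150.13, acetic acid 60.05, formic acid
46.03, ethanol 46.07 g·mol⁻¹ — so `mol_to_mass_yield(12/7, 118.09, 180.16)`
prints the familiar 1.12 g·g⁻¹.

## What the bundled fixture emulates

`asuc_core_model()` generates a reduced, fully mass- and charge-balanced
central-carbon network of *Actinobacillus succinogenes*-type anaerobic
succinate fermentation (~70 reactions, ~64 species):

* glucose entering by PEP:PTS and/or proton symport plus hexokinase
  (`transporter` option), sorbitol by PTS with an NADH-generating
  sorbitol-6-phosphate dehydrogenase, xylose into the non-oxidative
  pentose-phosphate pathway;
* full glycolysis, a lumped oxidative PPP (2 NADPH + CO2 per hexose-P) and
  a lumped non-oxidative PPP;
* the PEP node: ATP-generating PEP carboxykinase (the carboxylation entry
  into the C4 branch) versus pyruvate kinase into the C3 branch;
* the reductive C4 branch malate dehydrogenase → fumarase → menaquinol
  fumarate reductase; NADP-malic enzyme bridging pyruvate and malate with
  direction control (`me2` = forward / reverse / reversible); oxaloacetate
  decarboxylase;
* the C3 branch pyruvate-formate lyase, menaquinone formate dehydrogenase,
  phosphotransacetylase/acetate kinase and the two-step ethanol route;
* fumarate-respiration bioenergetics: the NADH and formate dehydrogenases
  are electrogenic (2 H⁺ translocated), an ATP synthase (4 H⁺/ATP) closes
  the circuit, and acid efflux is proton-coupled. Without this respiratory
  ATP credit a stoichiometric model prefers pure acetate+ethanol overflow
  (more substrate-level ATP) and never secretes succinate at maximal
  growth, which would contradict the organism's hallmark mixed-acid
  pattern;
* a toy biomass built by the biomass module (below), ATP maintenance, and
  optional hydrogenase, DMSO-respiration/glycerol, and carbonic-anhydrase
  (CO2 ↔ HCO3⁻) blocks. Succinyl-CoA ligase is deliberately absent, so the
  zero-flux constraint applied to it in genome-scale practice is structural
  here.

The defaults are the study conditions: glucose uptake 10 mmol·gDCW⁻¹·h⁻¹
(the conventional basis; figure-style runs set their own $q_S$, e.g.
8 mmol·gDCW⁻¹·h⁻¹ for the xylose chemostat condition), CO2, protons,
water, phosphate and ammonium unconstrained, cysteine and methionine
unconstrained (auxotrophies), and glutamate capped. The glutamate cap
deserves a note: the organism cannot synthesise 2-oxoglutarate, so
glutamate must come from the medium, but an uncapped bound would let the
solver burn it as an extra carbon source. `cap_glutamate()` measures the
biomass demand at the growth optimum with the bound wide open and re-caps
uptake at 1.05× that demand, recomputed per scenario. In the fixture the
transaminase/glutamate-dehydrogenase cycle conserves the glutamate pool,
so glutamate carbon structurally cannot inflate growth — the cap is then a
faithful, if redundant, guard; in a genome-scale model it is load-bearing.

### What the fixture does *not* emulate

The fixture reproduces directions, ceilings and qualitative flux
partitioning, not genome-scale magnitudes. Its biomass drains only protein
and glycogen (the network cannot make nucleotides or lipids), so growth
rates and growth-coupled yields are not comparable to a full model with a
measured biomass equation; phosphorus is fully recycled (no net P demand),
so phosphate uptake is structurally blocked; and a panel of 22 carbon
sources collapses to the bundled six-source `mini_panel()`. Passing tests
on the fixture therefore demonstrate correctness of the *methods* — LP
optimality, FVA bracketing, balancing, scoring — and the *stoichiometric
logic* of the C3/C4 split, but say nothing about quantitative agreement
with fermentation data for a particular strain; that comparison requires
the deposited genome-scale SBML and is what `scripts/repro_ibp722.R` does.

Three quantitative anchors, however, are exact properties of the
stoichiometry and are recovered by the fixture to machine precision:

* symport uptake + oxidative PPP + reverse malic enzyme and open CO2 give
  the electron-limited succinate ceiling 24/14 = 12/7 mol·mol⁻¹ = 1.12
  g·g⁻¹ on glucose, with 6/7 CO2 fixed per glucose;
* with a menaquinone-reducing hydrogenase and unlimited H2 the ceiling
  becomes carbon-limited at 2 mol·mol⁻¹ (each glucose-derived C3 unit
  carboxylated);
* the oxidative-TCA template (`oxtca_core_model()`: PDH, citrate synthase
  through succinyl-CoA synthetase, PEP-carboxylase anaplerosis, an
  O2-dependent NADH sink, no fumarate reductase or PEP carboxykinase)
  yields exactly 1 mol·mol⁻¹.

## Biomass construction

`macro_composition()` validates dry-weight mass fractions over the eight
macromolecule classes (protein, DNA, RNA, LPS, phospholipid, peptidoglycan,
glycogen, cofactors-and-vitamins) plus growth-associated (GAM,
mmol ATP·gDCW⁻¹) and non-growth-associated (NGAM, mmol ATP·gDCW⁻¹·h⁻¹)
maintenance. Each class gets a pseudo-reaction producing one gram of a
`*_g` pseudo-metabolite; `assemble_biomass()` drains them by mass fraction
plus GAM, so unit biomass flux consumes exactly one gram of dry weight —
checked by `biomass_mass_audit()`, which must return 1 within 0.1%.

Protein coefficients follow the residue-mass normalisation
$\mathrm{coeff}(aa) = f(aa) / \sum_i f(i)\,(M_i - M_{\mathrm{H_2O}})$
(mmol per g protein), with 4.3 ATP equivalents hydrolysed per peptide bond
(the common literature convention; an argument, not a constant) and the
condensation water returned. The CAV pool assumes each small molecule
contributes an equal mass share: $\mathrm{coeff}(i) = (1/n)/M_i$. The
fixture's composition is protein 0.70 / glycogen 0.30 with GAM
40 mmol·gDCW⁻¹ and NGAM 0 — GAM 40 is a typical bacterial value, NGAM 0
matches the no-maintenance convention of theoretical-yield analysis; both
are generator arguments. The fixture's protein uses the charged network
species' masses so its audit closes exactly; the 20-amino-acid table
`AA_MOLAR_MASSES` (free neutral species) is the default elsewhere.

## Curation checks

`element_balance()` reports per-element and charge residuals (products
minus reactants); exchanges and biomass pseudo-reactions are excluded, and
a missing formula marks a reaction unverifiable rather than failing.
`suggest_balancing()` solves the two-unknown integer system in
(water, proton) — compartment-local species — and flags any residual
touching elements other than H/O as structural. Dead-end detection is
purely topological over the sign pattern of $S$ under reversibility;
exchange reactions count as both producers and consumers regardless of the
current medium, since a closed uptake is a simulation choice, not a network
gap. `find_blocked_reactions()` is flux-based ([0,0] variability with no
optimality floor); note that plain FVA admits internal thermodynamically
infeasible loops, so a closed cycle is *not* blocked — loopless methods are
out of scope.

## Scenario machinery and its numerical choices

`scenario()` + `run_scenario()` make each figure-style run declarative:
medium, substrate and $q_S$, γ, bound overrides, transporter mode,
malic-enzyme direction and CO2 availability. Two conventions matter:

* **Fixed yield basis.** FVA yields divide product flux by the substrate
  uptake with the uptake pinned at $q_S$ (lower = upper bound), so the
  denominator cannot float below its bound at an FVA extreme.
* **CO2 availability fraction.** Fraction 1 means sentinel-unconstrained
  uptake and fraction 0 a zero uptake bound. Intermediate fractions need a
  reference: the package uses the CO2 uptake of the pFBA solution at full
  availability and scales its magnitude. Only the endpoints are
  convention-free; the interior of the scan is defined by this choice.
* **By-product ratio ranges** (SA/AA, FA/AA, SA/FA) default to the FVA
  range of the numerator with the denominator pinned at its pFBA flux — a
  documented approximation. `ratio_range(..., exact = TRUE)` solves the
  true fractional program via the Charnes–Cooper transform.

A caution on monotonicity: growth-coupled FVA maxima are *not* monotone in
CO2 availability, because the γ-floor is recomputed from each condition's
own optimum (feasible sets are not nested; at zero CO2 the far lower
maximal growth leaves more slack). The monotone statements the package
asserts are theorems: the theoretical-max succinate yield against a
shrinking CO2 bound, and — on the fixture — the pFBA succinate yield along
the scan. Likewise, with zero CO2 *uptake* the PEP-carboxykinase flux need
not vanish: internally produced CO2 (oxidative PPP, formate dehydrogenase,
decarboxylases) can be re-fixed at steady state.

Growth calls use a threshold of 1e-6 h⁻¹ (argument) on maximal growth;
a source without an exchange/transport reaction is called no-growth with
the reason recorded, which is how the two false negatives of the bundled
panel arise. Confusion-matrix percentages round half-up, reproducing the
86/0/9/5 split from counts 19/0/2/1 on a 22-source panel.

The glycerol/DMSO pair is the fixture's redox-imbalance story: with the
`dmso = TRUE` generator option, glycerol enters by an ATP-dependent ABC
system and is oxidised by a membrane (menaquinone-linked)
glycerol-3-phosphate dehydrogenase. Every purely fermentative route from
glycerol then nets zero ATP, so glycerol alone supports no growth; opening
DMSO as a terminal electron acceptor restores it.

## Annotation scoring

For one query CDS, each homology hit contributes weight
$w = w_{tax} \cdot w_{sim}$, where $w_{sim}$ is the hit's similarity score
normalised by the best hit and $w_{tax}$ the fraction of lineage ranks
shared with the query, counted from the root down. A candidate EC scores
$\sum_{\text{hits with EC}} w \big/ \sum_{\text{all hits}} w \in [0,1]$;
hits without any EC dilute all candidates, scores sum to 1 exactly when
every hit is annotated, and hit order is irrelevant. This concrete formula
is this package's definition — the underlying idea (frequency of the EC
among hits, down-weighted by taxonomic distance) circulates in annotation
platforms without a published equation — and it is isolated behind
`functional_score()` so an alternative weighting can be swapped in.
Partial ECs ("2.7.1.-") give their completions half credit (configurable).
Assignment takes the top EC at or above a threshold (default 0.5) with
ties (within 1e-9) sent to manual review and sub-threshold queries
retained for gap-filling revisits; `group_subunits()` joins CDSs sharing a
multimeric EC with `and` (one complex) and monomeric ones with `or`
(isozymes). There is no numeric benchmark for this scheme; validation is
property-based — planted-truth recovery at 70% truth fraction with
taxonomy bias is 100% over 200 seeded replicates, and monotonicity,
normalisation and permutation invariance are asserted directly.

## Problem sizes and determinism

The test-suite simulations run at the fixture's natural size (~70 reactions;
FVA over all reactions ≈ 140 LPs) and at 200 replicates for the LP-oracle
and annotation-recovery properties — sizes chosen so the whole suite
completes in a few minutes while still exercising every property at
non-trivial scale. All randomised fixtures are seeded and restore the
caller's RNG state; writing the same model twice produces byte-identical
files (sorted element order, no timestamps).

## Known limitations

* The simplex is dense and refactorises every iteration; fine up to a few
  thousand reactions, not tuned for much beyond that.
* No loopless FVA, no MILP-based strain design, no kinetic/dynamic FBA,
  no ¹³C flux fitting (measured fluxes can only be compared against, not
  fitted).
* SBML support covers Level 3 + FBC v2 and the legacy Level-2
  kinetic-law-parameter dialect; groups/layout/render packages and MAT
  files are not read.
* The fixture biomass is a stand-in: any comparison with genome-scale
  growth or yield magnitudes must use the deposited model through
  `scripts/repro_ibp722.R`.
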