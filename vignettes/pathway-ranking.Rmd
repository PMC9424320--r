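---
title: "Evaluating and ranking heterologous pathways with pathranker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and ranking heterologous pathways with pathranker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathranker)
```

## The problem

Retrosynthesis tools propose many candidate routes for producing a target
chemical in a host ("chassis") organism. Each route is a short chain of
non-native enzymatic reactions grafted onto the chassis' metabolic network.
Most proposed routes are poor: thermodynamically uphill, starved of
precursor flux, or catalyzed by enzymes nobody has ever found. pathranker
evaluates candidate pathways on these axes and ranks them, and turns the
chosen pathway into a combinatorial library of genetic construct designs
ready for automated DNA assembly.

The package covers six computational stages, each usable on its own:

1. **Exchange format** — pathways travel as SBML Level 3 documents enriched
   with annotations standard SBML does not house (structures, rule
   provenance, computed scores).
2. **Enumeration** — rule-level "master" pathways are expanded into
   concrete reactions by forking over reaction rules and their template
   reactions, re-adding cofactors.
3. **Flux** — maximal target production under a growth burden constraint
   (fraction-of-reaction FBA).
4. **Thermodynamics** — reaction and pathway Gibbs energies via a global
   pseudo-reaction found by linear programming.
5. **Scoring and matching** — a direct four-criterion score, a
   gradient-boosted global score, and similarity matching against
   literature reference pathways.
6. **Construct design** — exhaustive promoter x RBS-linker x gene-order
   enumeration on a BASIC assembly backbone.

## The enriched SBML dialect

Pathway documents are standard SBML L3V1 using the *groups* package: the
group `rp_pathway` lists the heterologous reactions; two further groups,
`rp_fba_ignored_species` and `rp_thermo_substituted_species`, document
decisions made during analysis. Chemical structures (InChI, SMILES,
InChIKey), rule provenance (rule id, template reaction id, enzyme
availability score) and computed properties live in one dedicated XML
namespace (`annotation_namespace()`), inside `<annotation>` elements that
standards-compliant readers skip. The element layout of that namespace is
defined by this package; the content it carries follows the conventions of
enriched-SBML pathway tooling, but the wire format is our own and should
not be mistaken for any other tool's.

Two serialization choices matter for reproducibility:

* Stoichiometries are written with at most 6 significant digits;
  energies and scores keep full double precision. With both conventions,
  write–read–write cycles are byte-identical, which the test suite asserts
  on generated fixtures.
* Species identity for deduplication is the InChIKey when present, else the
  id. The first 14-character InChIKey block (connectivity) is the identity
  used for structure-level comparison in matching and thermodynamic lookup.

Chassis models use the *flux-bounds* (fbc) package: per-reaction bound
parameters, an active objective marking the biomass reaction, and
`boundaryCondition="true"` for species excluded from mass balance.

## Fraction-of-reaction FBA

Plain FBA maximizes growth; a production strain must split resources
between growth and product. The fraction-of-reaction scheme makes that
burden explicit:

1. maximize the biomass reaction, record the optimum $B$;
2. fix both biomass bounds to $f \cdot B$;
3. maximize an irreversible sink on the target, `target ->`, bounds
   [0, 1000] mmol/gDCW/h;
4. restore every modified bound.

The default fraction is $f = 0.75$, a moderate burden that leaves room for
production without abandoning growth; it is exposed as an argument
(`fraction`) and on the command line (`--fraction`). The result depends on
$f$ monotonically (non-increasing target flux), which the suite checks on
a grid.

When a pathway is merged into the chassis, species absent from the chassis
that end up only consumed or only produced — typically cofactors with no
chassis counterpart — cannot carry steady-state flux. Their mass balance is
relaxed (they become boundary species) and they are recorded in
`rp_fba_ignored_species`. Pathway-internal intermediates, which are both
produced and consumed, remain balanced; relaxing them too would decouple
the pathway chain and inflate every flux estimate.

## Pathway thermodynamics

Reaction energies are formation-energy differences,
$\Delta_r G' = \sum_p n_p \Delta_f G'_p - \sum_s n_s \Delta_f G'_s$,
against a pluggable provider. The shipped provider is a TSV table
(`provider_key`, `dg_kj_mol`, `uncertainty`); an adapter to an external
thermodynamics service can implement the same two-element interface.
Species resolve to provider compounds through a fixed cascade that stops at
the first hit: id, InChIKey, InChI, SMILES, then the first provider key
sharing the species' first InChIKey block (first in table order), and
finally a user substitution, which is recorded in
`rp_thermo_substituted_species`. A reaction with any unresolved,
unsubstituted species has no thermodynamic value — absence, not zero.

At the pathway level the reactions are combined into one **global
pseudo-reaction** from chassis metabolites to the target. The multipliers
$x$ solve

$$\min\; c^\top x \quad \text{s.t.}\; A x = 0,\; x \ge 1,$$

where $A$ is the intermediates-by-reactions net stoichiometric matrix and
$c$ places 1 on every target-producing reaction. Intermediates are species
produced by one pathway reaction and consumed by another and not present in
the chassis; chassis metabolites are never constrained to cancel. Two
numerical choices deserve comment:

* **Objective sense.** Stated as a maximization, this program is unbounded:
  any feasible $x$ stays feasible under uniform scaling. Minimization is
  the sense under which the canonical three-reaction example has the unique
  solution $x = (3, 1.5, 1)$, and is what the package implements.
* **Tie-break.** $\min c^\top x$ alone can leave multipliers of reactions
  off the target path underdetermined. A second phase minimizes
  $\sum_i x_i$ at the fixed optimum, making the reported solution the
  minimal-scale one and deterministic. On fixtures the suite verifies by
  grid search that no feasible solution is componentwise smaller.

Multipliers are continuous (the example's 1.5 forces this). Species with
net stoichiometry below $10^{-9}$ are dropped from the pseudo-reaction, and
the suite asserts every intermediate cancels to that tolerance.

The linear programs (both here and in FBA) are solved by a dense two-phase
primal simplex with Bland's anti-cycling rule implemented in the package.
Problems in scope are small — tens of reactions — so a dense tableau is the
robust choice; degenerate instances (e.g. a biomass pinned exactly at its
optimum) are routine and the implementation is exercised against an
independent generic solver on non-degenerate cases in the tests.

## Features, scores and matching

**Reaction fingerprints.** A reaction is represented additively:
fingerprint(reaction) = fingerprint(substrates) + fingerprint(products),
with one contribution per participating species. Molecule fingerprints are
circular (Morgan-style) count vectors: atom environments of radius 0–2,
seeded from (element, degree, total bond order) invariants, hashed and
folded to 4096 bins. The radius (2) and width (4096) are package defaults;
the construction is invariant to atom ordering in the input SMILES, which
the suite checks against permuted SMILES of the same molecules.

**Pathway features.** The classifier consumes, per pathway: the chassis
taxonomy id; the pathway Gibbs energy; the fraction-of-reaction target
flux; the elementwise sum of reaction fingerprints; the mean enzyme
availability (rule) score; the sum of reaction Gibbs energies; and the
reaction count. The reaction-to-pathway aggregation (sum / mean) is
order-free by construction. Missing energy or flux is imputed with 0 plus a
binary missingness flag, so pathways with unresolved species remain
scoreable rather than silently dropped.

**Global score.** A gradient-boosted tree classifier (XGBoost) with maximum
tree depth 1000 and shrinkage 0.3; other hyperparameters stay at library
defaults, with 100 boosting rounds. Performance is reported from stratified
4-fold cross-validation (fold seed 42, exposed): overall accuracy and
false-positive rate at the 0.5 probability threshold.

**Direct score.** The non-learned alternative sums four criteria: inverse
pathway length, min–max normalized negated pathway energy, normalized mean
availability, normalized target flux — normalized across the candidate set
for one (target, chassis) pair. A criterion constant across the set
contributes 0.5 to every candidate (no information, no distortion).

**Top-k recovery.** For each (target, chassis) group containing a
reference pathway, the group counts as recovered when a reference score is
among the k highest *distinct* scores (ties share a rank), and the metric
is the fraction of recovered groups. It is non-decreasing in k.

**Literature matching.** A predicted pathway is compared to a reference
(steps of EC numbers plus main substrates/products) step by step:
similarity = ½ Jaccard over the union of main substrates and products
(first InChIKey block identity) + ½ EC agreement matched to three levels;
when either side lacks EC numbers the chemistry carries the whole weight.
Steps are aligned by dynamic programming over order-preserving injective
assignments, and the pathway score divides the best total by the larger
step count. "Main" species are the non-cofactors; the cofactor list is
configurable and defaults to common currency metabolites. The labeling
threshold is strict: a pathway is a literature pathway when its score
exceeds 0.5 — equality does not qualify. This scoring rule is
package-defined; only the threshold semantics and the structure-identity
criterion are anchored externally, so scores from other matching
implementations are not interchangeable with ours.

## Construct designs

For a registry of $P$ promoters, $R$ RBS-linker variants (each assignable
per gene), $G$ CDS and one backbone, enabling gene-order permutation yields
$P \cdot R^G \cdot G!$ designs — 96 for the canonical 2/2/3 registry. The
enumerator emits the full theoretical set in lexicographic order with
content-derived deterministic design ids; an exclusion list accommodates
downstream protocols that cannot build particular designs. The assembly
plan CSV (`design_id, backbone, promoter, slot1_linker, slot1_cds, ...`) is
this package's dialect, chosen because no authoritative column layout is
fixed by the assembly robots' drivers; it round-trips through
`read_assembly_plan()`.

## Synthetic fixtures: what they do and do not show

All tests run on generated data; nothing is downloaded.

* `make_toy_chassis(n_core)` builds a linear uptake → core chain → biomass
  model with the uptake capped at 10 mmol/gDCW/h, so the biomass optimum is
  known (10) and strictly positive for any size.
* `make_pathway_set()` attaches chains of fresh intermediates to chassis
  metabolites, with a cofactor pair on alternating reactions. Defaults
  mirror the structure of the expert-validation training collection:
  positive fraction 0.095 (one valid pathway in ten), pathway lengths 3–8
  (mean ≈ 5.5 reactions). The planted effect shifts positives by
  `effect_size` noise standard deviations: pathway energy down by
  `effect_size` × 10 kJ/mol, target flux up by `effect_size` × 1
  mmol/gDCW/h, availability scores up by `effect_size` × 0.1. Exactly
  `round(n × positive_fraction)` pathways are positive.
* Species receive real SMILES from a fixed 32-molecule alkane/alcohol/ether
  alphabet — fingerprints are computed on genuine molecular graphs — and
  synthetic InChIKeys (a deterministic hash into the 14-10-1 layout,
  labeled synthetic: they are not the keys of those molecules). Identity
  logic is exercised; chemistry-specific fingerprint structure is not.
* `make_rule_db()` produces rule databases whose enumeration counts are
  analytically predictable, with an option to plant a duplicated template
  under a second rule id.

Classifier checks run at collection size 200–300 with 4-fold CV; at the
default class imbalance the permutation-null accuracy stays within ±0.05 of
the majority rate and a planted effect of 3 noise-SD is recovered with
accuracy ≥ 0.95. Passing these tests shows the pipeline is correct and the
learner sees the planted signal; it does not certify real-data accuracy,
where features are correlated, labels are noisy, and class separation is
far from planted.

## Worked example

```{r example}
chassis <- make_toy_chassis(5, seed = 1)
pw <- make_pathway_set(30, chassis, seed = 7, effect_size = 3,
                       positive_fraction = 0.2)

## flux under a 75% growth burden for the first candidate
res <- fraction_of_reaction_fba(chassis, pw$pathways[[1]], fraction = 0.75)
res$result$target_flux

## thermodynamics against a generated formation-energy table
prov <- formation_provider(make_formation_table(pw$pathways, seed = 1))
annotated <- annotate_thermo(pw$pathways[[1]], prov,
                             chassis_species = names(chassis$species))
annotated$properties$pathway_dg

## direct scoring across the candidate set
head(direct_score(pw$pathways)[, c("pathway_id", "value")])
```

## Known limitations

* The simplex is dense: fine for toy and pathway-scale models, not for
  genome-scale reconstructions with thousands of reactions. Reading a
  genome-scale SBML works; optimizing one is outside the intended scale.
* Fingerprints use heavy-atom graphs without aromaticity perception or
  stereochemistry; two molecules differing only in those aspects can
  collide.
* The matching score implements the documented contract, not any external
  tool's exact formula; absolute score values are comparable only within
  this package.
* Formation energies are taken as given; no pH/ionic-strength transforms
  are applied (delegate to the provider).
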