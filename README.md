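# pathranker

Evaluation, scoring and ranking of heterologous metabolic pathways, and
combinatorial genetic-construct design for the pathway you pick.

Retrosynthesis software proposes many candidate routes for producing a
target chemical in a chassis organism (*E. coli*, *S. cerevisiae*, ...).
Most candidates are poor — thermodynamically uphill, starved of precursor
flux, or catalyzed by enzymes with no known sequence. pathranker is for
metabolic engineers and strain-design pipelines that need to triage such
candidate sets: it evaluates each pathway's production flux,
thermodynamic feasibility and enzyme availability, combines them into
direct or machine-learned scores, matches predictions against literature
pathways, and expands the chosen pathway into an assembly-ready library of
construct designs.

## What it computes

* **Enriched SBML I/O** — pathways as SBML L3V1 documents with the groups
  package (`rp_pathway`, `rp_fba_ignored_species`,
  `rp_thermo_substituted_species`) plus structures (InChI/SMILES/InChIKey),
  rule provenance and computed properties in a dedicated annotation
  namespace; chassis models with fbc flux bounds. Round-trips are
  byte-identical.
* **Pathway enumeration** — master pathways (rule-level transformations)
  are expanded by forking over reaction rules and template reactions,
  re-adding cofactors from the templates, removing duplicate pathways
  under structure-based species identity.
* **Fraction-of-reaction FBA** — maximize biomass flux v_bio to get the
  optimum B, pin v_bio = f·B (default f = 0.75), then maximize an
  irreversible target sink; all bounds restored afterwards.
* **Pseudo-reaction thermodynamics** — multipliers x solve
  min cᵀx s.t. Ax = 0, x ≥ 1 (A = intermediates × reactions net
  stoichiometry, c marks target-producing reactions), collapsing the
  pathway into one net reaction from chassis metabolites to the target;
  ΔG' values come from a pluggable formation-energy provider through an
  id → InChIKey → InChI → SMILES → InChIKey-block → substitution cascade.
* **Scoring** — Morgan-style 4096-bin count fingerprints with
  fp(reaction) = fp(substrates) + fp(products); an XGBoost global score
  (max depth 1000, shrinkage 0.3, stratified 4-fold CV at threshold 0.5);
  a direct score = 1/length + normalized(−ΔG') + normalized(availability)
  + normalized(flux); top-k recovery over distinct-score ranks.
* **Literature matching** — order-preserving step alignment on main
  substrate/product identity (first InChIKey block) and 3-level EC
  agreement; "literature pathway" label strictly above score 0.5.
* **Construct design** — all P · R^G · G! promoter × RBS-linker ×
  gene-order designs on a backbone (96 for 2 promoters, 2 linkers, 3 CDS),
  serialized to a deterministic assembly-plan CSV.
* **Synthetic fixtures** — seeded generators for toy chassis models, rule
  databases, formation tables and labeled pathway collections with a
  planted, tunable class separation.

## Worked example

```r
library(pathranker)

chassis <- make_toy_chassis(5, seed = 1)            # toy host, biomass optimum 10
pw <- make_pathway_set(30, chassis, seed = 7,       # 30 candidates, 20% positives
                       effect_size = 3, positive_fraction = 0.2)

# production flux under a 75% growth burden
res <- fraction_of_reaction_fba(chassis, pw$pathways[[1]], fraction = 0.75)
res$result$target_flux
#> [1] 2.5

# pathway Gibbs energy from a generated formation-energy table
prov <- formation_provider(make_formation_table(pw$pathways, seed = 1))
annotated <- annotate_thermo(pw$pathways[[1]], prov,
                             chassis_species = names(chassis$species))
annotated$properties$pathway_dg
#> [1] 335.18

# direct scores across the candidate set (sum of four normalized criteria,
# higher is better; 335 kJ/mol uphill drags SYN_0001 down)
head(direct_score(pw$pathways)[, c("pathway_id", "value")])
#>   pathway_id     value
#> 1   SYN_0001 0.9350768
#> 2   SYN_0002 2.9948980
#> 3   SYN_0003 1.1068271
#> 4   SYN_0004 1.1136918
#> 5   SYN_0005 1.2638850
#> 6   SYN_0006 1.6389000
```

With the uptake bound at 10 mmol/gDCW/h and biomass pinned at 7.5, at most
2.5 mmol/gDCW/h of carbon remain for the target — the flux the burden
constraint is designed to expose. A command-line dispatcher over the same
functions ships as `exec/pathranker`
(`pathranker fba --model m.sbml --pathway p.sbml --fraction 0.75 ...`).

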