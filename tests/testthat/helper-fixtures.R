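# Shared fixtures built in code; no files on disk.

# Three-reaction pathway used throughout the thermodynamics tests: two
# pathway-internal intermediates (CMPD3, CMPD4) that must cancel in the
# global pseudo-reaction, chassis currency metabolites (MNXM*) that must not.
thermo_example_pathway <- function() {
  sp <- lapply(c("MNXM1", "MNXM188", "MNXM4", "MNXM6", "MNXM13", "MNXM15",
                 "MNXM5", "CMPD3", "CMPD4", "TARGET"), species_record)
  pathway_record(
    "thermo_example",
    reactions = list(
      reaction_record("Rxn1",
                      reactants = c(MNXM188 = 1, MNXM4 = 1, MNXM6 = 1, MNXM1 = 3),
                      products = c(CMPD4 = 1, CMPD3 = 1, MNXM13 = 1,
                                   MNXM15 = 1, MNXM5 = 1)),
      reaction_record("Rxn2",
                      reactants = c(MNXM4 = 1, CMPD3 = 2),
                      products = c(MNXM1 = 2, TARGET = 1)),
      reaction_record("Rxn3",
                      reactants = c(MNXM4 = 1, MNXM6 = 1, CMPD4 = 3),
                      products = c(MNXM13 = 1, MNXM5 = 1))),
    target_id = "TARGET",
    species = sp)
}

thermo_example_chassis_species <- function() {
  grep("^MNXM", names(thermo_example_pathway()$species), value = TRUE)
}

# Simple 2-reaction chain A -> B -> T with fully resolvable species.
chain_pathway <- function(id = "chain") {
  pathway_record(
    id,
    reactions = list(
      reaction_record("S1", reactants = c(A = 1), products = c(B = 1)),
      reaction_record("S2", reactants = c(B = 1), products = c(T = 1))),
    target_id = "T",
    species = lapply(c("A", "B", "T"), species_record))
}

# Formation-energy provider over explicit values (id-keyed).
table_provider <- function(...) {
  vals <- c(...)
  formation_provider(data.frame(provider_key = names(vals),
                                dg_kj_mol = as.numeric(vals),
                                uncertainty = NA_real_,
                                stringsAsFactors = FALSE))
}

# The BASIC registry used in the combinatorial-design benchmarks: two
# constitutive promoters, two RBS linker variants, three CDS, one backbone.
lycopene_registry <- function() {
  parts_registry(
    promoters = c("PJ23105", "PJ23116"),
    rbs_linkers = c("A03", "A04"),
    cds = c("crtB", "crtE", "crtI"),
    backbone = "BASIC_SEVA_36_CmR-p15A.1")
}

# Independent brute-force oracle for pathway enumeration: builds the full
# Cartesian product of per-transformation completed alternatives and returns
# the set of duplicate-free reaction-signature multisets.
brute_force_enumeration <- function(m, db, species) {
  alts <- lapply(m$transformations, complete_transformation, db = db)
  sig <- function(r) {
    key_of <- function(sid) {
      sp <- species[[sid]]
      if (!is.null(sp) && !is.null(sp$inchikey)) sp$inchikey else sid
    }
    fmt <- function(v) {
      keys <- vapply(names(v), key_of, character(1))
      o <- order(keys)
      paste(sprintf("%.9f*%s", unname(v)[o], keys[o]), collapse = "+")
    }
    paste(fmt(r$reactants), fmt(r$products), sep = ">>")
  }
  combos <- expand.grid(lapply(alts, seq_along), KEEP.OUT.ATTRS = FALSE)
  keys <- vapply(seq_len(nrow(combos)), function(i) {
    sigs <- vapply(seq_along(alts),
                   function(j) sig(alts[[j]][[combos[i, j]]]), character(1))
    paste(sort(sigs), collapse = " || ")
  }, character(1))
  unique(keys)
}
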