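test_that("the three-reaction pseudo-reaction reproduces the known multipliers", {
  p <- thermo_example_pathway()
  got <- build_pseudo_reaction(p, chassis_species = thermo_example_chassis_species())
  expect_equal(unname(got$multipliers), c(3, 1.5, 1), tolerance = 1e-9)
  expect_setequal(got$intermediates, c("CMPD3", "CMPD4"))
  net <- got$net
  expect_equal(unname(net$reactants[["MNXM4"]]), 5.5, tolerance = 1e-9)
  expect_equal(unname(net$reactants[["MNXM6"]]), 4, tolerance = 1e-9)
  expect_equal(unname(net$products[["MNXM13"]]), 4, tolerance = 1e-9)
  expect_equal(unname(net$products[["MNXM15"]]), 3, tolerance = 1e-9)
  expect_equal(unname(net$products[["MNXM5"]]), 4, tolerance = 1e-9)
  # intermediates are gone from the net reaction
  expect_false(any(c("CMPD3", "CMPD4") %in%
                     c(names(net$reactants), names(net$products))))
})

test_that("degenerate pseudo-reactions behave: identity and unit chains", {
  single <- pathway_record(
    "single",
    reactions = list(reaction_record("R1", c(A = 1), c(T = 2))),
    target_id = "T", species = lapply(c("A", "T"), species_record))
  got <- build_pseudo_reaction(single)
  expect_equal(unname(got$multipliers), 1)
  expect_equal(got$net$reactants, single$reactions$R1$reactants)
  expect_equal(got$net$products, single$reactions$R1$products)

  ch <- chain_pathway()
  got2 <- build_pseudo_reaction(ch)
  expect_equal(unname(got2$multipliers), c(1, 1), tolerance = 1e-9)
  expect_identical(names(got2$net$reactants), "A")
  expect_identical(names(got2$net$products), "T")
})

test_that("intermediates cancel in every generated pathway", {
  chassis <- make_toy_chassis(5, seed = 4)
  pw <- make_pathway_set(8, chassis, seed = 5, n_reactions_range = c(2, 6),
                         positive_fraction = 0.3)
  for (p in pw$pathways) {
    got <- build_pseudo_reaction(p, chassis_species = names(chassis$species))
    for (sid in got$intermediates) {
      net <- 0
      for (j in seq_along(p$reactions)) {
        r <- p$reactions[[j]]
        net <- net + got$multipliers[[j]] *
          ((if (sid %in% names(r$products)) r$products[[sid]] else 0) -
           (if (sid %in% names(r$reactants)) r$reactants[[sid]] else 0))
      }
      expect_lt(abs(net), 1e-9)
    }
    expect_true(all(got$multipliers >= 1 - 1e-9))
  }
})

test_that("multipliers are the componentwise-minimal feasible solution", {
  p <- thermo_example_pathway()
  got <- build_pseudo_reaction(p, chassis_species = thermo_example_chassis_species())
  x <- unname(got$multipliers)
  # brute force over a small grid: no feasible y <= x with y != x
  A <- rbind(CMPD3 = c(1, -2, 0), CMPD4 = c(1, 0, -3))
  grid <- expand.grid(x1 = seq(1, x[1], by = 0.25),
                      x2 = seq(1, x[2], by = 0.25),
                      x3 = seq(1, x[3], by = 0.25))
  feas <- apply(grid, 1, function(y) all(abs(A %*% y) < 1e-9))
  dominated <- apply(grid, 1, function(y) all(y <= x + 1e-12) && any(y < x - 1e-12))
  expect_false(any(feas & dominated))
})

test_that("non-cancellable intermediates raise a thermodynamics error", {
  # M and N are both produced and consumed, but their cancellation system
  # (2 x1 = x2 and x1 = 3 x2) only admits x = 0, infeasible under x >= 1
  p_inf <- pathway_record(
    "stuck",
    reactions = list(
      reaction_record("R1", c(A = 1, N = 1), c(M = 2, T = 1)),
      reaction_record("R2", c(M = 1), c(N = 3, T = 1))),
    target_id = "T", species = lapply(c("A", "M", "N", "T"), species_record))
  expect_error(build_pseudo_reaction(p_inf), "cancel")
})

test_that("the lookup cascade stops at the first hit and records substitutions", {
  prov <- formation_provider(data.frame(
    provider_key = c("SP1",
                     "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                     "AAAAAAAAAAAAAA-CCCCCCCCCC-N",
                     "InChI=1S/H2O/h1H2", "CCO", "SUBKEY"),
    dg_kj_mol = c(-10, -20, -30, -40, -50, -60)))

  # id outranks a matching InChIKey
  s1 <- species_record("SP1", inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N")
  expect_identical(lookup_compound(s1, prov)$matched_by, "id")
  # exact InChIKey before anything structural
  s2 <- species_record("other", inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N")
  expect_identical(lookup_compound(s2, prov)$matched_by, "inchikey")
  # InChI and SMILES rungs
  s3 <- species_record("w", inchi = "InChI=1S/H2O/h1H2")
  expect_identical(lookup_compound(s3, prov)$matched_by, "inchi")
  s4 <- species_record("e", smiles = "CCO")
  expect_identical(lookup_compound(s4, prov)$matched_by, "smiles")
  # first-block fallback takes the first provider entry in table order
  s5 <- species_record("b", inchikey = "AAAAAAAAAAAAAA-ZZZZZZZZZZ-N")
  got5 <- lookup_compound(s5, prov)
  expect_identical(got5$matched_by, "inchikey_block1")
  expect_identical(got5$provider_key, "AAAAAAAAAAAAAA-BBBBBBBBBB-N")
  # structureless species resolve only through an explicit substitution
  s6 <- species_record("mystery")
  expect_null(lookup_compound(s6, prov))
  got6 <- lookup_compound(s6, prov, substitutions = list(mystery = "SUBKEY"))
  expect_identical(got6$matched_by, "substitution")
  expect_error(lookup_compound(s6, prov, substitutions = list(mystery = "NOPE")),
               "NOPE")
})

test_that("reaction energies are formation-energy differences; gaps yield absence", {
  prov <- table_provider(A = -100, B = -150, T = -250)
  r <- reaction_record("r", c(A = 1, B = 2), c(T = 1))
  sp <- stats::setNames(lapply(c("A", "B", "T"), species_record), c("A", "B", "T"))
  got <- reaction_dg(r, sp, prov)
  expect_equal(got$value, -250 - (-100 - 2 * 150))
  # one unresolved species -> no thermodynamic value
  r2 <- reaction_record("r2", c(A = 1), c(GHOST = 1))
  sp2 <- c(sp, list(GHOST = species_record("GHOST")))
  expect_null(reaction_dg(r2, sp2, prov))
  # degenerate identity reaction nets out to zero energy
  r3 <- reaction_record("r3", c(A = 1), c(A = 1))
  expect_equal(reaction_dg(r3, sp, prov)$value, 0)
})

test_that("pathway energy is linear in the member reactions", {
  prov <- table_provider(A = -100, B = -130, T = -240)
  p <- chain_pathway()
  got <- pathway_dg(p, prov)
  # multipliers are all 1 on a unit chain: pathway dG = sum of reaction dGs
  dg1 <- reaction_dg(p$reactions$S1, p$species, prov)$value
  dg2 <- reaction_dg(p$reactions$S2, p$species, prov)$value
  expect_equal(got$value, dg1 + dg2)
  # weighted case: the known three-reaction example with a constant provider
  pex <- thermo_example_pathway()
  keys <- names(pex$species)
  prov2 <- formation_provider(data.frame(
    provider_key = keys, dg_kj_mol = seq(-10, by = -7, length.out = length(keys))))
  mult <- build_pseudo_reaction(pex, thermo_example_chassis_species())$multipliers
  per_rxn <- vapply(pex$reactions, function(r)
    reaction_dg(r, pex$species, prov2)$value, numeric(1))
  expect_equal(pathway_dg(pex, prov2,
                          chassis_species = thermo_example_chassis_species())$value,
               sum(mult * per_rxn), tolerance = 1e-9)
})

test_that("annotation writes energies, properties and the substitution group", {
  p <- chain_pathway()
  prov <- table_provider(A = -100, B = -130, SUB_T = -240)
  p$species$T <- species_record("T")  # structureless target
  got <- annotate_thermo(p, prov, substitutions = list(T = "SUB_T"))
  expect_equal(got$reactions$S1$dg_prime, -30)
  expect_equal(got$properties$pathway_dg, -140)
  expect_true("T" %in% got$groups$rp_thermo_substituted_species)
  # the group survives serialization
  expect_true(grepl("rp_thermo_substituted_species", write_pathway(got)))
})
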