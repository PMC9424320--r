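# Hand-solvable setting: uptake of the carbon source is capped at 10, biomass
# drains the end of the chassis chain, and the heterologous pathway drains the
# first core metabolite, so target flux = 10 * (1 - fraction).
toy_setting <- function() {
  ch <- make_toy_chassis(2, seed = 1)
  p <- pathway_record(
    "p_direct",
    reactions = list(reaction_record("R_het", reactants = c(C1 = 1),
                                     products = c(TGT = 1))),
    target_id = "TGT",
    species = list(ch$species$C1, species_record("TGT")))
  list(ch = ch, p = p)
}

test_that("fraction-of-reaction FBA matches the hand-solved linear program", {
  s <- toy_setting()
  got <- fraction_of_reaction_fba(s$ch, s$p, fraction = 0.5)
  expect_equal(got$result$biomass_optimum, 10, tolerance = 1e-6)
  expect_equal(got$result$target_flux, 5, tolerance = 1e-6)
  # no slack left for the target when the biomass keeps its full optimum
  got1 <- fraction_of_reaction_fba(s$ch, s$p, fraction = 1.0)
  expect_equal(got1$result$target_flux, 0, tolerance = 1e-6)
  # annotations land on the pathway
  expect_equal(got$pathway$properties$target_flux, 5, tolerance = 1e-6)
  expect_equal(got$pathway$properties$fba_fraction, 0.5)
})

test_that("model bounds are bit-for-bit identical before and after the call", {
  s <- toy_setting()
  merged <- merge_pathway(s$ch, s$p)
  before <- lapply(merged$reactions, function(r) c(r$lower_bound, r$upper_bound))
  invisible(fraction_of_reaction_fba(s$ch, s$p, fraction = 0.3))
  after <- lapply(merge_pathway(s$ch, s$p)$reactions,
                  function(r) c(r$lower_bound, r$upper_bound))
  expect_identical(before, after)
  ch_after <- lapply(s$ch$reactions, function(r) c(r$lower_bound, r$upper_bound))
  expect_identical(ch_after,
                   lapply(make_toy_chassis(2, seed = 1)$reactions,
                          function(r) c(r$lower_bound, r$upper_bound)))
})

test_that("target flux is non-increasing in the biomass fraction", {
  ch <- make_toy_chassis(5, seed = 7)
  pw <- make_pathway_set(2, ch, seed = 8, n_reactions_range = c(2, 4),
                         positive_fraction = 0.4)
  for (p in pw$pathways) {
    fluxes <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9, 1.0), function(f) {
      fraction_of_reaction_fba(ch, p, f)$result$target_flux
    }, numeric(1))
    expect_true(all(diff(fluxes) <= 1e-6))
    # bounded by the unconstrained maximum of the sink
    merged <- merge_pathway(ch, p)
    unconstrained <- optimize_flux(merged, paste0("SINK_", p$target_id))$objective
    expect_true(all(fluxes <= unconstrained + 1e-6))
  }
})

test_that("results agree with an independently coded dense LP", {
  # same toy problem written out explicitly: columns are
  # R_uptake, R_core1, R_biomass, R_het, SINK; rows balance C1, C2, TGT
  S <- rbind(C1 = c(1, -1, 0, -1, 0),
             C2 = c(0, 1, -1, 0, 0),
             TGT = c(0, 0, 0, 1, -1))
  ub <- c(10, 1000, 1000, 1000, 1000)
  lp_max <- function(obj, extra_fix = NULL) {
    A3 <- S; b3 <- rep(0, 3)
    A1 <- diag(5); b1 <- ub
    if (!is.null(extra_fix)) {
      A3 <- rbind(A3, extra_fix$row)
      b3 <- c(b3, extra_fix$rhs)
    }
    unname(boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                         maxi = TRUE)$value)
  }
  for (f in c(0.25, 0.5, 0.8)) {
    B <- lp_max(c(0, 0, 1, 0, 0))
    oracle <- lp_max(c(0, 0, 0, 0, 1),
                     extra_fix = list(row = c(0, 0, 1, 0, 0), rhs = f * B))
    s <- toy_setting()
    got <- fraction_of_reaction_fba(s$ch, s$p, fraction = f)$result$target_flux
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("orphan cofactors are ignored and listed, without breaking the flux", {
  ch <- make_toy_chassis(2, seed = 1)
  p <- pathway_record(
    "p_cof",
    reactions = list(reaction_record(
      "R_het", reactants = c(C1 = 1, NADH_X = 1),
      products = c(TGT = 1, NAD_X = 1))),
    target_id = "TGT",
    species = c(list(ch$species$C1),
                lapply(c("TGT", "NADH_X", "NAD_X"), species_record)))
  got <- fraction_of_reaction_fba(ch, p, fraction = 0.5)
  expect_true(all(c("NADH_X", "NAD_X") %in% got$result$ignored_species))
  expect_true(all(c("NADH_X", "NAD_X") %in%
                    got$pathway$groups$rp_fba_ignored_species))
  # the dead-end cofactor pair must not block production
  expect_equal(got$result$target_flux, 5, tolerance = 1e-6)
})

test_that("merging is idempotent for identical duplicates and rejects conflicts", {
  s <- toy_setting()
  merged <- merge_pathway(s$ch, s$p)
  n_before <- length(merged$reactions)
  # pathway reaction with an id already present and the same definition
  p_dup <- s$p
  p_dup$reactions$R_core1 <- s$ch$reactions$R_core1
  p_dup$species$C2 <- s$ch$species$C2
  merged2 <- merge_pathway(s$ch, p_dup)
  expect_length(merged2$reactions, n_before)
  # same id, different stoichiometry -> merge error
  p_bad <- s$p
  p_bad$reactions$R_core1 <- reaction_record("R_core1", c(C1 = 2), c(C2 = 1))
  p_bad$species$C2 <- s$ch$species$C2
  expect_error(merge_pathway(s$ch, p_bad), "conflict")
})

test_that("out-of-range fractions are rejected", {
  s <- toy_setting()
  expect_error(fraction_of_reaction_fba(s$ch, s$p, fraction = 0), "fraction")
  expect_error(fraction_of_reaction_fba(s$ch, s$p, fraction = 1.5), "fraction")
})
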